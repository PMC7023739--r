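#' Define a clinic configuration
#'
#' A configuration is the decision vector studied in the capacity experiments
#' plus the fixed operational parameters of the clinic day. The decision
#' variables are: the number of women attending (`arrivals`, 2-20 in the
#' factorial design), the arrival pattern (`"All"` at opening or `"Half"`
#' split between 08:00 and 08:30), the consultation order (`"Mid"`: midwife
#' stage first; `"Doc"`: a woman whose check-in completes while a doctor is
#' idle is seen by the doctor first and skips the post-CTG visit), and the
#' numbers of midwives, doctors and CTG machines.
#'
#' Fixed parameters: one receptionist handles check-in and check-out, the
#' clinic opens at 08:00 and closes at 10:30 (it stays open past closing
#' until every woman has departed), and the model day ends at 23:59. An
#' optional Poisson stream of women from other clinics competing only for
#' reception can be switched on; it is off by default because its rate is a
#' local staffing detail, not part of the study design.
#'
#' @param arrivals Number of post-term women attending (X0).
#' @param arrival_pattern `"All"` or `"Half"` (X1).
#' @param consult_order `"Mid"` or `"Doc"` (X2).
#' @param midwives,doctors,ctg_machines Resource counts (X3, X4, X5).
#' @param reception_staff Receptionists on duty (fixed parameter).
#' @param open_time,close_time,horizon Clock times in decimal minutes since
#'   midnight; defaults 480 (08:00), 630 (10:30), 1439 (23:59).
#' @param background_stream_enabled Enable the other-clinic arrival stream.
#' @param background_rate Arrivals per hour for that stream.
#' @return A `clinic_config` object (a validated named list).
#' @export
#' @examples
#' clinic_config()  # the base case: 7 women, All/Mid, 2 midwives, 2 doctors, 3 CTGs
clinic_config <- function(arrivals = 7,
                          arrival_pattern = c("All", "Half"),
                          consult_order = c("Mid", "Doc"),
                          midwives = 2,
                          doctors = 2,
                          ctg_machines = 3,
                          reception_staff = 1,
                          open_time = CLINIC_OPEN,
                          close_time = CLINIC_CLOSE,
                          horizon = CLINIC_HORIZON,
                          background_stream_enabled = FALSE,
                          background_rate = 0) {
  arrival_pattern <- match.arg(arrival_pattern)
  consult_order <- match.arg(consult_order)
  cfg <- structure(
    list(
      arrivals = as.integer(arrivals),
      arrival_pattern = arrival_pattern,
      consult_order = consult_order,
      midwives = as.integer(midwives),
      doctors = as.integer(doctors),
      ctg_machines = as.integer(ctg_machines),
      reception_staff = as.integer(reception_staff),
      open_time = as.numeric(open_time),
      close_time = as.numeric(close_time),
      horizon = as.numeric(horizon),
      background_stream_enabled = isTRUE(background_stream_enabled),
      background_rate = as.numeric(background_rate)
    ),
    class = "clinic_config"
  )
  validate_clinic_config(cfg)
}

validate_clinic_config <- function(cfg) {
  stopifnot(inherits(cfg, "clinic_config"))
  if (cfg$arrivals < 1) {
    stop("arrivals must be at least 1", call. = FALSE)
  }
  counts <- c(midwives = cfg$midwives, doctors = cfg$doctors,
              ctg_machines = cfg$ctg_machines,
              reception_staff = cfg$reception_staff)
  if (any(counts < 1)) {
    stop("resource counts must all be >= 1 (",
         paste(names(counts)[counts < 1], collapse = ", "), ")",
         call. = FALSE)
  }
  if (!(cfg$open_time < cfg$close_time && cfg$close_time < cfg$horizon)) {
    stop("need open_time < close_time < horizon", call. = FALSE)
  }
  if (cfg$background_stream_enabled && cfg$background_rate <= 0) {
    stop("background stream enabled but background_rate <= 0", call. = FALSE)
  }
  cfg
}

#' @export
print.clinic_config <- function(x, ...) {
  cat("<clinic_config> ", x$arrivals, " women, ",
      x$arrival_pattern, "/", x$consult_order, ", ",
      x$midwives, " midwives, ", x$doctors, " doctors, ",
      x$ctg_machines, " CTGs, ", x$reception_staff, " reception\n", sep = "")
  cat("  open ", format_clock_time(x$open_time), ", close ",
      format_clock_time(x$close_time), ", horizon ",
      format_clock_time(x$horizon), "\n", sep = "")
  invisible(x)
}

#' Build the arrival schedule for a clinic day
#'
#' Under pattern `"All"` every woman arrives when the clinic opens. Under
#' `"Half"` the arrivals split between opening time and thirty minutes later;
#' for an odd count the larger half arrives at opening.
#'
#' @param arrivals Number of women.
#' @param pattern `"All"` or `"Half"`.
#' @param open_time Opening clock time in minutes since midnight.
#' @return A numeric vector of arrival times, one per woman, ordered by
#'   woman id.
#' @export
#' @examples
#' build_arrival_schedule(7, "Half")  # 4 at 08:00, 3 at 08:30
build_arrival_schedule <- function(arrivals, pattern, open_time = CLINIC_OPEN) {
  stopifnot(arrivals >= 1)
  if (!pattern %in% c("All", "Half")) {
    stop("unknown arrival pattern: '", pattern, "'", call. = FALSE)
  }
  if (pattern == "All") {
    rep(open_time, arrivals)
  } else {
    n_early <- ceiling(arrivals / 2)
    c(rep(open_time, n_early), rep(open_time + 30, arrivals - n_early))
  }
}
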