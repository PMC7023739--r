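# Multi-replication trials and the full-factorial experiment.
#
# Replication seeding uses L'Ecuyer-CMRG substreams: one master seed fixes a
# stream per replication, so trials are bit-reproducible, replications are
# order-invariant, and configurations sharing a master seed reuse the same
# service-time draws (common random numbers).

KPI_NAMES <- c("y1_arrivals", "y2_last_checkout", "y3_mean_los", "y4_overrun",
               "y5_midwife_wait", "y6_doctor_wait", "y7_ctg_connection_wait")

with_rng_restored <- function(code) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  force(code)
}

replication_streams <- function(master_seed, n) {
  set.seed(master_seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

#' Run a multi-replication trial of one configuration
#'
#' Simulates `n_reps` independent clinic days of one configuration and
#' summarises each KPI by its mean and 95% confidence half-width
#' (normal approximation, `1.96 * sd / sqrt(n)`). Days on which a woman is
#' still present at the model horizon are counted as invalid and excluded
#' from the summary with a warning.
#'
#' @param config A [clinic_config()].
#' @param dists Fitted distribution set ([fit_service_distributions()]).
#' @param n_reps Number of replications (>= 2).
#' @param master_seed Integer seed; each replication gets its own
#'   L'Ecuyer-CMRG substream derived from it.
#' @param keep_replications If `TRUE`, attach the per-replication KPI matrix
#'   as attribute `"replications"`.
#' @return A one-row tibble (class `trial_summary`) with the configuration
#'   fields, `n_reps`, `n_invalid`, a `<kpi>` mean column and a `<kpi>_hw`
#'   half-width column for each of the seven KPIs, and `feasible` (trial
#'   mean last-checkout at or before closing time).
#' @export
#' @examples
#' dists <- fit_service_distributions()
#' run_trial(clinic_config(), dists, n_reps = 100, master_seed = 1)
run_trial <- function(config, dists, n_reps = 10000, master_seed = 1,
                      keep_replications = FALSE) {
  validate_clinic_config(config)
  stopifnot(n_reps >= 2)
  kpis <- matrix(NA_real_, nrow = n_reps, ncol = 7L,
                 dimnames = list(NULL, KPI_NAMES))
  valid <- logical(n_reps)
  with_rng_restored({
    streams <- replication_streams(master_seed, n_reps)
    for (i in seq_len(n_reps)) {
      assign(".Random.seed", streams[[i]], globalenv())
      inputs <- draw_day_inputs(config, dists)
      mat <- simulate_day_core(config, inputs$svc, inputs$checks,
                               inputs$bg_arrivals, inputs$bg_service)
      valid[i] <- attr(mat, "valid")
      if (valid[i]) kpis[i, ] <- day_kpis_from_matrix(mat, config$close_time)
    }
  })
  n_invalid <- sum(!valid)
  if (n_invalid == n_reps) {
    stop("all ", n_reps, " replications invalid: demand of ",
         config$arrivals, " women cannot be served by the model horizon",
         call. = FALSE)
  }
  if (n_invalid > 0) {
    warning(n_invalid, " of ", n_reps, " replications invalid ",
            "(woman present at horizon); excluded from the summary",
            call. = FALSE)
    kpis <- kpis[valid, , drop = FALSE]
  }
  means <- colMeans(kpis)
  hws <- 1.96 * apply(kpis, 2L, sd) / sqrt(nrow(kpis))
  out <- tibble::tibble(
    arrivals = config$arrivals,
    arrival_pattern = config$arrival_pattern,
    consult_order = config$consult_order,
    midwives = config$midwives,
    doctors = config$doctors,
    ctg_machines = config$ctg_machines,
    n_reps = as.integer(n_reps),
    n_invalid = as.integer(n_invalid)
  )
  for (k in KPI_NAMES) {
    out[[k]] <- unname(means[k])
    out[[paste0(k, "_hw")]] <- unname(hws[k])
  }
  out$feasible <- out$y2_last_checkout <= config$close_time
  class(out) <- c("trial_summary", class(out))
  if (keep_replications) attr(out, "replications") <- kpis
  out
}

#' Enumerate the full-factorial configuration lattice
#'
#' The experiment crosses two arrival patterns, two consultation orders, two
#' midwife counts, two doctor counts, two CTG machine counts and nineteen
#' demand levels: 2 x 2 x 2 x 2 x 2 x 19 = 608 configurations, i.e. 32
#' resource/pathway combinations each evaluated at every demand level.
#' Rows are ordered by the group (resource triple) and subgroup (arrival
#' pattern x consultation order) labelling used in the result tables, then
#' by demand.
#'
#' @param x0_range Integer demand range, default `c(2, 20)`.
#' @param x1_levels,x2_levels Arrival patterns / consultation orders.
#' @param x3_levels,x4_levels,x5_levels Midwife / doctor / CTG counts.
#' @return A tibble with one row per configuration: `arrival_pattern`,
#'   `consult_order`, `midwives`, `doctors`, `ctg_machines`, `arrivals`,
#'   plus `group_id`, `subgroup_id` and `label` where the combination lies
#'   on the standard 2/3 x 2/3 x 3/4 reporting lattice.
#' @export
#' @examples
#' nrow(enumerate_factorial_configurations())  # 608
enumerate_factorial_configurations <- function(x0_range = c(2, 20),
                                               x1_levels = c("All", "Half"),
                                               x2_levels = c("Mid", "Doc"),
                                               x3_levels = c(2, 3),
                                               x4_levels = c(2, 3),
                                               x5_levels = c(3, 4)) {
  if (length(x0_range) != 2 || x0_range[2] < x0_range[1]) {
    stop("x0_range must be c(lo, hi) with hi >= lo", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    midwives = as.integer(x3_levels),
    doctors = as.integer(x4_levels),
    ctg_machines = as.integer(x5_levels),
    arrival_pattern = x1_levels,
    consult_order = x2_levels,
    arrivals = seq.int(x0_range[1], x0_range[2])
  )
  grid <- assign_group_labels(grid)
  dplyr::arrange(grid, !is.na(.data$group_id), .data$group_id,
                 .data$subgroup_id, .data$arrivals) |>
    dplyr::select(dplyr::all_of(c(
      "group_id", "subgroup_id", "label", "arrival_pattern", "consult_order",
      "midwives", "doctors", "ctg_machines", "arrivals"
    )))
}

#' Run trials for a table of configurations
#'
#' Maps [run_trial()] over the rows of a configuration tibble (such as from
#' [enumerate_factorial_configurations()]). All trials share the master
#' seed, so paired configurations reuse common random numbers.
#'
#' @param configs A tibble with columns `arrivals`, `arrival_pattern`,
#'   `consult_order`, `midwives`, `doctors`, `ctg_machines`.
#' @param dists Fitted distribution set.
#' @param n_reps Replications per configuration.
#' @param master_seed Integer master seed.
#' @param ... Further arguments to [clinic_config()] (e.g. `close_time`).
#' @return A tibble with one [run_trial()] summary row per configuration,
#'   carrying over any `group_id`/`subgroup_id`/`label` columns.
#' @export
run_factorial <- function(configs, dists, n_reps = 10000, master_seed = 1,
                          ...) {
  stopifnot(nrow(configs) > 0)
  rows <- purrr::map(seq_len(nrow(configs)), function(i) {
    row <- configs[i, ]
    cfg <- clinic_config(
      arrivals = row$arrivals,
      arrival_pattern = row$arrival_pattern,
      consult_order = row$consult_order,
      midwives = row$midwives,
      doctors = row$doctors,
      ctg_machines = row$ctg_machines,
      ...
    )
    out <- run_trial(cfg, dists, n_reps = n_reps, master_seed = master_seed)
    for (extra in intersect(c("group_id", "subgroup_id", "label"),
                            names(configs))) {
      out[[extra]] <- row[[extra]]
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Write trial summaries to CSV
#'
#' One row per configuration with all inputs, KPI means and half-widths,
#' written at full precision so that [read_trial_results()] round-trips the
#' table losslessly.
#'
#' @param summaries A tibble of [run_trial()] rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trial_results <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("no trial summaries to export", call. = FALSE)
  }
  readr::write_csv(summaries, path)
  invisible(path)
}

#' Read trial summaries written by [export_trial_results()]
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_trial_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Tidy a trial summary into long KPI form
#'
#' @param x A `trial_summary` row from [run_trial()].
#' @param ... Unused.
#' @return A tibble with one row per KPI: `kpi`, `mean`, `ci_halfwidth`.
#' @method tidy trial_summary
#' @export
tidy.trial_summary <- function(x, ...) {
  tibble::tibble(
    kpi = KPI_NAMES,
    mean = vapply(KPI_NAMES, function(k) x[[k]][1], numeric(1)),
    ci_halfwidth = vapply(KPI_NAMES, function(k) x[[paste0(k, "_hw")]][1],
                          numeric(1))
  )
}

#' One-line summary of a trial
#'
#' @param x A `trial_summary` row.
#' @param ... Unused.
#' @return A one-row tibble: configuration label fields, `n_reps`,
#'   `n_invalid`, `feasible`, mean LoS and mean last checkout.
#' @method glance trial_summary
#' @export
glance.trial_summary <- function(x, ...) {
  tibble::tibble(
    arrivals = x$arrivals[1],
    arrival_pattern = x$arrival_pattern[1],
    consult_order = x$consult_order[1],
    n_reps = x$n_reps[1],
    n_invalid = x$n_invalid[1],
    feasible = x$feasible[1],
    mean_los = x$y3_mean_los[1],
    last_checkout = format_clock_time(x$y2_last_checkout[1])
  )
}

#' @importFrom generics glance
#' @export
generics::glance
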