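# Discrete-event engine for one clinic day.
#
# Women flow through: reception check-in -> (doctor first, Doc order only,
# if one is idle at that instant) -> CTG machine -> midwife connects CTG ->
# scan (machine held; midwife held too when the drawn number of CTG checks
# is five or more) -> midwife disconnects -> doctor consultation (unless
# already seen) -> reception check-out. Every queue is FIFO per resource
# class; simultaneous events are processed in (time, woman id) order so a
# fixed seed fixes the whole schedule.

# event kinds
EV_ARRIVAL <- 1L
EV_CHECKIN_DONE <- 2L
EV_CONSULT_DONE <- 3L
EV_CONNECT_DONE <- 4L
EV_SCAN_DONE <- 5L
EV_DISCONNECT_DONE <- 6L
EV_CHECKOUT_DONE <- 7L
EV_BG_DONE <- 8L

# queue stages
ST_CHECKIN <- 1L
ST_CTG <- 2L
ST_MID_CONNECT <- 3L
ST_MID_DISCONNECT <- 4L
ST_DOCTOR <- 5L
ST_CHECKOUT <- 6L
ST_BACKGROUND <- 7L

REC_COLS <- c(
  "woman_id", "arrival", "checkin_wait", "checkin_service",
  "ctg_machine_wait", "midwife_connect_wait", "connect_service",
  "scan_service", "n_checks", "midwife_disconnect_wait",
  "disconnect_service", "doctor_wait", "consult_service",
  "checkout_wait", "checkout_service", "departure", "doctor_first", "los"
)

# Core engine. `svc` is an arrivals x 6 matrix of service durations in
# pathway order (check-in, connect, scan, disconnect, consultation,
# check-out); `checks` the per-woman CTG check counts. Background arrivals
# (other-clinic women) occupy reception once each for `bg_service` minutes
# and are excluded from the returned records. Returns the record matrix with
# attribute `valid` (FALSE when any woman is still present at the horizon).
simulate_day_core <- function(cfg, svc, checks,
                              bg_arrivals = numeric(0),
                              bg_service = numeric(0)) {
  n <- cfg$arrivals
  arr <- build_arrival_schedule(n, cfg$arrival_pattern, cfg$open_time)
  doc_order <- cfg$consult_order == "Doc"
  n_bg <- length(bg_arrivals)
  ntot <- n + n_bg

  ev_t <- c(arr, bg_arrivals)
  ev_w <- seq_len(ntot)
  ev_k <- rep(EV_ARRIVAL, ntot)

  avail_rec <- cfg$reception_staff
  avail_mid <- cfg$midwives
  avail_doc <- cfg$doctors
  avail_ctg <- cfg$ctg_machines
  q_rec <- integer(0); q_mid <- integer(0)
  q_doc <- integer(0); q_ctg <- integer(0)

  stage <- integer(ntot)
  qt <- numeric(ntot)
  doctor_first <- logical(ntot)
  held <- logical(ntot)
  ctg_done <- logical(ntot)

  w_ciw <- numeric(n); w_mw <- numeric(n); w_cw <- numeric(n)
  w_dw <- numeric(n); w_docw <- numeric(n); w_cow <- numeric(n)
  dep <- rep(NA_real_, n)

  schedule <- function(t, w, k) {
    ev_t[[length(ev_t) + 1L]] <<- t
    ev_w[[length(ev_w) + 1L]] <<- w
    ev_k[[length(ev_k) + 1L]] <<- k
  }

  dispatch_rec <- function(now) {
    while (avail_rec > 0L && length(q_rec) > 0L) {
      w <- q_rec[[1L]]
      q_rec <<- q_rec[-1L]
      avail_rec <<- avail_rec - 1L
      if (stage[[w]] == ST_CHECKIN) {
        w_ciw[[w]] <<- now - qt[[w]]
        schedule(now + svc[w, 1L], w, EV_CHECKIN_DONE)
      } else if (stage[[w]] == ST_CHECKOUT) {
        w_cow[[w]] <<- now - qt[[w]]
        schedule(now + svc[w, 6L], w, EV_CHECKOUT_DONE)
      } else {
        schedule(now + bg_service[[w - n]], w, EV_BG_DONE)
      }
    }
  }

  dispatch_mid <- function(now) {
    while (avail_mid > 0L && length(q_mid) > 0L) {
      w <- q_mid[[1L]]
      q_mid <<- q_mid[-1L]
      avail_mid <<- avail_mid - 1L
      if (stage[[w]] == ST_MID_CONNECT) {
        w_cw[[w]] <<- now - qt[[w]]
        schedule(now + svc[w, 2L], w, EV_CONNECT_DONE)
      } else {
        w_dw[[w]] <<- now - qt[[w]]
        schedule(now + svc[w, 4L], w, EV_DISCONNECT_DONE)
      }
    }
  }

  # a granted machine is held until disconnection ends; the woman then joins
  # the midwife queue to have the CTG connected
  dispatch_ctg <- function(now) {
    while (avail_ctg > 0L && length(q_ctg) > 0L) {
      w <- q_ctg[[1L]]
      q_ctg <<- q_ctg[-1L]
      avail_ctg <<- avail_ctg - 1L
      w_mw[[w]] <<- now - qt[[w]]
      stage[[w]] <<- ST_MID_CONNECT
      qt[[w]] <<- now
      q_mid[[length(q_mid) + 1L]] <<- w
      dispatch_mid(now)
    }
  }

  dispatch_doc <- function(now) {
    while (avail_doc > 0L && length(q_doc) > 0L) {
      w <- q_doc[[1L]]
      q_doc <<- q_doc[-1L]
      avail_doc <<- avail_doc - 1L
      w_docw[[w]] <<- now - qt[[w]]
      schedule(now + svc[w, 5L], w, EV_CONSULT_DONE)
    }
  }

  join <- function(w, st, now) {
    stage[[w]] <<- st
    qt[[w]] <<- now
    if (st == ST_CHECKIN || st == ST_CHECKOUT || st == ST_BACKGROUND) {
      q_rec[[length(q_rec) + 1L]] <<- w
      dispatch_rec(now)
    } else if (st == ST_CTG) {
      q_ctg[[length(q_ctg) + 1L]] <<- w
      dispatch_ctg(now)
    } else if (st == ST_DOCTOR) {
      q_doc[[length(q_doc) + 1L]] <<- w
      dispatch_doc(now)
    } else {
      q_mid[[length(q_mid) + 1L]] <<- w
      dispatch_mid(now)
    }
  }

  while (length(ev_t) > 0L) {
    idx <- which(ev_t == min(ev_t))
    if (length(idx) > 1L) idx <- idx[which.min(ev_w[idx])]
    now <- ev_t[[idx]]
    w <- ev_w[[idx]]
    k <- ev_k[[idx]]
    ev_t <- ev_t[-idx]; ev_w <- ev_w[-idx]; ev_k <- ev_k[-idx]

    if (k == EV_ARRIVAL) {
      join(w, if (w > n) ST_BACKGROUND else ST_CHECKIN, now)
    } else if (k == EV_CHECKIN_DONE) {
      avail_rec <- avail_rec + 1L
      dispatch_rec(now)
      # doctor-first is decided once, at this instant: only if a doctor is
      # idle right now does the woman have her consultation before the CTG
      if (doc_order && avail_doc > 0L) {
        doctor_first[[w]] <- TRUE
        avail_doc <- avail_doc - 1L
        w_docw[[w]] <- 0
        schedule(now + svc[w, 5L], w, EV_CONSULT_DONE)
      } else {
        join(w, ST_CTG, now)
      }
    } else if (k == EV_CONSULT_DONE) {
      avail_doc <- avail_doc + 1L
      dispatch_doc(now)
      if (doctor_first[[w]] && !ctg_done[[w]]) {
        join(w, ST_CTG, now)
      } else {
        join(w, ST_CHECKOUT, now)
      }
    } else if (k == EV_CONNECT_DONE) {
      if (checks[[w]] >= 5) {
        held[[w]] <- TRUE
      } else {
        avail_mid <- avail_mid + 1L
        dispatch_mid(now)
      }
      schedule(now + svc[w, 3L], w, EV_SCAN_DONE)
    } else if (k == EV_SCAN_DONE) {
      if (held[[w]]) {
        w_dw[[w]] <- 0
        schedule(now + svc[w, 4L], w, EV_DISCONNECT_DONE)
      } else {
        join(w, ST_MID_DISCONNECT, now)
      }
    } else if (k == EV_DISCONNECT_DONE) {
      avail_mid <- avail_mid + 1L
      avail_ctg <- avail_ctg + 1L
      ctg_done[[w]] <- TRUE
      dispatch_mid(now)
      dispatch_ctg(now)
      if (doctor_first[[w]]) {
        join(w, ST_CHECKOUT, now)
      } else {
        join(w, ST_DOCTOR, now)
      }
    } else if (k == EV_CHECKOUT_DONE) {
      avail_rec <- avail_rec + 1L
      dep[[w]] <- now
      dispatch_rec(now)
    } else if (k == EV_BG_DONE) {
      avail_rec <- avail_rec + 1L
      dispatch_rec(now)
    }
  }

  ids <- seq_len(n)
  mat <- cbind(
    woman_id = ids, arrival = arr,
    checkin_wait = w_ciw, checkin_service = svc[ids, 1L],
    ctg_machine_wait = w_mw, midwife_connect_wait = w_cw,
    connect_service = svc[ids, 2L], scan_service = svc[ids, 3L],
    n_checks = checks[ids], midwife_disconnect_wait = w_dw,
    disconnect_service = svc[ids, 4L], doctor_wait = w_docw,
    consult_service = svc[ids, 5L], checkout_wait = w_cow,
    checkout_service = svc[ids, 6L], departure = dep,
    doctor_first = as.numeric(doctor_first[ids]),
    los = dep - arr
  )
  attr(mat, "valid") <- all(!is.na(dep)) && all(dep <= cfg$horizon)
  mat
}

# Draw the per-woman uniform matrix for one replication and map it to
# service times by inversion. Row-major draws mean woman i's uniforms are
# independent of how many women follow her, which keeps service-time draws
# common across configurations sharing a seed.
draw_day_inputs <- function(cfg, dists) {
  n <- cfg$arrivals
  u <- matrix(runif(n * 7L), nrow = n, byrow = TRUE)
  svc <- cbind(
    quantile_service(dists$check_in, u[, 1L]),
    quantile_service(dists$connect_ctg, u[, 2L]),
    quantile_service(dists$ctg_scan, u[, 3L]),
    quantile_service(dists$disconnect_ctg, u[, 4L]),
    quantile_service(dists$consultation, u[, 5L]),
    quantile_service(dists$check_out, u[, 6L])
  )
  checks <- quantile_service(dists$n_ctg_checks, u[, 7L])
  bg_arrivals <- numeric(0)
  bg_service <- numeric(0)
  if (cfg$background_stream_enabled) {
    n_bg <- rpois(1L, cfg$background_rate *
                    (cfg$close_time - cfg$open_time) / 60)
    if (n_bg > 0L) {
      bg_arrivals <- sort(runif(n_bg, cfg$open_time, cfg$close_time))
      bg_service <- quantile_service(dists$check_in, runif(n_bg))
    }
  }
  list(svc = svc, checks = checks,
       bg_arrivals = bg_arrivals, bg_service = bg_service)
}

#' Simulate one clinic day
#'
#' Runs the discrete-event engine once: service times and CTG check counts
#' are drawn from the fitted distributions using R's active random-number
#' stream, and every woman is followed from arrival to check-out. The clinic
#' stays open past closing time until all women have departed; a day on
#' which any woman is still present at the model horizon (23:59) is flagged
#' invalid.
#'
#' @param config A [clinic_config()].
#' @param dists Distribution set from [fit_service_distributions()].
#' @param service_times Optional arrivals x 6 matrix of fixed service
#'   durations (pathway order: check-in, connect, scan, disconnect,
#'   consultation, check-out) overriding random draws — useful for
#'   deterministic scenario analysis.
#' @param n_checks Optional integer vector of CTG check counts per woman.
#' @return A `clinic_day` object: list with `records` (a tibble, one row per
#'   woman with every wait, service, departure and length of stay),
#'   `last_checkout`, `busy_minutes` (per-resource busy time inside opening
#'   hours), `valid`, and the configuration.
#' @export
#' @examples
#' dists <- fit_service_distributions()
#' set.seed(42)
#' day <- run_clinic_day(clinic_config(), dists)
#' day$records
run_clinic_day <- function(config, dists, service_times = NULL,
                           n_checks = NULL) {
  validate_clinic_config(config)
  if (is.null(service_times) || is.null(n_checks)) {
    inputs <- draw_day_inputs(config, dists)
    if (!is.null(service_times)) inputs$svc <- service_times
    if (!is.null(n_checks)) inputs$checks <- n_checks
  } else {
    inputs <- list(svc = service_times, checks = n_checks,
                   bg_arrivals = numeric(0), bg_service = numeric(0))
  }
  stopifnot(nrow(inputs$svc) == config$arrivals,
            length(inputs$checks) == config$arrivals)
  mat <- simulate_day_core(config, inputs$svc, inputs$checks,
                           inputs$bg_arrivals, inputs$bg_service)
  records <- tibble::as_tibble(as.data.frame(mat))
  records$doctor_first <- as.logical(records$doctor_first)
  structure(
    list(
      records = records,
      last_checkout = max(records$departure),
      busy_minutes = day_busy_minutes(records, config),
      valid = attr(mat, "valid"),
      config = config
    ),
    class = "clinic_day"
  )
}

# Per-resource busy minutes clipped to opening hours, reconstructed from the
# record timestamps. A CTG machine is busy from grant until disconnection
# ends; a midwife additionally covers the scan when she is held by the
# five-or-more-checks rule.
day_busy_minutes <- function(records, cfg) {
  r <- records
  checkin_start <- r$arrival + r$checkin_wait
  checkin_end <- checkin_start + r$checkin_service
  pre_consult_start <- ifelse(r$doctor_first, checkin_end, NA_real_)
  ctg_request <- ifelse(r$doctor_first,
                        checkin_end + r$consult_service, checkin_end)
  machine_grant <- ctg_request + r$ctg_machine_wait
  connect_start <- machine_grant + r$midwife_connect_wait
  connect_end <- connect_start + r$connect_service
  scan_end <- connect_end + r$scan_service
  disc_start <- scan_end + r$midwife_disconnect_wait
  disc_end <- disc_start + r$disconnect_service
  consult_start <- ifelse(r$doctor_first, pre_consult_start,
                          disc_end + r$doctor_wait)
  consult_end <- consult_start + r$consult_service
  checkout_start <- r$departure - r$checkout_service

  clip <- function(from, to) {
    sum(pmax(0, pmin(to, cfg$close_time) - pmax(from, cfg$open_time)))
  }
  held <- r$n_checks >= 5
  c(
    reception = clip(checkin_start, checkin_end) +
      clip(checkout_start, r$departure),
    midwives = clip(connect_start, connect_end) +
      clip(disc_start, disc_end) +
      sum(ifelse(held,
                 pmax(0, pmin(scan_end, cfg$close_time) -
                        pmax(connect_end, cfg$open_time)), 0)),
    doctors = clip(consult_start, consult_end),
    ctg_machines = clip(machine_grant, disc_end)
  )
}

#' @export
print.clinic_day <- function(x, ...) {
  cat("<clinic_day> ", nrow(x$records), " women, last checkout ",
      format_clock_time(x$last_checkout),
      if (!x$valid) " [INVALID: woman present at horizon]", "\n", sep = "")
  invisible(x)
}

# Fast KPI computation on the engine's record matrix.
day_kpis_from_matrix <- function(mat, close_time) {
  dep <- mat[, "departure"]
  c(
    y1 = nrow(mat),
    y2 = max(dep),
    y3 = mean(mat[, "los"]),
    y4 = mean(pmax(0, dep - close_time)),
    y5 = mean(mat[, "midwife_connect_wait"] +
                mat[, "midwife_disconnect_wait"]),
    y6 = mean(mat[, "doctor_wait"]),
    y7 = mean(mat[, "ctg_machine_wait"] + mat[, "midwife_connect_wait"])
  )
}

#' Compute the seven KPIs of a simulated clinic day
#'
#' The day-level key performance indicators are: Y1 the number of arrivals;
#' Y2 the time the last woman checks out; Y3 mean length of stay; Y4 clinic
#' overrun, the per-woman average of minutes by which checkout exceeds
#' closing time; Y5 mean midwife waiting time (connection wait plus
#' disconnection wait); Y6 mean doctor waiting time; and Y7 mean CTG
#' connection waiting time (machine wait plus midwife connection wait).
#' Y5 and Y7 both include the midwife connection wait — that is how the
#' clinic reports them, so adding the two double-counts that component.
#'
#' @param day A `clinic_day` from [run_clinic_day()], or its `records`
#'   tibble.
#' @param config The day's [clinic_config()]; taken from the `clinic_day`
#'   when omitted.
#' @return A one-row tibble with columns `y1_arrivals`, `y2_last_checkout`,
#'   `y3_mean_los`, `y4_overrun`, `y5_midwife_wait`, `y6_doctor_wait`,
#'   `y7_ctg_connection_wait`.
#' @export
compute_day_kpis <- function(day, config = NULL) {
  if (inherits(day, "clinic_day")) {
    if (is.null(config)) config <- day$config
    records <- day$records
  } else {
    records <- day
  }
  if (is.null(config)) {
    stop("config must be supplied when `day` is a plain records table",
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("empty day: no woman records", call. = FALSE)
  mat <- cbind(
    departure = records$departure, los = records$los,
    midwife_connect_wait = records$midwife_connect_wait,
    midwife_disconnect_wait = records$midwife_disconnect_wait,
    doctor_wait = records$doctor_wait,
    ctg_machine_wait = records$ctg_machine_wait
  )
  k <- day_kpis_from_matrix(mat, config$close_time)
  tibble::tibble(
    y1_arrivals = unname(k["y1"]),
    y2_last_checkout = unname(k["y2"]),
    y3_mean_los = unname(k["y3"]),
    y4_overrun = unname(k["y4"]),
    y5_midwife_wait = unname(k["y5"]),
    y6_doctor_wait = unname(k["y6"]),
    y7_ctg_connection_wait = unname(k["y7"])
  )
}
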