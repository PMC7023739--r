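# Plot helpers for simulated days and capacity scans.

#' Timeline plot of one simulated clinic day
#'
#' One horizontal track per woman showing each service interval; gaps
#' between intervals are waits. The dashed line marks closing time.
#'
#' @param object A `clinic_day` from [run_clinic_day()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clinic_day
#' @export
autoplot.clinic_day <- function(object, ...) {
  r <- object$records
  checkin_start <- r$arrival + r$checkin_wait
  checkin_end <- checkin_start + r$checkin_service
  ctg_request <- ifelse(r$doctor_first, checkin_end + r$consult_service,
                        checkin_end)
  connect_start <- ctg_request + r$ctg_machine_wait + r$midwife_connect_wait
  connect_end <- connect_start + r$connect_service
  scan_end <- connect_end + r$scan_service
  disc_start <- scan_end + r$midwife_disconnect_wait
  disc_end <- disc_start + r$disconnect_service
  consult_start <- ifelse(r$doctor_first, checkin_end,
                          disc_end + r$doctor_wait)
  consult_end <- consult_start + r$consult_service
  segs <- dplyr::bind_rows(
    tibble::tibble(woman = r$woman_id, from = checkin_start,
                   to = checkin_end, activity = "check-in"),
    tibble::tibble(woman = r$woman_id, from = connect_start,
                   to = connect_end, activity = "connect CTG"),
    tibble::tibble(woman = r$woman_id, from = connect_end, to = scan_end,
                   activity = "CTG scan"),
    tibble::tibble(woman = r$woman_id, from = disc_start, to = disc_end,
                   activity = "disconnect CTG"),
    tibble::tibble(woman = r$woman_id, from = consult_start,
                   to = consult_end, activity = "consultation"),
    tibble::tibble(woman = r$woman_id, from = r$departure -
                     r$checkout_service, to = r$departure,
                   activity = "check-out")
  )
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$from / 60, xend = .data$to / 60,
                   y = factor(.data$woman), yend = factor(.data$woman),
                   colour = .data$activity),
      linewidth = 3
    ) +
    ggplot2::geom_vline(xintercept = object$config$close_time / 60,
                        linetype = "dashed") +
    ggplot2::labs(x = "clock time (hours)", y = "woman",
                  colour = "activity") +
    ggplot2::theme_minimal()
}

#' Capacity and length-of-stay overview across combinations
#'
#' Bar chart of the maximum feasible demand per combination, annotated with
#' the mean length of stay at that demand.
#'
#' @param results Output of [optimise_all_combos()].
#' @return A ggplot.
#' @export
plot_capacity_overview <- function(results) {
  df <- build_kpi_table(results)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$label, levels = .data$label),
    y = .data$max_feasible, fill = .data$subgroup_id
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$y3_mean_los)),
                       vjust = -0.4, size = 2.7) +
    ggplot2::labs(x = "configuration", y = "maximum feasible demand (women)",
                  fill = "subgroup",
                  caption = "bar labels: mean length of stay (min) at capacity") +
    ggplot2::theme_minimal()
}

#' Feasibility curve of one capacity scan
#'
#' Trial-mean last-checkout time against demand, with the closing-time
#' constraint marked.
#'
#' @param object A `capacity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capacity_result
#' @export
autoplot.capacity_result <- function(object, ...) {
  df <- object$feasibility
  close_time <- CLINIC_CLOSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arrivals,
                                   y = .data$y2_last_checkout / 60)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$feasible)) +
    ggplot2::geom_hline(yintercept = close_time / 60, linetype = "dashed") +
    ggplot2::labs(x = "demand (women)",
                  y = "trial-mean last checkout (hours)",
                  colour = "feasible") +
    ggplot2::theme_minimal()
}
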