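# Grouping, report tables and configuration comparisons.

GROUP_TABLE <- tibble::tibble(
  group_id = 0:7,
  midwives = c(2L, 3L, 2L, 3L, 2L, 3L, 2L, 3L),
  doctors = c(2L, 2L, 3L, 3L, 2L, 2L, 3L, 3L),
  ctg_machines = c(3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L)
)

SUBGROUP_TABLE <- tibble::tibble(
  subgroup_id = c("a", "b", "c", "d"),
  arrival_pattern = c("All", "Half", "All", "Half"),
  consult_order = c("Mid", "Mid", "Doc", "Doc")
)

#' Attach group and subgroup labels to configuration rows
#'
#' The 32 resource/pathway combinations are reported in eight groups (0-7)
#' defined by the resource triple - 0 is the base case (2 midwives, 2
#' doctors, 3 CTG machines), 1 adds a midwife, 2 a doctor, 3 both, 4 a CTG
#' machine, 5-7 the machine plus staff - and four subgroups: a = All/Mid
#' (the base pathway), b = Half/Mid, c = All/Doc, d = Half/Doc. The mapping
#' is a bijection between combinations and (group, subgroup) pairs.
#'
#' @param df A data frame with columns `arrival_pattern`, `consult_order`,
#'   `midwives`, `doctors`, `ctg_machines`.
#' @return `df` with `group_id`, `subgroup_id` and `label` (e.g. `"0a"`)
#'   columns added; combinations off the reporting lattice get `NA` labels.
#' @export
#' @examples
#' assign_group_labels(tibble::tibble(
#'   arrival_pattern = "Half", consult_order = "Doc",
#'   midwives = 3, doctors = 3, ctg_machines = 4))  # 7d
assign_group_labels <- function(df) {
  out <- df |>
    dplyr::left_join(GROUP_TABLE,
                     by = c("midwives", "doctors", "ctg_machines")) |>
    dplyr::left_join(SUBGROUP_TABLE,
                     by = c("arrival_pattern", "consult_order"))
  out$label <- ifelse(
    is.na(out$group_id) | is.na(out$subgroup_id),
    NA_character_,
    paste0(out$group_id, out$subgroup_id)
  )
  out
}

#' Recover the combination a report label refers to
#'
#' Inverse of [assign_group_labels()] for a single label such as `"0a"` or
#' `"7d"`.
#'
#' @param label A two-character group/subgroup label.
#' @return A one-row tibble with the combination columns.
#' @export
combo_for_label <- function(label) {
  stopifnot(length(label) == 1, nchar(label) == 2)
  gid <- suppressWarnings(as.integer(substr(label, 1, 1)))
  sid <- substr(label, 2, 2)
  g <- GROUP_TABLE[GROUP_TABLE$group_id == gid, ]
  s <- SUBGROUP_TABLE[SUBGROUP_TABLE$subgroup_id == sid, ]
  if (nrow(g) != 1 || nrow(s) != 1) {
    stop("unknown group/subgroup label: '", label, "'", call. = FALSE)
  }
  tibble::tibble(
    arrival_pattern = s$arrival_pattern, consult_order = s$consult_order,
    midwives = g$midwives, doctors = g$doctors,
    ctg_machines = g$ctg_machines
  )
}

#' Render minutes since midnight as HH:MM:SS
#'
#' @param minutes_since_midnight Clock times in decimal minutes, within
#'   `[0, 1440)`.
#' @return Character vector of zero-padded 24-hour times, seconds rounded
#'   to the nearest integer.
#' @export
#' @examples
#' format_clock_time(627.5)  # "10:27:30"
format_clock_time <- function(minutes_since_midnight) {
  x <- minutes_since_midnight
  if (any(is.na(x)) || any(x < 0 | x >= 1440)) {
    stop("clock times must lie in [0, 1440) minutes", call. = FALSE)
  }
  secs <- round(x * 60)
  sprintf("%02d:%02d:%02d", secs %/% 3600L, (secs %% 3600L) %/% 60L,
          secs %% 60L)
}

#' Build the grouped KPI report table
#'
#' Arranges the 32-combination capacity results into the standard report
#' layout: rows ordered 0a ... 7d (base case first), with the input columns,
#' the optimised demand, and each KPI mean with its 95% half-width.
#'
#' @param results The tibble returned by [optimise_all_combos()] (one row
#'   per combination with `label` and KPI columns).
#' @return A tibble ordered by group and subgroup.
#' @export
build_kpi_table <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no capacity results supplied", call. = FALSE)
  }
  if (nrow(results) != 32) {
    stop("expected 32 combination rows, got ", nrow(results), call. = FALSE)
  }
  dplyr::arrange(results, .data$group_id, .data$subgroup_id)
}

#' Format the KPI report table for humans
#'
#' Renders [build_kpi_table()] output with the last-checkout KPI as
#' HH:MM:SS (its half-width in seconds) and the minute-valued KPIs rounded
#' to two decimals, as either a delimited table or Markdown.
#'
#' @param tbl Output of [build_kpi_table()] (or [optimise_all_combos()]).
#' @param format `"csv"` or `"markdown"`.
#' @return A character vector of lines.
#' @export
format_kpi_table <- function(tbl, format = c("csv", "markdown")) {
  format <- match.arg(format)
  tbl <- build_kpi_table(tbl)
  disp <- tibble::tibble(
    config = tbl$label,
    x1 = tbl$arrival_pattern,
    x2 = tbl$consult_order,
    x3 = tbl$midwives,
    x4 = tbl$doctors,
    x5 = tbl$ctg_machines,
    x0_y1 = tbl$max_feasible,
    y2 = paste0(format_clock_time(tbl$y2_last_checkout), " ± ",
                round(tbl$y2_last_checkout_hw * 60), "s")
  )
  for (k in KPI_NAMES[3:7]) {
    disp[[k]] <- sprintf("%.2f ± %.2f", tbl[[k]],
                         tbl[[paste0(k, "_hw")]])
  }
  header <- names(disp)
  cells <- apply(disp, 1L, as.character)
  if (format == "csv") {
    c(paste(header, collapse = ","),
      apply(disp, 1L, paste, collapse = ","))
  } else {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      apply(disp, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |")))
  }
}

#' Compare two configurations KPI by KPI
#'
#' Computes absolute and percentage changes from configuration `a` to
#' configuration `b` with the sign convention "reduction positive":
#' `reduction = a - b` and `pct = 100 * (a - b) / a`. A negative value
#' therefore denotes an increase. Percentages against a zero baseline are
#' `NA`.
#'
#' @param a,b One-row trial summaries (e.g. from [run_trial()] or the rows
#'   of [optimise_all_combos()]).
#' @return A tibble with one row per KPI: `kpi`, `a`, `b`,
#'   `reduction`, `pct_reduction`.
#' @export
#' @examples
#' # mean LoS 102.97 vs 86.06 -> reduction 16.91 min (16.4%)
compare_configurations <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  kpis <- intersect(KPI_NAMES, intersect(names(a), names(b)))
  va <- vapply(kpis, function(k) a[[k]][1], numeric(1))
  vb <- vapply(kpis, function(k) b[[k]][1], numeric(1))
  tibble::tibble(
    kpi = kpis,
    a = unname(va),
    b = unname(vb),
    reduction = unname(va - vb),
    pct_reduction = unname(ifelse(va == 0, NA_real_, 100 * (va - vb) / va))
  )
}
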