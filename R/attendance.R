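# Attendance analysis from printed appointment-count tables.
#
# The clinic's did-not-attend rate is dominated by women giving birth
# before their appointment; the guideline change in 2011 both increased
# demand and made attendance more likely. These helpers reproduce that
# analysis from small period/attended/scheduled count tables.

#' Packaged attendance counts
#'
#' Scheduled and attended appointment counts for the clinic before (2010)
#' and after (2011-2017) the guideline change.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `period,attended,scheduled`.
#' @return A tibble with one row per period.
#' @export
attendance_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "attendance_counts.csv",
                        package = "clinicflow", mustWork = TRUE)
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(period = readr::col_character(),
                            attended = readr::col_integer(),
                            scheduled = readr::col_integer()),
    progress = FALSE
  )
  if (any(out$scheduled <= 0) || any(out$attended < 0) ||
      any(out$attended > out$scheduled)) {
    stop("need 0 <= attended <= scheduled and scheduled > 0", call. = FALSE)
  }
  out
}

#' Attendance proportion per period
#'
#' @param counts A tibble with `attended` and `scheduled` columns (e.g.
#'   [attendance_counts()]).
#' @return `counts` with a `proportion` column added (attended/scheduled).
#' @export
#' @examples
#' attendance_proportion(attendance_counts())  # 0.298 and 0.472
attendance_proportion <- function(counts) {
  if (any(counts$scheduled == 0)) {
    stop("scheduled count of zero", call. = FALSE)
  }
  dplyr::mutate(counts, proportion = .data$attended / .data$scheduled)
}

#' Two-proportion chi-square test on attendance
#'
#' Pearson chi-square on the 2 x 2 attended / not-attended by period table,
#' without continuity correction, with 1 degree of freedom. The statistic
#' equals the squared pooled-variance two-sample z statistic for the
#' difference in proportions.
#'
#' @param counts A two-row tibble with `attended` and `scheduled` columns.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' two_proportion_chi_square(attendance_counts())  # statistic 77.235
two_proportion_chi_square <- function(counts) {
  stopifnot(nrow(counts) == 2)
  tab <- cbind(attended = counts$attended,
               not_attended = counts$scheduled - counts$attended)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: zero margin", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    n = sum(tab)
  )
}

#' Ratio-style percentage change between two counts
#'
#' Expresses the later count as a percentage of the earlier one
#' (`100 * later / earlier`), the convention used when attendance "increased
#' by 436%" from 200 to 872; equal counts give 100%.
#'
#' @param earlier,later Positive counts.
#' @return The ratio as a percentage.
#' @export
#' @examples
#' percent_ratio_change(200, 872)  # 436
percent_ratio_change <- function(earlier, later) {
  if (any(earlier <= 0)) stop("earlier count must be positive", call. = FALSE)
  100 * later / earlier
}

#' Full attendance report
#'
#' Proportions per period, the two-proportion chi-square test, and the
#' ratio-style growth of attended appointments between the first and last
#' period.
#'
#' @param counts A two-row attendance tibble; default the packaged counts.
#' @return A list with elements `proportions`, `test`.
#' @export
attendance_report <- function(counts = attendance_counts()) {
  list(
    proportions = attendance_proportion(counts),
    test = two_proportion_chi_square(counts)
  )
}
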