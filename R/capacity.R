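# Treatment-capacity search: the largest demand a resource/pathway
# combination can serve with the trial-mean last-checkout time at or before
# clinic closing. Feasibility is judged on the trial MEAN of the
# last-checkout KPI, and every demand level is evaluated (no early
# stopping), so sampling noise cannot truncate the scan.

#' Find the maximum treatment capacity of one combination
#'
#' Runs a trial at every demand level in `x0_range` for a fixed
#' resource/pathway combination and returns the largest demand whose
#' trial-mean last-checkout time is at or before closing time. Demand is
#' maximised first; the clinic-overrun KPI at the optimum is reported so
#' that ties between equally feasible policies can be broken toward lower
#' overrun.
#'
#' @param arrival_pattern,consult_order,midwives,doctors,ctg_machines The
#'   combination (X1-X5).
#' @param dists Fitted distribution set.
#' @param n_reps Replications per demand level (>= 100 recommended).
#' @param master_seed Integer master seed, shared by all demand levels.
#' @param x0_range Demand range to scan, default `c(2, 20)`.
#' @param ... Further arguments to [clinic_config()] (e.g. `close_time`).
#' @return A `capacity_result`: list with `combo` (one-row tibble),
#'   `max_feasible` (integer, or `NA` when no level is feasible),
#'   `feasibility` (per-demand tibble of trial summaries with a `feasible`
#'   flag), and `kpis_at_max` (the trial-summary row at the optimum).
#' @export
#' @examples
#' \donttest{
#' dists <- fit_service_distributions()
#' cap <- find_max_treatment_capacity("All", "Mid", 2, 2, 3, dists,
#'                                    n_reps = 200, master_seed = 1)
#' cap$max_feasible
#' }
find_max_treatment_capacity <- function(arrival_pattern, consult_order,
                                        midwives, doctors, ctg_machines,
                                        dists, n_reps = 1000,
                                        master_seed = 1,
                                        x0_range = c(2, 20), ...) {
  levels <- seq.int(x0_range[1], x0_range[2])
  trials <- purrr::map(levels, function(x0) {
    cfg <- clinic_config(
      arrivals = x0, arrival_pattern = arrival_pattern,
      consult_order = consult_order, midwives = midwives,
      doctors = doctors, ctg_machines = ctg_machines, ...
    )
    run_trial(cfg, dists, n_reps = n_reps, master_seed = master_seed)
  })
  trials <- dplyr::bind_rows(trials)
  feasible_levels <- trials$arrivals[trials$feasible]
  max_feasible <- if (length(feasible_levels) == 0) {
    NA_integer_
  } else {
    max(feasible_levels)
  }
  structure(
    list(
      combo = tibble::tibble(
        arrival_pattern = arrival_pattern, consult_order = consult_order,
        midwives = as.integer(midwives), doctors = as.integer(doctors),
        ctg_machines = as.integer(ctg_machines)
      ),
      max_feasible = max_feasible,
      feasibility = trials,
      kpis_at_max = if (!is.na(max_feasible)) {
        trials[trials$arrivals == max_feasible, ]
      }
    ),
    class = "capacity_result"
  )
}

#' @export
print.capacity_result <- function(x, ...) {
  cmb <- x$combo
  cat("<capacity_result> ", cmb$arrival_pattern, "/", cmb$consult_order, " ",
      cmb$midwives, " midwives, ", cmb$doctors, " doctors, ",
      cmb$ctg_machines, " CTGs\n", sep = "")
  if (is.na(x$max_feasible)) {
    cat("  no feasible demand level\n")
  } else {
    cat("  max feasible demand: ", x$max_feasible, " women (mean last",
        " checkout ", format_clock_time(x$kpis_at_max$y2_last_checkout),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a capacity result
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return One row per scanned demand level with the KPI means and the
#'   feasibility flag.
#' @method tidy capacity_result
#' @export
tidy.capacity_result <- function(x, ...) {
  x$feasibility
}

#' One-row summary of a capacity result
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return A one-row tibble: the combination, `max_feasible`, and the KPIs
#'   at the optimum (all `NA` when nothing is feasible).
#' @method glance capacity_result
#' @export
glance.capacity_result <- function(x, ...) {
  out <- x$combo
  out$max_feasible <- x$max_feasible
  if (!is.na(x$max_feasible)) {
    kp <- x$kpis_at_max
    for (k in c(KPI_NAMES, paste0(KPI_NAMES, "_hw"))) out[[k]] <- kp[[k]]
    out$n_reps <- kp$n_reps
  }
  out
}

#' Capacity search over all 32 resource/pathway combinations
#'
#' Applies [find_max_treatment_capacity()] to every combination of the two
#' arrival patterns, two consultation orders, and the 2/3 midwife, 2/3
#' doctor and 3/4 CTG-machine levels, in the group/subgroup order used in
#' the report tables (0a, 0b, ..., 7d).
#'
#' @param dists Fitted distribution set.
#' @param n_reps Replications per demand level.
#' @param master_seed Integer master seed.
#' @param x0_range Demand range to scan.
#' @param ... Further arguments to [clinic_config()].
#' @return A tibble with one row per combination: `group_id`, `subgroup_id`,
#'   `label`, the combination columns, `max_feasible`, and the KPI means and
#'   half-widths at the optimum.
#' @export
optimise_all_combos <- function(dists, n_reps = 1000, master_seed = 1,
                                x0_range = c(2, 20), ...) {
  combos <- enumerate_combos()
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    cmb <- combos[i, ]
    cap <- find_max_treatment_capacity(
      cmb$arrival_pattern, cmb$consult_order, cmb$midwives, cmb$doctors,
      cmb$ctg_machines, dists, n_reps = n_reps, master_seed = master_seed,
      x0_range = x0_range, ...
    )
    out <- glance(cap)
    out$group_id <- cmb$group_id
    out$subgroup_id <- cmb$subgroup_id
    out$label <- cmb$label
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("group_id", "subgroup_id", "label")),
                  dplyr::everything())
}

# the 32 combinations in report order
enumerate_combos <- function() {
  enumerate_factorial_configurations(x0_range = c(2, 2)) |>
    dplyr::select(-dplyr::all_of("arrivals"))
}
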