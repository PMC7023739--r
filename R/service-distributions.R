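#' Elicited service-time summary statistics
#'
#' Loads the packaged table of pooled staff estimates describing each clinic
#' activity: minimum, median, mean, maximum, standard deviation, kurtosis and
#' skewness of its duration in decimal minutes (the CTG check row is a count,
#' not a duration). These summaries are the sole data the simulator needs;
#' no patient-level timings exist for the clinic.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`activity,min,median,mean,max,sd,kurtosis,skewness`).
#' @return A tibble with one row per activity and the eight summary columns.
#' @export
#' @examples
#' service_time_summaries()
service_time_summaries <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "service_time_summaries.csv",
                        package = "clinicflow", mustWork = TRUE)
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      activity = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_summaries(out)
  out
}

validate_summaries <- function(df) {
  required <- c("activity", "min", "median", "mean", "max", "sd",
                "kurtosis", "skewness")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("summary table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ok <- row$min <= row$median && row$median <= row$max &&
      row$min <= row$mean && row$mean <= row$max && row$sd >= 0
    if (!ok) {
      stop("invalid summary row for '", row$activity,
           "': need min <= median,mean <= max and sd >= 0", call. = FALSE)
    }
    if (row$sd == 0 && row$min < row$max) {
      stop("invalid summary row for '", row$activity,
           "': sd = 0 requires min = max", call. = FALSE)
    }
  }
  invisible(df)
}

new_service_dist <- function(activity, family, lo, hi, shape1 = NA_real_,
                             shape2 = NA_real_, pmf = NULL, mean, sd, source) {
  structure(
    list(
      activity = activity, family = family,
      support_lo = lo, support_hi = hi,
      shape1 = shape1, shape2 = shape2,
      pmf = pmf, mean = mean, sd = sd,
      source = source
    ),
    class = "service_dist"
  )
}

#' Fit a bounded service-time distribution by moment matching
#'
#' Fits a four-parameter (scaled) Beta distribution on `[min, max]` whose
#' analytic mean and standard deviation equal the elicited summary's, the
#' standard construction for expert-elicited bounded durations. The elicited
#' median, skewness and kurtosis are not fitting targets; they can be compared
#' against the fit with [distribution_diagnostics()]. A degenerate summary
#' with `min == max` yields a point mass.
#'
#' The moment pair is feasible on a bounded support only when
#' `sd^2 < (mean - min) * (max - mean)`; an infeasible pair is an error.
#'
#' @param summary A one-row data frame (or list) with elements `activity`,
#'   `min`, `mean`, `max`, `sd` (other summary columns are carried along as
#'   diagnostics).
#' @return A `service_dist` object.
#' @export
#' @examples
#' row <- dplyr::filter(service_time_summaries(), activity == "Connect CTG")
#' fit_bounded_service_distribution(row)
fit_bounded_service_distribution <- function(summary) {
  summary <- as.list(summary)
  lo <- summary$min
  hi <- summary$max
  mu <- summary$mean
  sigma <- summary$sd

  if (lo == hi) {
    return(new_service_dist(summary$activity, "point-mass", lo, hi,
                            mean = lo, sd = 0, source = summary))
  }
  if (sigma == 0) {
    stop("summary for '", summary$activity,
         "' has sd = 0 on a non-degenerate support", call. = FALSE)
  }
  if (sigma^2 >= (mu - lo) * (hi - mu)) {
    stop("infeasible moments for '", summary$activity,
         "': sd^2 = ", signif(sigma^2, 6),
         " must be below (mean - min)*(max - mean) = ",
         signif((mu - lo) * (hi - mu), 6), call. = FALSE)
  }

  shapes <- beta_shapes_from_moments(lo, hi, mu, sigma)
  new_service_dist(summary$activity, "bounded-continuous", lo, hi,
                   shape1 = shapes[[1]], shape2 = shapes[[2]],
                   mean = mu, sd = sigma, source = summary)
}

# Closed-form Beta shapes on [lo, hi] with the given mean and sd:
# with m = (mu - lo)/(hi - lo) and v = (sigma/(hi - lo))^2,
#   alpha = m * (m (1 - m) / v - 1),  beta = (1 - m) * (m (1 - m) / v - 1).
beta_shapes_from_moments <- function(lo, hi, mu, sigma) {
  m <- (mu - lo) / (hi - lo)
  v <- (sigma / (hi - lo))^2
  nu <- m * (1 - m) / v - 1
  list(shape1 = m * nu, shape2 = (1 - m) * nu)
}

#' Fit the CTG check-count distribution
#'
#' The number of CTG checks during a scan is a count on `{0, ..., max}`. A
#' scaled Beta is first matched to the elicited mean and standard deviation,
#' then discretised by assigning each integer the Beta mass of its rounding
#' cell and renormalising. The resulting mass function keeps strictly
#' positive probability at five or more checks, so the rule that a midwife
#' stays with a woman needing five or more checks remains reachable.
#'
#' @param summary A one-row data frame (or list) for the check-count row;
#'   `min`, `mean`, `max`, `sd` are interpreted as counts.
#' @return A `service_dist` object with family `"discrete-count"` (or
#'   `"point-mass"` for a degenerate row).
#' @export
fit_ctg_check_count_distribution <- function(summary) {
  summary <- as.list(summary)
  lo <- summary$min
  hi <- summary$max
  if (lo == hi) {
    return(new_service_dist(summary$activity, "point-mass", lo, hi,
                            mean = lo, sd = 0, source = summary))
  }
  cont <- fit_bounded_service_distribution(summary)
  k <- seq(floor(lo), ceiling(hi))
  upper <- (pmin(k + 0.5, hi) - lo) / (hi - lo)
  lower <- (pmax(k - 0.5, lo) - lo) / (hi - lo)
  pmf <- pbeta(upper, cont$shape1, cont$shape2) -
    pbeta(lower, cont$shape1, cont$shape2)
  pmf <- pmf / sum(pmf)
  names(pmf) <- k
  mean_d <- sum(k * pmf)
  sd_d <- sqrt(sum(k^2 * pmf) - mean_d^2)
  new_service_dist(summary$activity, "discrete-count", floor(lo), ceiling(hi),
                   shape1 = cont$shape1, shape2 = cont$shape2,
                   pmf = pmf, mean = mean_d, sd = sd_d, source = summary)
}

#' Fit every activity distribution from a summary table
#'
#' Applies [fit_bounded_service_distribution()] to the six duration rows and
#' [fit_ctg_check_count_distribution()] to the check-count row, returning the
#' complete distribution set the simulation engine consumes.
#'
#' @param summaries A summary tibble, by default [service_time_summaries()].
#' @return A named list of `service_dist` objects with names `check_in`,
#'   `connect_ctg`, `ctg_scan`, `disconnect_ctg`, `consultation`,
#'   `check_out`, `n_ctg_checks`.
#' @export
#' @examples
#' dists <- fit_service_distributions()
#' dists$ctg_scan
fit_service_distributions <- function(summaries = service_time_summaries()) {
  validate_summaries(summaries)
  out <- lapply(ACTIVITY_KEYS, function(key) {
    label <- ACTIVITY_LABELS[[key]]
    row <- summaries[summaries$activity == label, ]
    if (nrow(row) != 1) {
      stop("expected exactly one summary row for '", label, "'", call. = FALSE)
    }
    if (key == "n_ctg_checks") {
      fit_ctg_check_count_distribution(row)
    } else {
      fit_bounded_service_distribution(row)
    }
  })
  setNames(out, ACTIVITY_KEYS)
}

#' Quantile function of a fitted service distribution
#'
#' Maps uniforms to the fitted scale by inversion; used by the engine so that
#' a replication's uniform draws are reusable across configurations (common
#' random numbers).
#'
#' @param dist A `service_dist`.
#' @param u Uniform(0,1) values.
#' @return Durations in minutes (or integer counts for a discrete fit).
#' @export
quantile_service <- function(dist, u) {
  stopifnot(inherits(dist, "service_dist"))
  switch(dist$family,
    "point-mass" = rep(dist$support_lo, length(u)),
    "bounded-continuous" = dist$support_lo +
      (dist$support_hi - dist$support_lo) * qbeta(u, dist$shape1, dist$shape2),
    "discrete-count" = {
      k <- as.integer(names(dist$pmf))
      k[findInterval(u, cumsum(dist$pmf), left.open = TRUE) + 1L]
    },
    stop("unknown family: ", dist$family, call. = FALSE)
  )
}

#' Draw service times from a fitted distribution
#'
#' Draws are made by inversion from R's active random-number stream, so a
#' fixed seed reproduces the sequence exactly.
#'
#' @param dist A `service_dist`.
#' @param n Number of draws.
#' @return A numeric vector of length `n`, always within the support.
#' @export
#' @examples
#' set.seed(1)
#' sample_service_time(fit_service_distributions()$connect_ctg, 5)
sample_service_time <- function(dist, n = 1) {
  quantile_service(dist, runif(n))
}

#' Compare a fitted distribution against its source summary
#'
#' Reports the analytic mean and standard deviation of the fit (exact by
#' construction, up to the discretisation step for counts) next to the
#' elicited values, plus Monte-Carlo estimates of the median, skewness and
#' excess-free kurtosis, which the moment-matching construction does not
#' constrain.
#'
#' @param dist A `service_dist`.
#' @param n_mc Monte-Carlo sample size for the unconstrained moments.
#' @return A one-row tibble of diagnostics; deviation columns are fit minus
#'   source. Higher-moment columns are `NA` for a point mass.
#' @export
distribution_diagnostics <- function(dist, n_mc = 1e5) {
  stopifnot(inherits(dist, "service_dist"))
  src <- dist$source
  if (dist$family == "point-mass") {
    mc_median <- dist$support_lo
    mc_skew <- NA_real_
    mc_kurt <- NA_real_
  } else {
    x <- sample_service_time(dist, n_mc)
    mc_median <- stats::median(x)
    z <- (x - mean(x)) / sd(x)
    mc_skew <- mean(z^3)
    mc_kurt <- mean(z^4)
  }
  tibble::tibble(
    activity = dist$activity,
    family = dist$family,
    support_lo = dist$support_lo,
    support_hi = dist$support_hi,
    mean_fit = dist$mean,
    mean_source = src$mean,
    mean_dev = dist$mean - src$mean,
    sd_fit = dist$sd,
    sd_source = src$sd,
    sd_dev = dist$sd - src$sd,
    median_mc = mc_median,
    median_source = src$median,
    skewness_mc = mc_skew,
    skewness_source = src$skewness,
    kurtosis_mc = mc_kurt,
    kurtosis_source = src$kurtosis
  )
}

#' @export
print.service_dist <- function(x, ...) {
  cat("<service_dist> ", x$activity, " [", x$family, "]\n", sep = "")
  cat("  support: [", x$support_lo, ", ", x$support_hi, "]\n", sep = "")
  if (x$family == "bounded-continuous") {
    cat("  Beta shapes: ", signif(x$shape1, 5), ", ", signif(x$shape2, 5),
        "\n", sep = "")
  }
  cat("  mean ", signif(x$mean, 6), ", sd ", signif(x$sd, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted service distribution
#'
#' @param x A `service_dist`.
#' @param ... Unused.
#' @return A one-row tibble of the distribution's parameters.
#' @method tidy service_dist
#' @export
tidy.service_dist <- function(x, ...) {
  tibble::tibble(
    activity = x$activity,
    family = x$family,
    support_lo = x$support_lo,
    support_hi = x$support_hi,
    shape1 = x$shape1,
    shape2 = x$shape2,
    mean = x$mean,
    sd = x$sd
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Plot a fitted service distribution against its support
#'
#' Density curve for continuous fits, mass function for discrete ones; the
#' elicited mean is marked.
#'
#' @param object A `service_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot service_dist
#' @export
autoplot.service_dist <- function(object, ...) {
  if (object$family == "discrete-count") {
    df <- tibble::tibble(x = as.integer(names(object$pmf)),
                         p = as.numeric(object$pmf))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$p)) +
      ggplot2::geom_col(width = 0.8, fill = "steelblue") +
      ggplot2::labs(x = "count", y = "probability")
  } else if (object$family == "point-mass") {
    df <- tibble::tibble(x = object$support_lo, p = 1)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$p)) +
      ggplot2::geom_col(width = 0.05) +
      ggplot2::labs(x = "minutes", y = "probability")
  } else {
    xs <- seq(object$support_lo, object$support_hi, length.out = 301)
    scale <- object$support_hi - object$support_lo
    dens <- dbeta((xs - object$support_lo) / scale,
                  object$shape1, object$shape2) / scale
    df <- tibble::tibble(x = xs, d = dens)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$d)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "minutes", y = "density")
  }
  p +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::ggtitle(object$activity) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
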