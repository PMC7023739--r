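test_that("packaged summary table matches the elicited values", {
  s <- service_time_summaries()
  expect_equal(nrow(s), 7)
  connect <- s[s$activity == "Connect CTG", ]
  expect_equal(unlist(connect[c("min", "median", "mean", "max", "sd")]),
               c(min = 2.000, median = 3.341, mean = 3.410, max = 5.000,
                 sd = 0.863))
  scan <- s[s$activity == "CTG Scan", ]
  expect_equal(c(scan$min, scan$max), c(20, 45))
  checkout <- s[s$activity == "Check out", ]
  expect_equal(c(checkout$min, checkout$mean, checkout$max),
               c(0.130, 1.589, 5.000))
  # round-trips through an on-disk copy exactly
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s, tmp)
  expect_equal(as.data.frame(service_time_summaries(tmp)), as.data.frame(s))
})

test_that("moment matching recovers every elicited mean and sd", {
  s <- service_time_summaries()
  dists <- fit_service_distributions(s)
  for (key in setdiff(names(dists), "n_ctg_checks")) {
    d <- dists[[key]]
    src <- d$source
    expect_equal(d$mean, src$mean, tolerance = 1e-6)
    expect_equal(d$sd, src$sd, tolerance = 1e-3)
    # analytic Beta moments, recomputed from the shapes, agree too
    ab <- d$shape1 + d$shape2
    mu <- d$support_lo + (d$support_hi - d$support_lo) * d$shape1 / ab
    sig <- (d$support_hi - d$support_lo) *
      sqrt(d$shape1 * d$shape2 / (ab^2 * (ab + 1)))
    expect_equal(mu, src$mean, tolerance = 1e-9)
    expect_equal(sig, src$sd, tolerance = 1e-9)
  }
})

test_that("consultation shapes agree with an independent numeric solver", {
  row <- as.list(service_time_summaries()[5, ])
  expect_equal(row$activity, "Consultation")
  d <- fit_bounded_service_distribution(row)
  # brute-force solve of the two moment equations on the unit interval
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    m <- a / (a + b)
    v <- a * b / ((a + b)^2 * (a + b + 1))
    mu <- row$min + (row$max - row$min) * m
    sig <- (row$max - row$min) * sqrt(v)
    (mu - row$mean)^2 + (sig - row$sd)^2
  }
  sol <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 500))
  expect_lt(sol$value, 1e-10)
  expect_equal(exp(sol$par[1]), d$shape1, tolerance = 1e-6)
  expect_equal(exp(sol$par[2]), d$shape2, tolerance = 1e-6)
})

test_that("infeasible moment pairs raise a fitting error naming the bound", {
  bad <- list(activity = "too-wide", min = 0, median = 5, mean = 5, max = 10,
              sd = 5.001, kurtosis = 0, skewness = 0)
  expect_error(fit_bounded_service_distribution(bad), "mean - min")
  # boundary case: sd^2 exactly equal to (mean-min)(max-mean) also fails
  boundary <- modifyList(bad, list(sd = 5))
  expect_error(fit_bounded_service_distribution(boundary), "infeasible")
  # just inside the bound succeeds
  ok <- modifyList(bad, list(sd = 4.999))
  expect_s3_class(fit_bounded_service_distribution(ok), "service_dist")
  expect_error(
    fit_bounded_service_distribution(
      list(activity = "flat", min = 1, median = 2, mean = 2, max = 3, sd = 0)
    ),
    "sd = 0"
  )
})

test_that("degenerate summaries collapse to point masses", {
  d <- fit_bounded_service_distribution(
    list(activity = "fixed", min = 5, median = 5, mean = 5, max = 5, sd = 0)
  )
  expect_equal(d$family, "point-mass")
  expect_equal(sample_service_time(d, 10), rep(5, 10))
  dc <- fit_ctg_check_count_distribution(
    list(activity = "fixed count", min = 3, median = 3, mean = 3, max = 3,
         sd = 0)
  )
  expect_equal(dc$family, "point-mass")
  expect_equal(sample_service_time(dc, 5), rep(3, 5))
})

test_that("check-count fit honours the elicited moments and the >=5 rule", {
  d <- fit_service_distributions()$n_ctg_checks
  expect_equal(d$family, "discrete-count")
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
  expect_equal(as.integer(names(d$pmf)), 0:10)
  expect_equal(d$mean, 2.120, tolerance = 0.01)
  expect_equal(d$sd, 1.462, tolerance = 0.05)
  expect_gt(sum(d$pmf[as.integer(names(d$pmf)) >= 5]), 0)
  set.seed(7)
  x <- sample_service_time(d, 2e4)
  expect_true(all(x == floor(x) & x >= 0 & x <= 10))
  expect_gt(mean(x >= 5), 0)
})

test_that("sampling is support-bounded and seed-deterministic", {
  dists <- fit_service_distributions()
  for (d in dists) {
    set.seed(11)
    x <- sample_service_time(d, 1e4)
    expect_true(all(x >= d$support_lo & x <= d$support_hi))
    set.seed(11)
    expect_identical(sample_service_time(d, 1e4), x)
  }
  # inversion is monotone in the uniform
  u <- seq(0.01, 0.99, by = 0.01)
  q <- quantile_service(dists$consultation, u)
  expect_true(all(diff(q) > 0))
})

test_that("diagnostics report supports, exact means and the free moments", {
  dists <- fit_service_distributions()
  set.seed(3)
  dg <- distribution_diagnostics(dists$check_out, n_mc = 2e4)
  expect_equal(c(dg$support_lo, dg$support_hi), c(0.130, 5.000))
  expect_lt(abs(dg$mean_dev), 1e-6)
  expect_true(is.finite(dg$skewness_mc) && is.finite(dg$kurtosis_mc))
  pm <- distribution_diagnostics(point_dist(5))
  expect_true(is.na(pm$skewness_mc) && is.na(pm$kurtosis_mc))
  expect_equal(pm$sd_fit, 0)
  td <- tidy(dists$connect_ctg)
  expect_equal(td$mean, 3.410)
  expect_equal(td$family, "bounded-continuous")
})
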