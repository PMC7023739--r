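# Deterministic schedule checks use point-mass service times at the
# elicited activity means, frozen against hand-computed event lists.

test_that("one woman with ample resources reproduces the no-wait pathway", {
  day <- run_clinic_day(ample_config(1), point_mass_dists())
  r <- day$records
  waits <- unlist(r[grepl("_wait$", names(r))])
  expect_equal(unname(waits), rep(0, length(waits)))
  expect_equal(r$los, ZERO_CONTENTION_LOS)
  expect_equal(r$departure, 480 + 57.441)
  expect_true(day$valid)
})

test_that("two women through single-server stations match the hand schedule", {
  cfg <- clinic_config(arrivals = 2, arrival_pattern = "All",
                       consult_order = "Mid", midwives = 1, doctors = 1,
                       ctg_machines = 1)
  day <- run_clinic_day(cfg, point_mass_dists())
  r <- day$records
  # woman 1 sails through: departs 480 + 57.441
  expect_equal(r$departure[1], 537.441)
  expect_equal(r$los[1], 57.441)
  # woman 2 waits 0.457 at check-in, then the machine for woman 1's whole
  # connect+scan+disconnect makespan, less her own later queue entry
  expect_equal(r$checkin_wait[2], 0.457)
  expect_equal(r$ctg_machine_wait[2], (3.410 + 26.250 + 3.410) - 0.457)
  expect_equal(r$midwife_connect_wait[2], 0)
  expect_equal(r$doctor_wait[2], 0)
  expect_equal(r$departure[2], 570.511)
  expect_equal(r$los[2], 90.511)
})

test_that("doctor-first pathway matches the hand schedule", {
  cfg <- clinic_config(arrivals = 2, arrival_pattern = "All",
                       consult_order = "Doc", midwives = 1, doctors = 1,
                       ctg_machines = 1)
  day <- run_clinic_day(cfg, point_mass_dists())
  r <- day$records
  # woman 1 takes the idle doctor straight after check-in; woman 2 finds
  # the doctor busy, follows the midwife-first path, and grabs the machine
  # while woman 1 is still in consultation
  expect_equal(r$doctor_first, c(TRUE, FALSE))
  expect_equal(r$doctor_wait, c(0, 0))
  expect_equal(r$ctg_machine_wait, c(11.202, 0))
  expect_equal(r$departure, c(548.643, 537.898))
  expect_equal(r$los, c(68.643, 57.898))
})

test_that("length of stay equals the sum of recorded intervals", {
  dists <- fitted_dists
  set.seed(101)
  for (cfg in list(clinic_config(arrivals = 9),
                   clinic_config(arrivals = 12, arrival_pattern = "Half",
                                 consult_order = "Doc"),
                   clinic_config(arrivals = 5, midwives = 3, doctors = 3,
                                 ctg_machines = 4))) {
    day <- run_clinic_day(cfg, dists)
    r <- day$records
    parts <- r$checkin_wait + r$checkin_service + r$ctg_machine_wait +
      r$midwife_connect_wait + r$connect_service + r$scan_service +
      r$midwife_disconnect_wait + r$disconnect_service + r$doctor_wait +
      r$consult_service + r$checkout_wait + r$checkout_service
    expect_equal(r$los, parts, tolerance = 1e-9)
    expect_equal(r$los, r$departure - r$arrival, tolerance = 1e-12)
    expect_true(all(r[grepl("_wait$|_service$", names(r))] >= 0))
  }
})

test_that("every scheduled woman attends and departs exactly once", {
  set.seed(202)
  day <- run_clinic_day(clinic_config(arrivals = 14), fitted_dists)
  r <- day$records
  expect_equal(nrow(r), 14)
  expect_equal(sort(r$woman_id), 1:14)
  expect_true(all(is.finite(r$departure)))
  expect_equal(day$last_checkout, max(r$departure))
})

test_that("queues are first-in first-out per resource class", {
  set.seed(303)
  for (i in 1:5) {
    cfg <- clinic_config(arrivals = 10,
                         consult_order = sample(c("Mid", "Doc"), 1))
    r <- run_clinic_day(cfg, fitted_dists)$records
    # CTG machine queue: entry when check-in (or the doctor-first
    # consultation) completes; grant after the recorded machine wait
    entry <- r$arrival + r$checkin_wait + r$checkin_service +
      ifelse(r$doctor_first, r$consult_service, 0)
    grant <- entry + r$ctg_machine_wait
    ord <- order(entry, r$woman_id)
    expect_true(all(diff(grant[ord]) >= -1e-9))
    # doctor queue among midwife-first women: entry at disconnection end
    mid_first <- !r$doctor_first
    if (sum(mid_first) > 1) {
      entry_d <- (entry + r$ctg_machine_wait + r$midwife_connect_wait +
                    r$connect_service + r$scan_service +
                    r$midwife_disconnect_wait +
                    r$disconnect_service)[mid_first]
      grant_d <- entry_d + r$doctor_wait[mid_first]
      ord_d <- order(entry_d, r$woman_id[mid_first])
      expect_true(all(diff(grant_d[ord_d]) >= -1e-9))
    }
  }
})

test_that("ample resources eliminate every wait", {
  set.seed(404)
  for (i in 1:20) {
    day <- run_clinic_day(ample_config(6), fitted_dists)
    waits <- day$records[grepl("_wait$", names(day$records))]
    expect_equal(unname(unlist(waits)), rep(0, 6 * 6))
    expect_equal(day$records$los,
                 rowSums(day$records[grepl("_service$", names(day$records))]))
  }
})

test_that("a midwife is held through the scan for five or more checks", {
  cfg <- clinic_config(arrivals = 2, midwives = 1, doctors = 2,
                       ctg_machines = 2)
  svc <- jittered_services(2)
  # woman 1 needs 5+ checks: the single midwife stays through her scan, so
  # woman 2 cannot be connected until woman 1's disconnection ends
  day <- run_clinic_day(cfg, dists = NULL, service_times = svc,
                        n_checks = c(5L, 2L))
  r <- day$records
  expect_equal(r$midwife_disconnect_wait[1], 0)
  # woman 1 occupies the midwife for connect + scan + disconnect; woman 2
  # joins the midwife queue her own check-in duration later
  w1_busy <- svc[1, 2] + svc[1, 3] + svc[1, 4]
  expect_equal(r$midwife_connect_wait[2], w1_busy - r$checkin_service[2],
               tolerance = 1e-9)
  # with fewer than 5 checks the midwife is released during the scan
  day2 <- run_clinic_day(cfg, dists = NULL, service_times = svc,
                         n_checks = c(2L, 2L))
  expect_lt(day2$records$midwife_connect_wait[2], w1_busy)
})

test_that("days overrunning the horizon are flagged invalid", {
  cfg <- clinic_config(arrivals = 15, midwives = 1, doctors = 1,
                       ctg_machines = 1, open_time = 480, close_time = 500,
                       horizon = 600)
  set.seed(505)
  day <- run_clinic_day(cfg, fitted_dists)
  expect_false(day$valid)
  expect_gt(day$last_checkout, 600)
})

test_that("day KPIs implement the trial-average definitions", {
  set.seed(606)
  cfg <- clinic_config()
  day <- run_clinic_day(cfg, fitted_dists)
  k <- compute_day_kpis(day)
  r <- day$records
  expect_equal(k$y1_arrivals, 7)
  expect_equal(k$y2_last_checkout, max(r$departure))
  expect_equal(k$y3_mean_los, mean(r$los))
  expect_equal(k$y5_midwife_wait,
               mean(r$midwife_connect_wait + r$midwife_disconnect_wait))
  expect_equal(k$y7_ctg_connection_wait,
               mean(r$ctg_machine_wait + r$midwife_connect_wait))
  if (k$y4_overrun > 0) expect_gt(k$y2_last_checkout, cfg$close_time)

  # overrun is a per-woman average of late minutes: one woman 5 min late
  # among 7 gives 5/7
  recs <- day$records
  recs$departure <- rep(600, 7)
  recs$departure[3] <- 635
  recs$los <- recs$departure - recs$arrival
  k2 <- compute_day_kpis(recs, cfg)
  expect_equal(k2$y4_overrun, 5 / 7)

  expect_error(compute_day_kpis(recs[0, ], cfg), "empty")
})

test_that("resource busy time stays within capacity and opening hours", {
  set.seed(707)
  day <- run_clinic_day(clinic_config(arrivals = 10), fitted_dists)
  busy <- day$busy_minutes
  window <- 630 - 480
  caps <- c(reception = 1, midwives = 2, doctors = 2, ctg_machines = 3)
  expect_true(all(busy >= 0))
  expect_true(all(busy <= caps[names(busy)] * window + 1e-9))
})
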