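test_that("baseline zone is mean +/- 3 SD with window guards", {
  set.seed(1)
  v <- rnorm(40, 0.5, 0.02)
  z <- baseline_zone(v)
  expect_equal(z$mean, mean(v))
  expect_equal(z$half_width, 3 * sd(v))
  expect_equal(c(z$lower, z$upper), c(mean(v) - 3 * sd(v), mean(v) + 3 * sd(v)))
  expect_error(baseline_zone(rnorm(9)), "at least 10")
  expect_error(baseline_zone(rep(0.5, 20)), "zero SD")
})

make_timeline <- function(acf, step = 5) {
  tibble::tibble(window = seq_along(acf),
                 t_center = step * seq_along(acf), acf = acf)
}

test_that("loss and recovery timing follows the window-center convention", {
  zone <- tibble::tibble(mean = 0.5, half_width = 0.15,
                         lower = 0.35, upper = 0.65)
  # exits at the first post-onset window (t = 65), back in from t = 75
  tl <- make_timeline(c(rep(0.5, 12), 0.9, rep(0.5, 12)))
  r <- measure_response(tl, zone, onset = 60, offset = 62)
  expect_equal(r$loss_time, 5)  # 65 - 60
  expect_equal(r$recovery_time, 8)  # dwell run starts at t = 70
  expect_false(r$loss_censored || r$recovery_censored)
})

test_that("never leaving the zone means censored loss and zero recovery", {
  zone <- tibble::tibble(mean = 0.5, half_width = 0.3, lower = 0.2,
                         upper = 0.8)
  tl <- make_timeline(rep(0.5, 30))
  r <- measure_response(tl, zone, onset = 60, offset = 65)
  expect_true(r$loss_censored)
  expect_equal(r$recovery_time, 0)
  expect_false(r$recovery_censored)
})

test_that("dwell requirement suppresses single-window false recoveries", {
  zone <- tibble::tibble(mean = 0, half_width = 0.5, lower = -0.5,
                         upper = 0.5)
  acf <- c(rep(0, 12), 0.9, 0.9, 0, 0.9, 0, 0, 0, 0, 0)
  tl <- make_timeline(acf)
  r3 <- measure_response(tl, zone, onset = 60, offset = 70, dwell = 3)
  # dwell 3: the isolated in-zone window at t = 75 does not count;
  # recovery starts at t = 85 (t_center of window 17)
  expect_equal(r3$recovery_time, 15)
  r1 <- measure_response(tl, zone, onset = 60, offset = 70, dwell = 1)
  expect_equal(r1$recovery_time, 5)
  expect_lt(r1$recovery_time, r3$recovery_time)
})

test_that("recovery censors when the ACF never re-enters", {
  zone <- tibble::tibble(mean = 0, half_width = 0.1, lower = -0.1,
                         upper = 0.1)
  tl <- make_timeline(c(rep(0, 12), rep(0.9, 10)))
  r <- measure_response(tl, zone, onset = 60, offset = 65)
  expect_false(r$loss_censored)
  expect_true(r$recovery_censored)
  expect_error(measure_response(tl, zone, onset = -5, offset = 300),
               "outside the ACF timeline")
})

test_that("missing windows count as out-of-zone and break dwell runs", {
  zone <- tibble::tibble(mean = 0.5, half_width = 0.2, lower = 0.3,
                         upper = 0.7)
  acf <- c(rep(0.5, 12), NA, rep(0.5, 8))
  tl <- make_timeline(acf)
  r <- measure_response(tl, zone, onset = 60, offset = 62, dwell = 2)
  expect_equal(r$loss_time, 5)  # the NA window at t = 65
  expect_equal(r$recovery_time, 8)  # first full in-zone pair starts t = 70
})

test_that("longer horizons never lose uncensored recoveries", {
  # deterministic ACF path: out of zone until t = 120, in-zone after
  zone <- tibble::tibble(mean = 0, half_width = 0.2, lower = -0.2,
                         upper = 0.2)
  full <- c(rep(0, 12), rep(1, 12), rep(0, 20))
  short <- make_timeline(full[1:28])
  long <- make_timeline(full)
  rs <- measure_response(short, zone, 60, 65)
  rl <- measure_response(long, zone, 60, 65)
  expect_false(rl$recovery_censored)
  expect_true(rl$recovery_time <= max(long$t_center))
  expect_equal(rs$recovery_time, rl$recovery_time)
})

test_that("experiment rows are reproducible and summaries guarded", {
  topo <- test_topology(n = 20, links = 40, seed = 3)
  ss <- c("0" = 0.9, "1" = 2)
  ex1 <- suppressWarnings(
    run_es_experiment(topo, z_grid = c(0, 1), n_realizations = 3,
                      baseline = 60, horizon = 30, s_star = ss, seed = 77))
  ex2 <- suppressWarnings(
    run_es_experiment(topo, z_grid = c(0, 1), n_realizations = 3,
                      baseline = 60, horizon = 30, s_star = ss, seed = 77))
  expect_identical(tidy(ex1), tidy(ex2))
  expect_true(all(c("kurtosis", "loss_time", "recovery_time") %in%
                  names(tidy(ex1))))
  # 6 rows: per-row output intact, summary refused
  expect_null(glance(ex1))
  expect_equal(nrow(tidy(ex1)), 6)
})
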