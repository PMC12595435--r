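test_that("order parameter matches hand-computed configurations", {
  n <- 200
  same <- matrix(0.7, n, 5)
  expect_equal(as.numeric(order_parameter(same, 100)), rep(1, n))
  anti <- cbind(rep(0, n), rep(pi, n))
  expect_equal(as.numeric(order_parameter(anti, 100)), rep(0, n),
               tolerance = 1e-12)
  quad <- matrix(rep(c(0, pi / 2, pi, 3 * pi / 2), each = n), n)
  expect_equal(as.numeric(order_parameter(quad, 100)), rep(0, n),
               tolerance = 1e-12)
  expect_error(order_parameter(matrix(0, 10, 1), 100), "at least 2")
})

test_that("PCF equals N-scaled temporal variance", {
  r <- op_series(rep(c(0.4, 0.6), 100), 100, 100)
  expect_equal(pcf(r), 1.0)
  expect_equal(pcf(op_series(rep(0.5, 200), 10, 50)), 0)
  set.seed(1)
  x <- runif(500)
  expect_equal(pcf(x, n_oscillators = 37), oracle_pcf(x, 37),
               tolerance = 1e-12)
  expect_error(pcf(op_series(rep(0.3, 50), 10, 10)), "at least")
})

test_that("Pearson kurtosis matches moment-ratio oracle and bounds", {
  expect_equal(kurtosis_pearson(rep(c(-1, 1), 10)), 1)
  x10 <- c(rep(0, 8), 1, -1)
  expect_equal(kurtosis_pearson(x10), 5)  # hand: m4/m2^2 = 0.2/0.04
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(50 + i)
    expect_equal(kurtosis_pearson(x), oracle_kurtosis(x), tolerance = 1e-12)
    expect_gte(kurtosis_pearson(x), 1)
  }
  set.seed(3)
  big <- rnorm(2e5)
  expect_lt(abs(kurtosis_pearson(big) - 3), 0.1)
  expect_error(kurtosis_pearson(rep(1, 10)), "zero variance")
  expect_error(kurtosis_pearson(c(1, 2, 3)), "at least 4")
})

test_that("windowed ACF agrees with the direct-sum oracle per window", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.8), 3000))
  w <- windowed_acf(x, sampling_rate = 100, window_length = 2, step = 1,
                    lag = 10)
  starts <- seq(1, length(x) - 200 + 1, by = 100)
  manual <- sapply(starts, function(s) oracle_acf_lag(x[s:(s + 199)], 10))
  expect_equal(w$acf, manual, tolerance = 1e-10)
  expect_true(all(abs(w$acf) <= 1))
})

test_that("windowed ACF edge behaviour: lag 0, periodic input, guards", {
  x <- sin(2 * pi * 10 * seq(0, 20, by = 1e-3))
  w0 <- windowed_acf(x, sampling_rate = 1000, window_length = 2, step = 1,
                     lag = 0)
  expect_true(all(abs(w0$acf - 1) < 1e-12))
  # lag = one full period of a pure sinusoid
  wp <- windowed_acf(x, sampling_rate = 1000, window_length = 2, step = 1,
                     lag = 100)
  expect_true(all(wp$acf > 0.9))
  expect_error(windowed_acf(x, sampling_rate = 1000, window_length = 0.1,
                            step = 0.05, lag = 100), "window too short")
  expect_error(windowed_acf(x[1:3000], sampling_rate = 1000,
                            window_length = 4, step = 2, lag = 10),
               "too short for 2 windows")
  # zero-variance windows are recorded missing, excluded from kurtosis
  y <- c(rep(0, 1000), rnorm(3000))
  wz <- windowed_acf(y, sampling_rate = 100, window_length = 5, step = 5,
                     lag = 3)
  expect_true(any(!is.finite(wz$acf)))
  expect_true(is.finite(attr(wz, "kurtosis")))
})

test_that("white-noise window ACFs have near-Gaussian kurtosis", {
  set.seed(5)
  x <- rnorm(60000)
  w <- windowed_acf(x, sampling_rate = 100, window_length = 5, step = 0.5,
                    lag = 50)
  expect_gt(attr(w, "n_windows"), 1000)
  expect_lt(abs(attr(w, "kurtosis") - 3), 0.3)
  expect_lt(abs(mean(w$acf)), 0.02)
})

test_that("critical-point finder takes the peak with documented tie-break", {
  sw <- tibble::tibble(s = c(1, 2, 3), pcf = c(1, 5, 2))
  expect_equal(find_critical_point(sw)$s_star, 2)
  tie <- tibble::tibble(s = c(1, 2, 3), pcf = c(2, 5, 5))
  expect_equal(find_critical_point(tie)$s_star, 2)
  ends <- tibble::tibble(s = 1:3, pcf = c(6, 5, 2))
  expect_true(find_critical_point(ends)$endpoint)
  flat <- tibble::tibble(s = 1:4, pcf = rep(2, 4))
  expect_true(find_critical_point(flat)$flat)
  expect_error(find_critical_point(tibble::tibble(s = 1:2, pcf = 1:2)),
               "at least 3")
  # per-realization rows are averaged before the argmax
  reps <- tibble::tibble(s = rep(1:3, each = 2),
                         pcf = c(1, 1, 9, 1, 2, 2))
  expect_equal(find_critical_point(reps)$s_star, 2)
})

test_that("DFA recovers known scaling exponents", {
  # average a few independent realizations: the single-series estimator
  # has sampling SD ~ 0.03 at this length
  set.seed(6)
  wn <- mean(replicate(5, hurst_dfa(rnorm(8000))))
  expect_lt(abs(wn - 0.5), 0.05)
  bm <- mean(replicate(5, hurst_dfa(cumsum(rnorm(8000)))))
  expect_lt(abs(bm - 1.5), 0.12)
  fgn <- mean(sapply(7:11, function(s) hurst_dfa(make_fgn(8000, 0.8, s))))
  expect_lt(abs(fgn - 0.8), 0.07)
  expect_error(hurst_dfa(rnorm(500)), "at least 1000")
  expect_error(hurst_dfa(c(rnorm(2000), NA)), "nonfinite")
})

test_that("DFA matches the naive per-box lm oracle", {
  set.seed(8)
  x <- rnorm(3000)
  boxes <- c(10, 20, 40, 80, 160)
  expect_equal(hurst_dfa(x, box_sizes = boxes), oracle_dfa(x, boxes),
               tolerance = 1e-10)
})

test_that("Spearman correlation matches rank oracle and hand case", {
  expect_equal(rank_correlation(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_equal(rank_correlation(1:6, exp(1:6))$rho, 1)
  expect_equal(rank_correlation(1:6, -(1:6)^3)$rho, -1)
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(rank_correlation(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-10)
  }
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:4, 1:4))
})
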