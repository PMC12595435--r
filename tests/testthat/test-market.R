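test_that("collapse/recovery formulas match the worked example exactly", {
  px <- tibble::tibble(date = as.Date("2008-01-01") + 0:3,
                       price = c(100, 60, 50, 90))
  mt <- collapse_recovery_rates(px, px$date[1], px$date[3], alpha = 1)
  expect_equal(mt$r1, 0.8, tolerance = 1e-14)
  expect_equal(mt$r2, 0.8, tolerance = 1e-14)
  expect_equal(mt$response_time, log(1.25), tolerance = 1e-14)
  expect_equal(mt$recovery_time, log(1.25), tolerance = 1e-14)
})

test_that("formula endpoints: full collapse and zero recovery", {
  px <- tibble::tibble(date = as.Date("2008-01-01") + 0:3,
                       price = c(100, 50, 50, 50))
  full <- collapse_recovery_rates(px, px$date[1], px$date[2], alpha = 1)
  expect_equal(full$r1, 1)
  expect_equal(full$response_time, 0)
  expect_equal(full$r2, 0)
  expect_true(is.na(full$recovery_time))  # log domain edge flagged missing
})

test_that("negative rates keep values but drop times", {
  px <- tibble::tibble(date = as.Date("2008-01-01") + 0:3,
                       price = c(100, 120, 50, 40))
  mt <- collapse_recovery_rates(px, px$date[1], px$date[3], alpha = 1)
  expect_lt(mt$r1, 0)
  expect_true(is.na(mt$response_time))
  expect_lt(mt$r2, 0)
  expect_true(is.na(mt$recovery_time))
})

test_that("rates and times are invariant to price rescaling", {
  set.seed(20)
  px <- tibble::tibble(date = as.Date("2007-01-01") + 0:299,
                       price = 100 * exp(cumsum(rnorm(300, 0, 0.02))))
  ext <- locate_extrema(px, "2007-03-01", "2007-08-01")
  a <- collapse_recovery_rates(px, ext$t_max, ext$t_min, alpha = 40)
  px2 <- dplyr::mutate(px, price = price * 7.31)
  b <- collapse_recovery_rates(px2, ext$t_max, ext$t_min, alpha = 40)
  expect_equal(a$r1, b$r1, tolerance = 1e-12)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  expect_equal(a$response_time, b$response_time, tolerance = 1e-12)
})

test_that("extrema location handles monotone and V-shaped windows", {
  d <- as.Date("2008-01-01") + 0:99
  mono <- tibble::tibble(date = d, price = seq(100, 1, length.out = 100))
  e1 <- locate_extrema(mono, d[1], d[100])
  expect_equal(e1$t_max, d[1])
  expect_equal(e1$t_min, d[100])
  expect_true(e1$is_crash)
  vee <- tibble::tibble(date = d, price = c(seq(100, 50, length.out = 50),
                                            seq(51, 100, length.out = 50)))
  e2 <- locate_extrema(vee, d[1], d[100])
  expect_equal(e2$t_min, d[50])
  rising <- tibble::tibble(date = d, price = seq(1, 100, length.out = 100))
  expect_false(locate_extrema(rising, d[1], d[100])$is_crash)
  expect_error(locate_extrema(mono, "2012-01-01", "2012-02-01"),
               "no trading days")
})

test_that("guards: alpha overrun and flat market", {
  px <- tibble::tibble(date = as.Date("2008-01-01") + 0:9,
                       price = c(100, 90, 80, 70, 60, 50, 55, 60, 65, 70))
  expect_error(collapse_recovery_rates(px, px$date[1], px$date[6],
                                       alpha = 10), "overruns")
  flat <- tibble::tibble(date = px$date, price = rep(100, 10))
  expect_error(collapse_recovery_rates(flat, flat$date[1], flat$date[5],
                                       alpha = 2), "flat market")
})

test_that("market_es_proximity recovers i.i.d. Gaussian null near 3", {
  set.seed(21)
  n <- 2200
  px <- tibble::tibble(date = as.Date("2005-01-01") + seq_len(n),
                       market_id = "M1",
                       price = 100 * exp(cumsum(rnorm(n, 0, 0.01))))
  est <- market_es_proximity(px, px$date[1], px$date[n],
                             window_length = 60, step = 2)
  expect_equal(est$mode, "index")
  expect_lt(abs(est$kurtosis - 3), 0.8)
})

test_that("market_es_proximity guards degenerate inputs", {
  n <- 300
  px <- tibble::tibble(date = as.Date("2006-01-01") + seq_len(n),
                       market_id = "M1", price = rep(100, n))
  expect_error(market_es_proximity(px, px$date[1], px$date[n]), "constant")
  short <- tibble::tibble(date = as.Date("2006-01-01") + 1:100,
                          market_id = "M1",
                          price = exp(cumsum(rnorm(100, 0, 0.01))))
  expect_error(market_es_proximity(short, short$date[1], short$date[100]),
               "at least 150")
})

test_that("lag-0 market ACF is degenerate and flagged via missing kurtosis", {
  set.seed(22)
  n <- 400
  px <- tibble::tibble(date = as.Date("2005-01-01") + seq_len(n),
                       market_id = "M1",
                       price = 100 * exp(cumsum(rnorm(n, 0, 0.01))))
  est <- market_es_proximity(px, px$date[1], px$date[n], lag = 0)
  expect_true(is.na(est$kurtosis))  # all window ACFs exactly 1
})
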