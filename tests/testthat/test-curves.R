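test_that("background subtraction is per-timepoint control-mean subtraction", {
  # control identical to treatment -> all zeros
  tp <- c(0, 12, 24, 36)
  same <- dplyr::bind_rows(
    tibble::tibble(sample = "t1", group = "trt", time_h = tp, value = c(1, 5, 9, 9)),
    tibble::tibble(sample = "c1", group = "PBS", time_h = tp, value = c(1, 5, 9, 9))
  )
  expect_true(all(subtract_background(same, "PBS")$value == 0))

  # constant control offset b shifts treatment by -b
  off <- dplyr::bind_rows(
    tibble::tibble(sample = "t1", group = "trt", time_h = tp, value = c(10, 20, 30, 40)),
    tibble::tibble(sample = "c1", group = "PBS", time_h = tp, value = 7)
  )
  expect_equal(subtract_background(off, "PBS")$value, c(3, 13, 23, 33))

  # random matrices match independent per-column arithmetic
  set.seed(21)
  tp <- seq(0, 96, by = 8)
  rnd <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ tibble::tibble(sample = paste0("t", .x), group = "trt",
                                         time_h = tp, value = runif(length(tp), 0, 100))),
    purrr::map_dfr(1:3, ~ tibble::tibble(sample = paste0("c", .x), group = "PBS",
                                         time_h = tp, value = runif(length(tp), 0, 10)))
  )
  got <- subtract_background(rnd, "PBS")
  bg <- tapply(rnd$value[rnd$group == "PBS"], rnd$time_h[rnd$group == "PBS"], mean)
  manual <- rnd$value[rnd$group == "trt"] -
    bg[as.character(rnd$time_h[rnd$group == "trt"])]
  expect_equal(got$value, as.vector(manual))
  # negative results are kept, not clipped
  neg <- dplyr::bind_rows(
    tibble::tibble(sample = "t1", group = "trt", time_h = tp, value = 0),
    tibble::tibble(sample = "c1", group = "PBS", time_h = tp, value = 5)
  )
  expect_true(all(subtract_background(neg, "PBS")$value == -5))
})

test_that("central difference is exact for lines and quadratics, and linear", {
  t <- c(0, 1, 2.5, 4, 7)
  expect_equal(central_difference(t, 3 * t + 2), rep(3, 5))
  expect_equal(central_difference(0:2, (0:2)^2)[2], 2)  # y = t^2 at t = 1

  # brute-force index arithmetic on random input
  set.seed(3)
  y <- rnorm(9); tt <- sort(runif(9, 0, 10))
  d <- central_difference(tt, y)
  for (i in 2:8) expect_equal(d[i], (y[i + 1] - y[i - 1]) / (tt[i + 1] - tt[i - 1]))
  expect_equal(d[1], (y[2] - y[1]) / (tt[2] - tt[1]))
  expect_equal(d[9], (y[9] - y[8]) / (tt[9] - tt[8]))

  # linearity: d(a*y1 + b*y2) = a*d(y1) + b*d(y2)
  y2 <- rnorm(9)
  expect_equal(central_difference(tt, 2 * y - 5 * y2),
               2 * central_difference(tt, y) - 5 * central_difference(tt, y2))
})

test_that("production stop is the first negative interior derivative", {
  tp <- seq(0, 168, by = 12)
  expect_true(is.na(production_stop_time(tp, 2^(tp / 24))))  # monotone rise
  # rise to a peak at day 4, then decline -> day 4 at grid resolution
  y <- pmin(tp, 96) - pmax(0, tp - 96)
  expect_equal(production_stop_time(tp, y), 108 / 24, tolerance = 0.51)
  # noise-free generated curves recover the programmed stop exactly at grid
  # resolution, for several programmed stops
  for (stopd in c(2, 4, 5)) {
    cur <- generate_synthetic_curves(n_samples = 1, n_background = 1,
                                     stop_time_days = stopd, noise_sd = 0,
                                     seed = 1)
    one <- subset(cur, group == "BS-GFP")
    got <- production_stop_time(one$time_h, one$value)
    expect_lte(abs(got - stopd), 12 / 24)  # within one sampling interval
  }
})

test_that("noisy synthetic curves still localise the programmed stop", {
  # at plate-reader-like noise, >= 90% of seeds land within one interval
  hits <- vapply(1:20, function(s) {
    cur <- generate_synthetic_curves(n_samples = 1, n_background = 1,
                                     noise_sd = 100, seed = s)
    one <- subset(cur, group == "BS-GFP")
    got <- production_stop_time(one$time_h, one$value)
    !is.na(got) && abs(got - 4) <= 12 / 24
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("log-log rate constant recovers power-law exponents", {
  tp <- seq(2, 50, by = 4)
  # f(t) = A t^k exactly -> slope k for any A > 0
  for (k in c(0.5, 1, 2)) {
    df <- tibble::tibble(sample = "a", group = "g", time_h = tp,
                         value = 7.3 * tp^k)
    expect_equal(glance(rate_constant(df))$rate_constant, k, tolerance = 1e-10)
  }
  # two samples -> mean of the two slopes
  df2 <- dplyr::bind_rows(
    tibble::tibble(sample = "a", group = "g", time_h = tp, value = tp^1),
    tibble::tibble(sample = "b", group = "g", time_h = tp, value = tp^3)
  )
  rc <- rate_constant(df2)
  expect_equal(rc$rate_constant, 2, tolerance = 1e-10)
  expect_equal(sort(tidy(rc)$slope), c(1, 3), tolerance = 1e-10)

  # invariance under positive scaling of all values
  df3 <- dplyr::mutate(df2, value = value * 1234)
  expect_equal(rate_constant(df3)$rate_constant, rc$rate_constant,
               tolerance = 1e-10)

  # noisy ensemble with known exponent: mean within 5%
  noisy <- generate_power_law_curves(n_samples = 8, exponent = 0.8,
                                     noise_sd = 0.05, seed = 4)
  expect_equal(glance(rate_constant(noisy))$rate_constant, 0.8,
               tolerance = 0.05)

  # non-positive values are excluded and reported
  dfz <- tibble::tibble(sample = "a", group = "g", time_h = tp,
                        value = c(-1, 0, (7.3 * tp^2)[-(1:2)]))
  rcz <- rate_constant(dfz)
  expect_equal(rcz$n_excluded, 2)
  expect_equal(rcz$rate_constant, 2, tolerance = 0.05)
})

test_that("doubling-time fits recover programmed kinetics", {
  t <- seq(0, 600, by = 10)
  # exact exponential growth: Td recovered exactly, scale-invariant
  for (td in c(20, 30, 60)) {
    y <- 0.01 * 2^(t / td)
    expect_equal(glance(fit_doubling_time(t, y))$doubling_time, td,
                 tolerance = 1e-8)
    expect_equal(glance(fit_doubling_time(t, 50 * y))$doubling_time, td,
                 tolerance = 1e-8)
  }
  # logistic-like saturating curve with noise: mid-exponential fit within 10%
  set.seed(12)
  K <- 1; y0 <- 1e-3; r <- log(2) / 30
  y <- K * y0 * exp(r * t) / (K + y0 * (exp(r * t) - 1))
  y <- y * exp(rnorm(length(t), sd = 0.03))
  expect_equal(glance(fit_doubling_time(t, y))$doubling_time, 30,
               tolerance = 0.1)
})

test_that("the synthetic generator is reproducible and structurally sound", {
  a <- generate_synthetic_curves(seed = 99)
  b <- generate_synthetic_curves(seed = 99)
  expect_identical(a, b)
  c2 <- generate_synthetic_curves(seed = 100)
  expect_false(identical(a, c2))

  # noise 0: smooth analytic curve, background group flat at the offset
  sm <- generate_synthetic_curves(noise_sd = 0, seed = 1)
  bg <- subset(sm, group == "PBS")
  expect_true(all(bg$value == 500))
  # round trip: subtract background, then stop time and ensemble statistics
  sub <- subtract_background(sm, "PBS")
  st <- curve_stats(sub)
  expect_equal(st$stop_time_days, 4, tolerance = 0.51)
  expect_equal(st$n_not_reached, 0)
  expect_s3_class(tidy(st), "tbl_df")
  expect_s3_class(plot_curves(sm), "ggplot")
})

test_that("curve tables validate and round-trip through CSV", {
  bad <- tibble::tibble(sample = "a", group = "g", time_h = 1:2, value = 1:2)
  expect_error(fluorescence_curves(bad), "3 timepoints")
  ragged <- dplyr::bind_rows(
    tibble::tibble(sample = "a", group = "g", time_h = 1:4, value = 1),
    tibble::tibble(sample = "b", group = "g", time_h = 1:3, value = 1)
  )
  expect_error(fluorescence_curves(ragged), "same timepoint grid")

  cur <- generate_synthetic_curves(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(cur, path)
  expect_equal(as.data.frame(read_curves_csv(path)), as.data.frame(cur),
               tolerance = 1e-12)
})
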