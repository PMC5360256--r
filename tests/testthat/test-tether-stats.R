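test_that("exact binomial intervals match a root-finding oracle", {
  expect_equal(clopper_pearson(0, 20)[1], 0)
  expect_equal(clopper_pearson(20, 20)[2], 1)
  # independent oracle: invert the binomial tail probabilities numerically
  lo_oracle <- uniroot(function(p) 1 - pbinom(2, 10, p) - 0.16,
                       c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  hi_oracle <- uniroot(function(p) pbinom(3, 10, p) - 0.16,
                       c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  ci <- clopper_pearson(3, 10)
  expect_equal(ci[1], lo_oracle, tolerance = 1e-8)
  expect_equal(ci[2], hi_oracle, tolerance = 1e-8)
})

test_that("binned proportions carry exact intervals and bin statistics", {
  t_lysis <- c(12, 15, 18, 23, 27, 55)
  has_fc <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  bins <- bin_proportions(t_lysis, has_fc, bin_width = 10)
  expect_equal(nrow(bins), 3) # empty bins omitted
  expect_equal(bins$n, c(3, 2, 1))
  expect_equal(bins$p_fc, c(1 / 3, 1, 1))
  expect_equal(bins$t_mean[1], mean(c(12, 15, 18)))
  expect_equal(bins$t_sd[1], sd(c(12, 15, 18)))
  expect_equal(bins$ci_hi[2], 1)
  allzero <- bin_proportions(rep(5, 20), rep(FALSE, 20))
  expect_equal(allzero$ci_lo, 0)
  expect_equal(allzero$p_fc, 0)
})

test_that("trend regression is exact on collinear bins", {
  bins <- data.frame(t_mean = c(10, 20, 30, 40),
                     p_fc = 0.1 + 0.0077 * c(10, 20, 30, 40))
  tr <- linear_trend(bins)
  expect_equal(tr$slope, 0.0077, tolerance = 1e-12)
  flat <- data.frame(t_mean = c(10, 20, 30), p_fc = rep(0.4, 3))
  expect_equal(linear_trend(flat)$slope, 0)
  expect_error(linear_trend(flat[1:2, ]), "3 bins")
})

test_that("event rates reproduce printed values at printed precision", {
  r1 <- event_rate(53, 221)
  expect_equal(round(r1$rate, 3), 0.240)
  expect_equal(round(r1$se, 3), 0.033)
  r2 <- event_rate(19, 238)
  expect_equal(round(r2$rate, 3), 0.080)
  expect_equal(round(r2$se, 3), 0.018)
  r0 <- event_rate(0, 100)
  expect_equal(c(r0$rate, r0$se), c(0, 0))
  expect_error(event_rate(3.5, 100), "integer")
})

test_that("the exact Poisson rate test matches enumeration and symmetry", {
  expect_equal(poisson_rate_test(7, 100, 7, 100), 1)
  expect_equal(poisson_rate_test(0, 10, 0, 10), 1)
  # printed comparison of the two vesicle-free conditions
  expect_equal(poisson_rate_test(19, 238, 11, 200), 0.42, tolerance = 0.05)
  # exhaustive enumeration oracle for all N <= 12
  enum_p <- function(n1, T1, n2, T2) {
    N <- n1 + n2
    p0 <- T1 / (T1 + T2)
    probs <- dbinom(0:N, N, p0)
    lower <- sum(probs[seq_len(n1 + 1)])
    upper <- sum(probs[(n1 + 1):(N + 1)])
    min(1, 2 * min(lower, upper))
  }
  for (N in 0:12) for (n1 in 0:N) {
    for (Ts in list(c(1, 1), c(2, 1), c(238, 200))) {
      expect_equal(poisson_rate_test(n1, Ts[1], N - n1, Ts[2]),
                   enum_p(n1, Ts[1], N - n1, Ts[2]), tolerance = 1e-12)
    }
  }
})

test_that("step histograms bin correctly and conserve counts", {
  h <- step_histogram(4.5)
  expect_equal(h$count[h$center == 3.75], 1) # 4.5 falls in [2.5, 5.0)
  expect_equal(sum(h$count), 1)
  h0 <- step_histogram(numeric(0))
  expect_true(all(h0$count == 0))
  expect_equal(h0$center[1], -8.75)
  expect_equal(h0$center[length(h0$center)], 48.75)
  # boundary membership is half-open
  hb <- step_histogram(c(2.5, 5.0 - 1e-9))
  expect_equal(hb$count[hb$center == 3.75], 2)
  # conservation and agreement with analytic bin probabilities
  set.seed(3)
  x <- rnorm(1000, 4.5, 3.1)
  h <- step_histogram(x)
  expect_equal(sum(h$count), attr(h, "n_in_range"))
  expect_equal(attr(h, "n_in_range"), sum(x >= -10 & x < 50))
  p <- pnorm(h$center + 1.25, 4.5, 3.1) - pnorm(h$center - 1.25, 4.5, 3.1)
  expect_true(all(abs(h$count - 1000 * p) <=
                    3 * sqrt(1000 * p * (1 - p)) + 1))
})

test_that("Gaussian peak fitting recovers exact-model histograms", {
  centers <- seq(-8.75, 48.75, by = 2.5)
  counts <- 80 * exp(-(centers - 4.5)^2 / (2 * 3.1^2))
  h <- structure(data.frame(center = centers, count = counts,
                            count_error = sqrt(counts)),
                 class = c("step_histogram", "data.frame"))
  attr(h, "width") <- 2.5
  fit <- fit_gaussian_peak(h)
  expect_lt(abs(fit$dz_peak - 4.5), 0.01)
  expect_lt(abs(fit$sd_peak - 3.1), 0.01)
  single <- h; single$count <- c(10, rep(0, length(centers) - 1))
  expect_error(fit_gaussian_peak(single), "4 non-zero")
})

test_that("correlation behaves and flags degenerate input", {
  x <- c(1, 3, 7, 9)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, rep(2, 4)), "zero variance")
  set.seed(17)
  expect_lt(abs(pearson_correlation(runif(500), runif(500))), 0.1)
})

test_that("unfolding arithmetic reproduces the helix extension estimates", {
  expect_equal(helix_extension(1), 0.215)
  expect_equal(helix_extension(25), 5.375) # prints as 5.4
  expect_equal(helix_extension(40), 8.6)
  expect_equal(helix_extension(0), 0)
  expect_error(helix_extension(-1), "non-negative")
  expect_equal(unfolded_contour(6216), 2268.84) # ~2.3 um
  expect_equal(unfolded_contour(1), 0.365)
  expect_equal(unfolded_contour(23), 8.395)
  expect_equal(camera_pixel_size(16, 100), 160)
})
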