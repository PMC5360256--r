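test_that("forward intensity model follows the exponential decay", {
  fld <- evanescent_field(I0 = 400, d_tirf = 102, I_background = 100)
  expect_equal(intensity_at_height(fld, 0), 400)
  expect_equal(intensity_at_height(fld, 102), 400 / exp(1))
  expect_equal(intensity_at_height(fld, 141), 400 * exp(-141 / 102))
  expect_lt(abs(intensity_at_height(fld, 141) - 100.3), 0.1)
  z <- seq(0, 500, by = 10)
  expect_true(all(diff(intensity_at_height(fld, z)) < 0))
  expect_error(intensity_at_height(fld, -1), "negative")
})

test_that("intensity-ratio inversion recovers height changes", {
  expect_equal(delta_z_tirf(300, 300, 100, 102)[1], 0)
  expect_equal(delta_z_tirf(100 + exp(1) * 50, 150, 100, 100)[1], 100)
  expect_equal(delta_z_tirf(500, 200, 100, 102)[1], 102 * log(4))
  out <- delta_z_tirf(500, c(200, 100, 90), 100, 102)
  expect_true(is.na(out[2]) && is.na(out[3]))
  expect_identical(attr(out, "out_of_field"), c(FALSE, TRUE, TRUE))
})

test_that("round trip through forward model and inversion is exact", {
  fld <- evanescent_field(I0 = 350, d_tirf = 97, I_background = 80)
  b <- fld$I_background
  for (zi in c(0, 5, 50, 200, 5 * 97)) {
    for (zf in c(0, 13, 97, 333, 5 * 97)) {
      dz <- delta_z_tirf(intensity_at_height(fld, zi) + b,
                         intensity_at_height(fld, zf) + b, b, fld$d_tirf)
      expect_equal(dz[1], zf - zi, tolerance = 1e-12)
    }
  }
})

test_that("theoretical decay length matches physics and the printed value", {
  d <- theoretical_decay_length(488, 66.8, 1.515, 1.33)
  expect_equal(round(d), 94)
  # independent route via the imaginary transmitted-angle cosine
  oracle <- function(lam, th, n1, n2) {
    sin_t <- n1 * sin(th * pi / 180) / n2
    lam / (4 * pi * n2 * sqrt(sin_t^2 - 1))
  }
  for (th in c(63, 66.8, 70, 80))
    expect_equal(theoretical_decay_length(488, th, 1.515, 1.33),
                 oracle(488, th, 1.515, 1.33), tolerance = 1e-9)
  # decay length shrinks with steeper illumination, grows toward critical
  expect_lt(theoretical_decay_length(488, 70), theoretical_decay_length(488, 66.8))
  crit <- asin(1.33 / 1.515) * 180 / pi
  expect_gt(theoretical_decay_length(488, crit + 1e-4), 1e4)
  expect_error(theoretical_decay_length(488, crit - 0.1), "critical")
})

test_that("decay-length calibration recovers the generating constant", {
  z <- seq(0, 500, by = 5)
  exact <- list(data.frame(z = z, I = 400 * exp(-z / 100) + 50))
  cal <- calibrate_decay_length(exact)
  expect_equal(cal$d_tirf, 100, tolerance = 1e-6)
  expect_equal(cal$n, 1)
  # noisy recovery within 2 aggregate SDs across seeded realizations
  set.seed(11)
  ok <- 0; reps <- 100
  for (r in 1:reps) {
    apps <- lapply(1:5, function(i)
      data.frame(z = z, I = (400 * exp(-z / 102) + 100) *
                   (1 + rnorm(length(z), 0, 0.03))))
    cal <- calibrate_decay_length(apps)
    if (abs(cal$d_tirf - 102) <= 2 * cal$sd) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
  # non-monotonic series are screened out and reported
  bad <- data.frame(z = z, I = 200 + 100 * sin(z / 30))
  cal <- calibrate_decay_length(c(exact, list(bad)))
  expect_equal(cal$n, 1)
  expect_equal(cal$excluded$series, 2)
  expect_error(calibrate_decay_length(list()), "no approach")
  expect_error(calibrate_decay_length(list(bad)), "excluded")
})

test_that("ROI extraction averages the 3x3 window", {
  frames <- array(10, dim = c(9, 9, 4))
  tr <- roi_mean_intensity(frames, c(4, 4))
  expect_equal(tr$intensity, rep(10, 4))
  frames[] <- 0
  expect_equal(roi_mean_intensity(frames, c(4, 4))$intensity, rep(0, 4))
  frames[3, 3, ] <- 90  # pixel (x=2, y=2) in 0-based coordinates
  expect_equal(roi_mean_intensity(frames, c(3, 3))$intensity, rep(10, 4))
  expect_error(roi_mean_intensity(frames, c(0, 4)), "clipped")
})

test_that("paired servo/TIRF traces separate tether from tip-link stretch", {
  fld <- evanescent_field(I0 = 400, d_tirf = 100, I_background = 100)
  tt <- seq(0, 20, by = 0.1)
  z_true <- pmin(20 * tt, 300)   # vesicle follows the servo rigidly
  tr <- structure(data.frame(time = tt,
                             intensity = intensity_at_height(fld, z_true) +
                               fld$I_background),
                  class = c("intensity_trace", "data.frame"))
  cmp <- compare_extension_traces(tt, z_true, tr, fld)
  expect_lt(max(abs(cmp$difference)), 1e-9)
  # tip-link stretch: servo moves but vesicle stays put
  tr0 <- structure(data.frame(time = tt,
                              intensity = rep(400 + 100, length(tt))),
                   class = c("intensity_trace", "data.frame"))
  cmp <- compare_extension_traces(tt, z_true, tr0, fld)
  expect_lt(max(abs(cmp$dz_tirf)), 1e-9)
  expect_equal(cmp$difference, cmp$dz_servo)
  # vesicle out of the wave: flagged non-finite, servo still reported
  trout <- structure(data.frame(time = tt,
                                intensity = c(rep(500, 100),
                                              rep(100, length(tt) - 100))),
                     class = c("intensity_trace", "data.frame"))
  cmp <- compare_extension_traces(tt, z_true, trout, fld)
  expect_true(all(is.na(cmp$dz_tirf[101:length(tt)])))
  expect_true(all(is.finite(cmp$dz_servo)))
  expect_error(compare_extension_traces(tt + 100, z_true, tr, fld),
               "overlap")
})
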