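test_that("a noiseless single-exponential transient is characterised accurately", {
  tr <- make_transient_trace(t_event = 3, amp = 0.1, tau = 0.05)
  det <- detect_transients(tr$times, tr$v, baseline = 0)
  expect_equal(nrow(det), 1)
  expect_equal(det$tau, 0.05, tolerance = 0.02)
  expect_equal(det$t_start, 3, tolerance = 2e-3)
  expect_equal(det$v_max, 0.1, tolerance = 1e-3)
  expect_equal(det$shape, "unitary")
  expect_gt(det$fit_quality, 0.999)
})

test_that("flat traces yield no transients", {
  tt <- seq(0, 10, by = 1e-3)
  expect_equal(nrow(detect_transients(tt, rep(0.2, length(tt)),
                                      baseline = 0.2)), 0)
  set.seed(2)
  noisy <- rnorm(length(tt), 0, 0.002)
  det <- detect_transients(tt, noisy, baseline = 0, noise_sd = 0.002)
  expect_lte(nrow(det), 1) # at most rare chance crossings
  expect_error(detect_transients(tt[tt < 1.5], noisy[tt < 1.5], baseline = 0),
               "shorter")
})

test_that("well-separated transients stay distinct, overlapping ones merge", {
  tau <- 0.05
  tr <- make_transient_trace(t_event = 3, amp = 0.1, tau = tau)
  on <- tr$times >= 3 + 10 * tau
  tr$v[on] <- tr$v[on] + 0.08 * exp(-(tr$times[on] - 3 - 10 * tau) / tau)
  det <- detect_transients(tr$times, tr$v, baseline = 0)
  expect_equal(nrow(det), 2)
  expect_lt(det$t_start[1], det$t_start[2])
  expect_equal(det$shape, c("unitary", "unitary"))
  # peaks closer than 3 tau without baseline return form one complex event
  tr2 <- make_transient_trace(t_event = 3, amp = 0.1, tau = tau)
  on <- tr2$times >= 3 + 1.5 * tau
  tr2$v[on] <- tr2$v[on] + 0.09 * exp(-(tr2$times[on] - 3 - 1.5 * tau) / tau)
  det2 <- detect_transients(tr2$times, tr2$v, baseline = 0)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$shape, "complex")
  expect_gte(det2$n_peaks, 2)
})

test_that("two-line step estimation is exact on noiseless traces", {
  cases <- expand.grid(h = c(7, 0, 501), a = c(0, 2), b = c(0, -1.5))
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    tr <- make_step_trace(h = cs$h, slope_before = cs$a, slope_after = cs$b)
    dz <- measure_step(tr$times, tr$z, t_start = 5, t_end = 5.1)
    expect_equal(as.numeric(dz), two_line_oracle(cs$h, cs$a, cs$b, 5, 5.1),
                 tolerance = 1e-9)
  }
})

test_that("step estimation tolerates creep and noise", {
  set.seed(13)
  tr <- make_step_trace(h = 7, slope_before = 2, slope_after = 2,
                        noise_sd = 0.5)
  dz <- measure_step(tr$times, tr$z, t_start = 5, t_end = 5.1)
  expect_lt(abs(as.numeric(dz) - two_line_oracle(7, 2, 2, 5, 5.1)), 0.5)
  # window truncation is flagged; too-short windows error
  dz2 <- measure_step(tr$times, tr$z, 5, 5.1, limits = c(4.9, 5.3))
  expect_true(attr(dz2, "truncated"))
  expect_error(measure_step(tr$times, tr$z, 5, 5.1, limits = c(4.999, 5.101)),
               "fewer than")
})

test_that("step estimates are unbiased under Gaussian noise", {
  set.seed(21)
  n <- 200
  errs <- vapply(seq_len(n), function(i) {
    tr <- make_step_trace(h = 7, noise_sd = 0.5, dur = 6, t_start = 3,
                          t_end = 3.1)
    as.numeric(measure_step(tr$times, tr$z, 3, 3.1)) - 7
  }, numeric(1))
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(n))
})

test_that("event typing follows the setpoint-attainment rules", {
  seg <- data.frame(index = 1, t_start = 1, t_end = 13.5, t_reached = 1,
                    reached_setpoint = TRUE)
  tt <- seq(0, 13.5, by = 1e-3)
  setp <- -0.2
  v <- ifelse(tt >= 1, setp, seq(0, setp, length.out = length(tt))[1])
  # FC: transient at t = 6, force resumes afterwards
  v_fc <- v + ifelse(tt >= 6, 0.1 * exp(-(tt - 6) / 0.05), 0)
  tr <- data.frame(t_start = 6, t_vmax = 6.001, t_end = 6.3)
  expect_equal(classify_event_type(tr, seg, tt, v_fc, noise_sd = 0.002), "FC")
  # R: transient before the setpoint was attained
  tr_r <- data.frame(t_start = 0.5, t_vmax = 0.501, t_end = 0.8)
  expect_equal(classify_event_type(tr_r, seg, tt, v_fc, noise_sd = 0.002), "R")
  # F: deflection stays at the free level to the segment end
  v_f <- ifelse(tt < 6, v, 0)
  tr_f <- data.frame(t_start = 6, t_vmax = 6.001, t_end = 6.05)
  expect_equal(classify_event_type(tr_f, seg, tt, v_f, noise_sd = 0.002), "F")
  # classification is total over a mixed set
  all3 <- rbind(tr_r, tr)
  types <- classify_event_type(all3, seg, tt, v_fc, noise_sd = 0.002)
  expect_equal(types, c("R", "FC"))
})

test_that("size classification implements the event taxonomy", {
  expect_equal(classify_shape_and_size("unitary", 7), "S",
               ignore_attr = TRUE)
  expect_equal(classify_shape_and_size("unitary", 1839), "E",
               ignore_attr = TRUE)
  expect_equal(classify_shape_and_size("complex", 501), "C_E",
               ignore_attr = TRUE)
  expect_equal(classify_shape_and_size("complex", 12), "C_S",
               ignore_attr = TRUE)
  # tie at the 50-nm boundary goes to the extended class
  expect_equal(classify_shape_and_size("unitary", 50), "E",
               ignore_attr = TRUE)
  out <- classify_shape_and_size(c("unitary", "complex"), c(NA, 3))
  expect_true(is.na(out[1]))
  expect_identical(attr(out, "unsized"), c(TRUE, FALSE))
})

test_that("clamp duration runs from setpoint attainment to segment end or F", {
  seg <- data.frame(index = 1, t_start = 0.5, t_end = 13,
                    t_reached = 0.5, reached_setpoint = TRUE)
  none <- data.frame(event_type = character(0), t_start = numeric(0),
                     t_end = numeric(0))
  expect_equal(as.numeric(clamp_duration(seg, none)), 12.5)
  fev <- data.frame(event_type = "F", t_start = 8.5, t_end = 8.6)
  expect_equal(as.numeric(clamp_duration(seg, fev)), 8.0)
  rev <- data.frame(event_type = "R", t_start = 0.3, t_end = 1.2)
  expect_equal(as.numeric(clamp_duration(seg, rev)), 11.8)
  unreached <- data.frame(index = 2, t_start = 0, t_end = 13,
                          t_reached = NA, reached_setpoint = FALSE)
  d <- clamp_duration(unreached, none)
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "flag"), "setpoint_not_reached")
  # summed over four default segments the total clamp time is 50 s
  segs <- data.frame(index = 1:4, t_start = c(0.5, 13.2, 25.9, 38.6),
                     t_end = c(13, 25.7, 38.4, 51.1),
                     t_reached = c(0.5, 13.2, 25.9, 38.6),
                     reached_setpoint = TRUE)
  tot <- sum(vapply(1:4, function(i)
    as.numeric(clamp_duration(segs[i, ], none)), numeric(1)))
  expect_equal(tot, 50)
})

test_that("an injected F event truncates the pull and is typed F", {
  cfg <- sim_config(seed = 31, p_f_event = 1, event_rate_short = 0.15,
                    event_rate_long = 0)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  f_true <- gt[gt$event_type == "F", ][1, ]
  res <- analyse_recording(sim)
  fdet <- res$events[res$events$event_type == "F", ]
  expect_gte(nrow(fdet), 1)
  expect_equal(fdet$t_start[1], f_true$true_time, tolerance = 0.05)
  seg <- res$phases$segments[res$phases$segments$index == f_true$segment_index, ]
  dur <- clamp_duration(seg, res$events[res$events$segment_index == seg$index, ])
  expect_lt(as.numeric(dur), seg$nominal_duration)
})
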