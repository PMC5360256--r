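# shared fixtures: all synthetic, generated in code

# analyse a simulated recording end to end (calibrate -> parse -> detect)
analyse_recording <- function(sim) {
  rec <- sim$recording
  sched <- rec$meta$schedule
  app <- sched[sched$phase == "approach", ]
  asel <- rec$times >= app$t_start & rec$times < app$t_end
  drift <- estimate_drift(list(data.frame(z = rec$z_servo[asel],
                                          v = rec$v_defl[asel])))
  rc <- correct_drift(rec, drift$drift)
  ph <- parse_phases(rc)
  list(recording = rc, phases = ph, drift = drift,
       events = detect_events(rc, ph))
}

# did the detector recover a true event at time t?
covers <- function(events, t, slack = 0.05) {
  any(events$t_start - slack <= t & t <= events$t_end + slack)
}

# noiseless single-exponential transient on a flat baseline
make_transient_trace <- function(t_event = 3, amp = 0.1, tau = 0.05,
                                 dur = 10, dt = 1e-3, baseline = 0,
                                 noise_sd = 0) {
  tt <- seq(0, dur, by = dt)
  v <- rep(baseline, length(tt))
  on <- tt >= t_event
  v[on] <- v[on] + amp * exp(-(tt[on] - t_event) / tau)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  list(times = tt, v = v)
}

# piecewise-linear servo trace with a step between t_start and t_end
make_step_trace <- function(h = 7, slope_before = 0, slope_after = 0,
                            t_start = 5, t_end = 5.1, dur = 10, dt = 1e-3,
                            noise_sd = 0) {
  tt <- seq(0, dur, by = dt)
  z <- slope_before * tt
  after <- tt > t_end
  z[after] <- slope_before * t_start + h + slope_after * (tt[after] - t_end)
  mid <- tt >= t_start & tt <= t_end
  z[mid] <- approx(c(t_start, t_end),
                   c(slope_before * t_start,
                     slope_before * t_start + h), xout = tt[mid])$y
  if (noise_sd > 0) z <- z + rnorm(length(z), 0, noise_sd)
  list(times = tt, z = z)
}

# analytic two-line step oracle: fit the generating lines exactly
two_line_oracle <- function(h, slope_before, slope_after, t_start, t_end) {
  t_mid <- (t_start + t_end) / 2
  before <- slope_before * t_mid
  after <- slope_before * t_start + h + slope_after * (t_mid - t_end)
  after - before
}
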