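#' Configuration for a synthetic force-clamp recording
#'
#' Builds the parameter set for the synthetic AFM/TIRF recording generator.
#' The generator emulates the structure of a combined force-clamp + TIRF
#' experiment on a membrane-sheet vesicle: a coarse approach phase, a push
#' phase, and four sequential constant-force (clamp) segments of stepwise
#' increasing pull force, each 12.5 s by default.  Tether-extension events
#' appear as upward deflection transients with single-exponential decay and
#' a simultaneous lagged step in the servo height trace.
#'
#' Sign convention: the deflection voltage `v_defl` increases when the
#' cantilever bends away from the surface.  The free cantilever sits at 0 V
#' (plus drift); pull setpoints are therefore negative voltages, pushes
#' positive, and the pull force is `F = -k * D * (setpoint - baseline)`
#' (in pN, with `k` in N/m and `D` in nm/V).
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param sample_rate_clamp Sampling rate during push/ramp/clamp phases (Hz).
#' @param approach_dt Sampling interval during the coarse approach phase (s).
#' @param approach_height Starting servo height of the approach (nm).
#' @param push_duration Duration of the push phase (s).
#' @param push_force Push force magnitude (pN, applied as a negative force).
#' @param clamp_durations Durations of the four clamp segments (s).
#' @param setpoint_forces Strictly increasing pull forces of the four
#'   segments (pN).
#' @param ramp_duration Duration of the setpoint ramp between segments (s).
#' @param spring_constant Cantilever spring constant `k` (N/m).
#' @param deflection_sensitivity Deflection sensitivity `D` (nm/V).
#' @param drift_rate Deflection drift with servo height (V/um).
#' @param deflection_noise_sd White deflection noise SD (V).
#' @param servo_response_time Delay before the servo starts to follow a
#'   released extension (s).
#' @param event_rate_short,event_rate_long Poisson rates of short and long
#'   tether-extension events during clamps (events/s).
#' @param short_event_mean,short_event_sd Gaussian parameters of short-event
#'   magnitudes (nm); draws are truncated at 0 (extensions are positive).
#' @param long_event_range Log-uniform range of long-event magnitudes (nm).
#' @param transient_tau_range Uniform range of transient decay constants (s).
#' @param p_f_event Probability per segment of a full-dissociation (F) event.
#' @param p_r_event Probability per ramp of a rapid (R) event.
#' @param tirf An [evanescent_field()] describing the excitation.
#' @param frame_rate TIRF camera frame rate (Hz).
#' @param frame_size Frame size in pixels `c(nx, ny)`.
#' @param pixel_size_nm Camera pixel size in the sample plane (nm).
#' @param psf_sigma_px Gaussian spot width (pixels).
#' @param n_bg_spots Number of static background vesicles per stack.
#' @param shot_noise Add Poisson shot noise to simulated frames?
#' @param vesicle_attached Is a fluorescent vesicle attached to the tip?
#' @param gtpgs Simulated condition flag: GTPgS present?
#' @param t_lysis Time after cell lysis assigned to the recording (min).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       sample_rate_clamp = 1000,
                       approach_dt = 0.14,
                       approach_height = 1500,
                       push_duration = 5,
                       push_force = 200,
                       clamp_durations = rep(12.5, 4),
                       setpoint_forces = c(100, 200, 300, 400),
                       ramp_duration = 0.2,
                       spring_constant = 0.03,
                       deflection_sensitivity = 50,
                       drift_rate = -0.05,
                       deflection_noise_sd = 0.002,
                       servo_response_time = 0.01,
                       event_rate_short = 0.24,
                       event_rate_long = 0.02,
                       short_event_mean = 4.5,
                       short_event_sd = 3.1,
                       long_event_range = c(50, 2000),
                       transient_tau_range = c(0.02, 0.08),
                       p_f_event = 0,
                       p_r_event = 0,
                       tirf = evanescent_field(),
                       frame_rate = 10,
                       frame_size = c(32, 32),
                       pixel_size_nm = 160,
                       psf_sigma_px = 1.2,
                       n_bg_spots = 4,
                       shot_noise = TRUE,
                       vesicle_attached = TRUE,
                       gtpgs = TRUE,
                       t_lysis = 30) {
  cfg <- as.list(environment())
  if (length(cfg$setpoint_forces) != length(cfg$clamp_durations))
    stop("setpoint_forces and clamp_durations must have equal length")
  if (any(diff(cfg$setpoint_forces) <= 0))
    stop("setpoint_forces must be strictly increasing")
  if (cfg$sample_rate_clamp < 50)
    stop("sample_rate_clamp below 50 Hz cannot resolve the 200-ms step-fit ",
         "windows")
  if (any(c(cfg$clamp_durations, cfg$push_duration, cfg$approach_dt,
            cfg$ramp_duration, cfg$frame_rate) <= 0))
    stop("all durations and rates must be positive")
  if (cfg$event_rate_short < 0 || cfg$event_rate_long < 0)
    stop("event rates must be non-negative")
  if (cfg$short_event_sd <= 0) stop("short_event_sd must be positive")
  if (cfg$spring_constant <= 0 || cfg$spring_constant > 1)
    stop("spring_constant must lie in (0, 1] N/m")
  if (cfg$spring_constant < 0.008 || cfg$spring_constant > 0.04)
    warning("spring_constant outside the calibrated 0.008-0.04 N/m range")
  if (cfg$deflection_sensitivity < 33 || cfg$deflection_sensitivity > 67)
    warning("deflection_sensitivity outside the calibrated 33-67 nm/V range")
  stopifnot(inherits(cfg$tirf, "evanescent_field"))
  class(cfg) <- "sim_config"
  cfg
}

# pN per volt of deflection for a given calibration
kd_pn_per_v <- function(k, D) 1000 * k * D

# truncated-at-zero Gaussian draw (rejection; extensions are positive)
rtnorm_pos <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Simulate a force-clamp recording with ground truth
#'
#' Generates a synchronized synthetic recording (time, deflection voltage,
#' servo height, camera frame-sync trace) following the acquisition
#' protocol: approach (coarse sampling), push, then four clamp segments of
#' increasing pull force.  Injected tether-extension events produce a step
#' rise in the deflection trace with single-exponential decay and a
#' simultaneous, servo-lagged step of the true magnitude in the height
#' trace; the deflection includes white noise and a drift term proportional
#' to servo height.  A full-dissociation (F) event terminates the pull for
#' the remainder of the recording.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recording` (class `afm_recording`: `times`,
#'   `v_defl`, `z_servo`, `fnum`, `meta`) and `ground_truth` (class
#'   `ground_truth_log`: one row per injected event with
#'   `segment_index`, `true_time`, `true_dz`, `true_tau`, `event_type`,
#'   `shape`; attributes `true_d_tirf`, `true_drift`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$spring_constant
  D <- config$deflection_sensitivity
  kd <- kd_pn_per_v(k, D)
  sr <- config$sample_rate_clamp
  dt <- 1 / sr
  nseg <- length(config$setpoint_forces)
  v_free <- 0
  v_push <- v_free + config$push_force / kd       # push: positive deflection
  v_set <- v_free - config$setpoint_forces / kd   # pulls: negative deflection

  # --- draw events ------------------------------------------------------
  gt <- list()
  seg_events <- vector("list", nseg)
  f_times <- rep(NA_real_, nseg)
  r_events <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    dur <- config$clamp_durations[i]
    margin <- 0.4
    n_s <- stats::rpois(1, config$event_rate_short * dur)
    n_l <- stats::rpois(1, config$event_rate_long * dur)
    tt <- sort(stats::runif(n_s + n_l, margin, dur - margin))
    dz <- numeric(0)
    if (n_s + n_l > 0) {
      dz_s <- rtnorm_pos(n_s, config$short_event_mean, config$short_event_sd)
      lr <- log(config$long_event_range)
      dz_l <- exp(stats::runif(n_l, lr[1], lr[2]))
      # interleave magnitudes over the sorted times (sample.int, not
      # sample(): a single draw must not expand into a permutation)
      dz <- c(dz_s, dz_l)[sample.int(n_s + n_l)]
    }
    tau <- stats::runif(length(tt), config$transient_tau_range[1],
                        config$transient_tau_range[2])
    seg_events[[i]] <- data.frame(t = tt, dz = dz, tau = tau)
    if (stats::runif(1) < config$p_f_event)
      f_times[i] <- stats::runif(1, margin, dur - margin)
    if (stats::runif(1) < config$p_r_event)
      r_events[[i]] <- data.frame(
        t = stats::runif(1, 0.02, config$ramp_duration - 0.02),
        dz = rtnorm_pos(1, config$short_event_mean, config$short_event_sd),
        tau = stats::runif(1, config$transient_tau_range[1],
                           config$transient_tau_range[2]))
  }

  # --- assemble phases --------------------------------------------------
  times <- v <- z <- numeric(0)
  schedule <- list()
  t0 <- 0
  add_phase <- function(phase, index, tt, vv, zz, setpt_v, setpt_F) {
    times <<- c(times, tt); v <<- c(v, vv); z <<- c(z, zz)
    schedule[[length(schedule) + 1]] <<- data.frame(
      phase = phase, index = index, t_start = tt[1],
      t_end = tt[length(tt)] + (if (length(tt) > 1)
        tt[2] - tt[1] else dt),
      setpoint_v = setpt_v, setpoint_F = setpt_F)
  }

  # approach: coarse sampling, z descends to the surface at ~150 nm/s
  n_app <- max(20, round(config$approach_height / 150 / config$approach_dt))
  t_app <- seq(0, by = config$approach_dt, length.out = n_app)
  z_app <- seq(config$approach_height, 0, length.out = n_app)
  add_phase("approach", 0L, t_app, rep(v_free, n_app), z_app, NA, NA)
  t0 <- t_app[n_app] + config$approach_dt

  # push
  t_push <- seq(t0, by = dt, length.out = round(config$push_duration * sr))
  add_phase("push", 0L, t_push, rep(v_push, length(t_push)),
            rep(0, length(t_push)), v_push, -config$push_force)
  t0 <- t_push[length(t_push)] + dt

  z_base <- 0
  detached <- FALSE
  detach_time <- NA_real_
  z_rail_rate <- 10000  # nm/s servo slew once the tip is free
  z_at_detach <- NA_real_
  v_prev <- v_push

  for (i in seq_len(nseg)) {
    # ramp to the new setpoint
    n_rmp <- round(config$ramp_duration * sr)
    t_rmp <- seq(t0, by = dt, length.out = n_rmp)
    if (detached) {
      v_rmp <- rep(v_free, n_rmp)
      z_rmp <- pmin(z_at_detach + z_rail_rate * (t_rmp - detach_time),
                    z_at_detach + 3000)
    } else {
      v_rmp <- seq(v_prev, v_set[i], length.out = n_rmp)
      z_rmp <- rep(z_base, n_rmp)
      re <- r_events[[i]]
      if (!is.null(re)) {
        trel <- t_rmp - t0
        on <- trel >= re$t
        v_rmp[on] <- v_rmp[on] + (re$dz / D) * exp(-(trel[on] - re$t) / re$tau)
        lag <- trel >= re$t + config$servo_response_time
        z_rmp[lag] <- z_rmp[lag] + re$dz *
          (1 - exp(-(trel[lag] - re$t - config$servo_response_time) / re$tau))
        z_base <- z_base + re$dz
        gt[[length(gt) + 1]] <- data.frame(
          segment_index = i, true_time = t0 + re$t, true_dz = re$dz,
          true_tau = re$tau, event_type = "R", shape = "unitary")
      }
    }
    add_phase("ramp", i, t_rmp, v_rmp, z_rmp, v_set[i],
              config$setpoint_forces[i])
    t0 <- t_rmp[n_rmp] + dt

    # clamp segment
    dur <- config$clamp_durations[i]
    n_cl <- round(dur * sr)
    t_cl <- seq(t0, by = dt, length.out = n_cl)
    trel <- t_cl - t0
    if (detached) {
      v_cl <- rep(v_free, n_cl)
      z_cl <- pmin(z_at_detach + z_rail_rate * (t_cl - detach_time),
                   z_at_detach + 3000)
    } else {
      v_cl <- rep(v_set[i], n_cl)
      z_cl <- rep(z_base, n_cl)
      ev <- seg_events[[i]]
      if (!is.na(f_times[i]))
        ev <- ev[ev$t < f_times[i], , drop = FALSE]
      if (nrow(ev)) {
        # shape bookkeeping: transients closer than 3*tau superpose into a
        # complex event
        gap_prev <- c(Inf, diff(ev$t))
        gap_next <- c(diff(ev$t), Inf)
        cplx <- gap_prev < 3 * ev$tau | gap_next < 3 * ev$tau
        for (j in seq_len(nrow(ev))) {
          # deflection tracks the not-yet-reabsorbed extension, saturating
          # at the free-cantilever level for large releases
          on <- trel >= ev$t[j]
          v_cl[on] <- v_cl[on] +
            (ev$dz[j] / D) * exp(-(trel[on] - ev$t[j]) / ev$tau[j])
          lag <- trel >= ev$t[j] + config$servo_response_time
          z_cl[lag] <- z_cl[lag] + ev$dz[j] *
            (1 - exp(-(trel[lag] - ev$t[j] - config$servo_response_time) /
                       ev$tau[j]))
          gt[[length(gt) + 1]] <- data.frame(
            segment_index = i, true_time = t0 + ev$t[j], true_dz = ev$dz[j],
            true_tau = ev$tau[j], event_type = "FC",
            shape = if (cplx[j]) "complex" else "unitary")
        }
        z_base <- z_base + sum(ev$dz)
        v_cl <- pmin(v_cl, v_free)
      }
      if (!is.na(f_times[i])) {
        detached <- TRUE
        detach_time <- t0 + f_times[i]
        z_at_detach <- z_cl[max(which(trel < f_times[i]))]
        off <- trel >= f_times[i]
        v_cl[off] <- v_free
        z_cl[off] <- pmin(z_at_detach + z_rail_rate * (trel[off] - f_times[i]),
                          z_at_detach + 3000)
        gt[[length(gt) + 1]] <- data.frame(
          segment_index = i, true_time = detach_time, true_dz = NA_real_,
          true_tau = NA_real_, event_type = "F", shape = "unitary")
      }
    }
    add_phase("clamp", i, t_cl, v_cl, z_cl, v_set[i],
              config$setpoint_forces[i])
    t0 <- t_cl[n_cl] + dt
    v_prev <- v_set[i]
  }

  # drift with servo height, then white noise
  v <- v + config$drift_rate * z / 1000
  if (config$deflection_noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, config$deflection_noise_sd)

  fnum <- (floor(times * config$frame_rate) + 1) / 1000

  schedule <- do.call(rbind, schedule)
  rec <- structure(list(
    times = times, v_defl = v, z_servo = z, fnum = fnum,
    meta = list(spring_constant = k, deflection_sensitivity = D,
                sample_rate_clamp = sr, frame_rate = config$frame_rate,
                t_lysis = config$t_lysis, gtpgs = config$gtpgs,
                vesicle_observed = config$vesicle_attached,
                v_free = v_free, seed = config$seed,
                schedule = schedule)),
    class = "afm_recording")

  gtl <- if (length(gt)) do.call(rbind, gt) else
    data.frame(segment_index = integer(0), true_time = numeric(0),
               true_dz = numeric(0), true_tau = numeric(0),
               event_type = character(0), shape = character(0))
  attr(gtl, "true_d_tirf") <- config$tirf$d_tirf
  attr(gtl, "true_drift") <- config$drift_rate
  class(gtl) <- c("ground_truth_log", "data.frame")
  list(recording = rec, ground_truth = gtl)
}

#' @export
print.afm_recording <- function(x, ...) {
  cat("AFM force-clamp recording:", length(x$times), "samples,",
      sprintf("%.1f s", diff(range(x$times))), "\n")
  ph <- x$meta$schedule
  cat("  phases:", paste(unique(ph$phase), collapse = ", "),
      "| clamp segments:", sum(ph$phase == "clamp"), "\n")
  cat("  k =", x$meta$spring_constant, "N/m, D =",
      x$meta$deflection_sensitivity, "nm/V, t_lysis =", x$meta$t_lysis,
      "min\n")
  invisible(x)
}

#' Simulate a TIRF image stack matching a recording
#'
#' Renders one frame per camera frame encoded in the recording's `fnum`
#' trace.  The tip-attached vesicle is drawn as a 2-D Gaussian spot at the
#' frame centre whose brightness follows the evanescent decay of the
#' excitation with the vesicle's current height (servo height clamped at the
#' surface); static background vesicles and a uniform background level are
#' added, plus optional Poisson shot noise.  The spot profile is normalised
#' so that the mean over the standard 3x3 ROI equals the vesicle intensity
#' given by the field model, making ROI extraction directly comparable to
#' [intensity_at_height()].
#'
#' @param recording An `afm_recording`.
#' @param field An [evanescent_field()].
#' @param config The [sim_config()] used for the recording (frame geometry,
#'   noise and seed are taken from it).
#' @return An object of class `tirf_stack`: list with `frames` (array
#'   `[y, x, frame]`), `frame_times` (s), `pixel_size_nm`, `center_px`
#'   (0-based `c(x, y)` of the tip vesicle).
#' @export
simulate_tirf_stack <- function(recording, field, config) {
  stopifnot(inherits(recording, "afm_recording"),
            inherits(field, "evanescent_field"),
            inherits(config, "sim_config"))
  nx <- config$frame_size[1]; ny <- config$frame_size[2]
  if (nx < 3 || ny < 3) stop("frame size must be at least 3x3 pixels")
  set.seed(config$seed + 1L)
  frames_idx <- as.integer(round(recording$fnum * 1000))
  n_frames <- max(frames_idx)
  frame_times <- (seq_len(n_frames) - 1) / config$frame_rate
  z_ves <- pmax(stats::approx(recording$times, recording$z_servo,
                              xout = frame_times, rule = 2)$y, 0)
  cx <- floor(nx / 2); cy <- floor(ny / 2)  # 0-based centre pixel
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  spot <- function(px, py, sigma) {
    w <- exp(-((xs - px)^2 + (ys - py)^2) / (2 * sigma^2))
    roi <- w[(py + 1 - 1):(py + 1 + 1), (px + 1 - 1):(px + 1 + 1)]
    w * (9 / sum(roi))  # 3x3 ROI mean of the spot = its nominal intensity
  }
  tipw <- spot(cx, cy, config$psf_sigma_px)
  base <- matrix(field$I_background, ny, nx)
  if (config$n_bg_spots > 0) {
    excl <- min(4, floor(min(nx, ny) / 4))  # keep clear of the tip ROI
    for (b in seq_len(config$n_bg_spots)) {
      for (try in 1:100) {
        px <- sample(1:(nx - 2), 1); py <- sample(1:(ny - 2), 1)
        if (abs(px - cx) > excl || abs(py - cy) > excl) break
      }
      base <- base + spot(px, py, config$psf_sigma_px) *
        stats::runif(1, 0.5, 1.5) * field$I0
    }
  }
  I_ves <- if (config$vesicle_attached)
    intensity_at_height(field, z_ves) else rep(0, n_frames)
  frames <- array(0, dim = c(ny, nx, n_frames))
  for (f in seq_len(n_frames)) frames[, , f] <- base + tipw * I_ves[f]
  if (config$shot_noise) {
    frames[] <- stats::rpois(length(frames), lambda = frames)
  }
  structure(list(frames = frames, frame_times = frame_times,
                 pixel_size_nm = config$pixel_size_nm,
                 center_px = c(cx, cy)),
            class = "tirf_stack")
}

#' @export
print.tirf_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("TIRF stack:", d[3], "frames of", d[2], "x", d[1], "px,",
      x$pixel_size_nm, "nm/px\n")
  invisible(x)
}
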