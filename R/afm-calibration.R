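#' Robust deflection-noise estimate
#'
#' Estimates the white-noise SD of a deflection trace from the median
#' absolute successive difference, which is insensitive to baseline drift
#' and to sparse transients.
#'
#' @param v Deflection trace (V).
#' @return Noise SD (V).
#' @export
noise_sd_estimate <- function(v) {
  stats::mad(diff(v)) / sqrt(2)
}

#' Deflection sensitivity from a push curve
#'
#' The deflection sensitivity `D` (nm of cantilever deflection per volt of
#' photodiode signal) is calibrated by pressing the tip onto a hard surface:
#' while the tip is pinned, servo motion translates one-to-one into
#' cantilever bending, so the slope of `v_defl` versus `z` in the contact
#' region gives `1/D`.
#'
#' The contact region is auto-detected as the points whose deflection lies
#' in the upper part of the deflection range (the rising contact branch), or
#' can be supplied explicitly.
#'
#' @param z Servo height (nm).
#' @param v_defl Deflection (V).
#' @param contact_span Optional logical/index vector selecting the contact
#'   region; auto-detected when `NULL`.
#' @param min_points Minimum number of contact points required.
#' @return Deflection sensitivity `D` in nm/V, with the fitted slope and
#'   number of points in attributes.
#' @export
deflection_sensitivity <- function(z, v_defl, contact_span = NULL,
                                   min_points = 5) {
  stopifnot(length(z) == length(v_defl))
  if (is.null(contact_span)) {
    rng <- diff(range(v_defl))
    noise <- noise_sd_estimate(v_defl)
    if (rng < max(5 * noise, .Machine$double.eps * 100))
      stop("no contact region: deflection range indistinguishable from noise")
    contact_span <- v_defl >= min(v_defl) + 0.2 * rng
  }
  zz <- z[contact_span]; vv <- v_defl[contact_span]
  if (length(zz) < min_points) stop("contact region has too few points")
  fit <- stats::lm(vv ~ zz)
  slope <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (!is.finite(slope) || abs(slope) == 0 ||
      (is.finite(se) && se > 0 && abs(slope) / se < 5))
    stop("no significant slope in the contact region")
  D <- 1 / abs(slope)
  attr(D, "slope_V_per_nm") <- slope
  attr(D, "n_points") <- length(zz)
  D
}

#' Deflection drift with servo height
#'
#' The free-cantilever deflection voltage varies slightly with servo height
#' (optical path artefact).  This estimates that drift as the linear slope
#' of `v_defl` versus `z` over out-of-contact episodes, reported in V/um,
#' averaged over episodes.
#'
#' @param free_segments List of data frames with columns `z` (nm) and `v`
#'   (V), each an out-of-contact episode.
#' @return List with `drift` (mean slope, V/um), `sd` (SD across episodes;
#'   `NA` for a single episode) and `per_segment` (slopes, V/um).
#' @export
estimate_drift <- function(free_segments) {
  if (!length(free_segments)) stop("no free-cantilever segments supplied")
  slopes <- vapply(free_segments, function(s) {
    stopifnot(all(c("z", "v") %in% names(s)))
    unname(stats::coef(stats::lm(v ~ z, data = s))[2]) * 1000
  }, numeric(1))
  list(drift = mean(slopes),
       sd = if (length(slopes) > 1) stats::sd(slopes) else NA_real_,
       per_segment = slopes)
}

#' Remove height-dependent drift from a recording
#'
#' Subtracts `drift * z / 1000` from the deflection trace (drift in V/um,
#' `z` in nm), referencing the deflection to zero servo height.
#'
#' @param recording An `afm_recording`.
#' @param drift Drift rate (V/um), e.g. from [estimate_drift()].
#' @return The recording with a corrected `v_defl` trace; the applied drift
#'   is stored in `meta$drift_corrected`.
#' @export
correct_drift <- function(recording, drift) {
  stopifnot(inherits(recording, "afm_recording"))
  recording$v_defl <- recording$v_defl - drift * recording$z_servo / 1000
  recording$meta$drift_corrected <- drift
  recording
}

#' Pull force and its uncertainty for a clamp segment
#'
#' Converts the clamp setpoint voltage into a pull force using the
#' free-cantilever baselines measured before contact (`v_contact`) and after
#' final release (`v_end`).  With deflection voltage increasing when the
#' cantilever bends away from the surface, a pull setpoint lies below the
#' free baseline, so `F = -k * D * (setpoint_v - baseline) * 1000` (pN)
#' is positive for pulls and negative for pushes.  The two baselines give
#' two force estimates whose mean is reported; half their spread, combined
#' in quadrature with the baseline noise contribution, gives `sigma_F`.
#'
#' @param setpoint_v Clamp setpoint deflection (V, drift-corrected).
#' @param v_contact Free baseline before contact (V); `NA` if unavailable.
#' @param v_end Free baseline after final release (V); `NA` if unavailable.
#' @param k Spring constant (N/m).
#' @param D Deflection sensitivity (nm/V).
#' @param noise_sd Baseline noise SD (V), propagated into `sigma_F`.
#' @return List with `F` (pN), `sigma_F` (pN), the per-baseline estimates
#'   `F_contact`, `F_end`, and `flags` (character; `"missing_baseline"` when
#'   only one baseline was available).
#' @export
compute_pull_force <- function(setpoint_v, v_contact, v_end, k, D,
                               noise_sd = 0) {
  stopifnot(k > 0, D > 0)
  kd <- kd_pn_per_v(k, D)
  F_c <- if (is.na(v_contact)) NA_real_ else -kd * (setpoint_v - v_contact)
  F_e <- if (is.na(v_end)) NA_real_ else -kd * (setpoint_v - v_end)
  flags <- character(0)
  if (is.na(F_c) && is.na(F_e))
    stop("both baselines missing: pull force undefined")
  if (is.na(F_c) || is.na(F_e)) {
    flags <- "missing_baseline"
    Fm <- if (is.na(F_c)) F_e else F_c
    spread <- NA_real_
    sigma <- kd * noise_sd
  } else {
    Fm <- (F_c + F_e) / 2
    spread <- abs(F_c - F_e) / 2
    sigma <- sqrt(spread^2 + (kd * noise_sd)^2)
  }
  list(F = Fm, sigma_F = sigma, F_contact = F_c, F_end = F_e, flags = flags)
}

#' Parse a recording into approach, push and clamp segments
#'
#' Splits a recording along the acquisition schedule stored in its metadata
#' and, for each clamp segment, determines whether the deflection actually
#' attained the setpoint and when.  Attainment is judged on a
#' median-smoothed, drift-corrected deflection trace: the setpoint counts as
#' reached once the deflection covers at least `reach_frac` of the distance
#' from the free baseline to the setpoint.
#'
#' @param recording An `afm_recording` (drift-correct it first with
#'   [correct_drift()] for best results).
#' @param reach_frac Fraction of the baseline-to-setpoint excursion that
#'   must be attained (default 0.9, so a segment plateauing 20% short is
#'   flagged as not reached).
#' @param baseline_window Length of the pre-contact window used for the
#'   `v_contact` baseline (s).
#' @return List with `approach` and `push` (single-row data frames of time
#'   spans), `segments` (data frame, class `clamp_segments`: `index`,
#'   `t_start`, `t_end`, `setpoint_v`, `setpoint_F`, `reached_setpoint`,
#'   `t_reached`, `nominal_duration`), and `v_contact` (V).
#' @export
parse_phases <- function(recording, reach_frac = 0.9,
                         baseline_window = 0.5) {
  stopifnot(inherits(recording, "afm_recording"))
  sched <- recording$meta$schedule
  if (is.null(sched))
    stop("recording carries no acquisition schedule in its metadata")
  tt <- recording$times; vv <- recording$v_defl
  v_free <- recording$meta$v_free %||% 0
  app <- sched[sched$phase == "approach", , drop = FALSE]
  psh <- sched[sched$phase == "push", , drop = FALSE]
  # pre-contact free baseline: tail of the approach
  sel <- tt >= app$t_end - baseline_window & tt < app$t_end
  if (!any(sel)) sel <- tt < app$t_end
  v_contact <- mean(vv[sel])
  cl <- sched[sched$phase == "clamp", , drop = FALSE]
  rmp <- sched[sched$phase == "ramp", , drop = FALSE]
  segs <- lapply(seq_len(nrow(cl)), function(i) {
    # search from the start of the preceding ramp through the clamp
    t_from <- if (i <= nrow(rmp)) rmp$t_start[rmp$index == cl$index[i]]
              else cl$t_start[i]
    if (!length(t_from)) t_from <- cl$t_start[i]
    span <- tt >= t_from & tt < cl$t_end[i]
    vs <- vv[span]
    k <- min(length(vs) - (1 - length(vs) %% 2), 51)
    vsm <- if (k >= 3) stats::runmed(vs, k) else vs
    target <- v_free + reach_frac * (cl$setpoint_v[i] - v_free)
    hit <- if (cl$setpoint_v[i] < v_free) vsm <= target else vsm >= target
    reached <- any(hit)
    data.frame(index = cl$index[i], t_start = cl$t_start[i],
               t_end = cl$t_end[i], setpoint_v = cl$setpoint_v[i],
               setpoint_F = cl$setpoint_F[i],
               reached_setpoint = reached,
               t_reached = if (reached) tt[span][which(hit)[1]] else NA_real_,
               nominal_duration = cl$t_end[i] - cl$t_start[i])
  })
  segs <- do.call(rbind, segs)
  class(segs) <- c("clamp_segments", "data.frame")
  list(approach = app, push = psh, segments = segs, v_contact = v_contact)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame-time map from the camera sync trace
#'
#' The camera frame-fire signal is recorded alongside the AFM traces as a
#' staircase `fnum` whose value times 1000 is the TIRF frame number.  This
#' maps each frame number to the first sample time at which it appears.
#'
#' @param fnum The frame-sync trace (V-encoded frame counter / 1000).
#' @param times Sample times (s).
#' @return Data frame with columns `frame` (integer) and `time` (s).
#' @export
sync_frames <- function(fnum, times) {
  stopifnot(length(fnum) == length(times))
  frames <- as.integer(round(fnum * 1000))
  if (any(diff(frames) < 0)) stop("fnum trace is not monotone non-decreasing")
  first <- !duplicated(frames)
  data.frame(frame = frames[first], time = times[first])
}
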