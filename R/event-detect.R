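#' Detect force transients in a deflection trace
#'
#' Scans a (drift-corrected) deflection span for tether-extension force
#' transients: upward excursions above the clamp baseline that rise steeply
#' and relax back with a single-exponential decay, the same morphology as
#' amperometric spikes.  For each transient the peak (`v_max`, `t_vmax`),
#' the half-rise time (`t_half`), a linear fit to the rising flank (whose
#' baseline intercept defines `t_start`), and an exponential fit to the
#' falling flank (decay constant `tau`; `t_end` is where the fitted decay
#' re-enters one noise SD of the baseline) are determined.
#'
#' Nearby excursions are merged into a single complex event when their peaks
#' are separated by less than `merge_factor` times the decay constant and
#' the trace does not return to within 2 SD of the baseline between them;
#' events with two or more resolved peaks are labelled `complex`.
#'
#' @param times Sample times (s), strictly increasing.
#' @param v Deflection trace (V), drift-corrected.
#' @param baseline Baseline level (V): a scalar (e.g. the clamp setpoint), a
#'   vector matching `v`, or `NULL` to use a 1-s running median.
#' @param noise_sd Baseline noise SD (V); estimated robustly when `NULL`.
#' @param threshold Detection threshold in baseline-noise SDs (default 4).
#' @param merge_factor Complex-merging window in units of `tau` (default 3).
#' @param baseline_window Running-median window for automatic baselines (s);
#'   the span must be at least twice this long.
#' @return Data frame with one row per event: `t_start`, `t_end`, `t_vmax`,
#'   `v_max` (baseline-subtracted, V), `t_half`, `rise_slope` (V/s), `tau`
#'   (s), `fit_quality` (R^2 of the log-linear decay fit), `n_peaks`,
#'   `shape` (`"unitary"`/`"complex"`).
#' @export
detect_transients <- function(times, v, baseline = NULL, noise_sd = NULL,
                              threshold = 4, merge_factor = 3,
                              baseline_window = 1) {
  stopifnot(length(times) == length(v), length(v) >= 2)
  span <- times[length(times)] - times[1]
  if (span < 2 * baseline_window)
    stop("segment shorter than twice the baseline window")
  dt <- stats::median(diff(times))
  if (is.null(baseline)) {
    k <- round(baseline_window / dt)
    k <- max(3, k + (1 - k %% 2))
    k <- min(k, length(v) - (1 - length(v) %% 2))
    baseline <- stats::runmed(v, k)
  }
  b <- if (length(baseline) == 1) rep(baseline, length(v)) else baseline
  res <- v - b
  if (is.null(noise_sd)) noise_sd <- noise_sd_estimate(v)
  sd_eff <- max(noise_sd, 1e-4 * max(res, 0), 1e-12)

  above <- res > threshold * sd_eff
  if (!any(above)) return(empty_transients())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])

  # per-run peak and half-decay-scale estimates used by the grouping rule
  runs$ipk <- mapply(function(i0, i1) i0 - 1 + which.max(res[i0:i1]),
                     runs$i0, runs$i1)
  runs$tpk <- times[runs$ipk]
  runs$tau0 <- mapply(function(ipk, i1) {
    seg <- res[ipk:i1]
    ih <- which(seg <= res[ipk] / 2)[1]
    if (is.na(ih)) (i1 - ipk + 1) * dt / log(2) else ih * dt / log(2)
  }, runs$ipk, runs$i1)

  # group runs into events: an event ends only once the trace has returned
  # to within 2 SD of the baseline for a sustained stretch, or the next
  # peak is further than merge_factor decay constants away
  n_gap <- max(3, round(0.05 / dt))
  grp <- integer(nrow(runs)); grp[1] <- 1L
  if (nrow(runs) > 1) {
    big_tau <- runs$tau0[1]
    big_pk <- res[runs$ipk[1]]
    for (j in 2:nrow(runs)) {
      prev <- j - 1
      gap <- res[runs$i1[prev]:runs$i0[j]]
      low <- rle(gap < 2 * sd_eff)
      sustained <- length(low$lengths) &&
        any(low$lengths[low$values] >= n_gap)
      far <- (runs$tpk[j] - runs$tpk[prev]) >
        merge_factor * max(big_tau, runs$tau0[prev])
      if (sustained || far) {
        grp[j] <- grp[prev] + 1L
        big_tau <- runs$tau0[j]
        big_pk <- res[runs$ipk[j]]
      } else {
        grp[j] <- grp[prev]
        if (res[runs$ipk[j]] > big_pk) {
          big_pk <- res[runs$ipk[j]]
          big_tau <- runs$tau0[j]
        }
      }
    }
  }

  groups <- split(seq_len(nrow(runs)), grp)
  out <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    i0 <- runs$i0[idx[1]]; i1 <- runs$i1[idx[length(idx)]]
    # minimum evidence: single-sample noise crossings are not events
    if (sum(res[i0:i1] > threshold * sd_eff) < 3) return(NULL)
    i_prev_end <- if (g > 1) runs$i1[groups[[g - 1]][length(groups[[g - 1]])]]
                  else 0L
    ipk_all <- i0 - 1 + which.max(res[i0:i1])
    vmax <- res[ipk_all]
    # resolved peaks over the whole event span (smoothed against noise)
    grp_res <- res[i0:i1]
    if (length(grp_res) >= 5) grp_res <- stats::runmed(grp_res, 5)
    pk <- i0 - 1 + peak_indices(grp_res, max(2 * sd_eff, 0.05 * vmax))
    n_pk <- length(pk)
    # rising flank of the first run (not beyond the previous event)
    ir <- i0
    while (ir > i_prev_end + 1 && ir > 1 && res[ir - 1] > sd_eff)
      ir <- ir - 1
    ipk1 <- runs$ipk[idx[1]]
    t_half <- {
      hv <- res[ipk1] / 2
      ih <- ir - 1 + which(res[ir:ipk1] >= hv)[1]
      if (ih > 1 && res[ih] != res[ih - 1])
        times[ih - 1] + (hv - res[ih - 1]) * (times[ih] - times[ih - 1]) /
          (res[ih] - res[ih - 1])
      else times[ih]
    }
    rise_idx <- ir:ipk1
    rise_idx <- rise_idx[res[rise_idx] > 0.1 * res[ipk1]]
    if (length(rise_idx) >= 2) {
      rf <- stats::lm(res[rise_idx] ~ times[rise_idx])
      slope <- unname(stats::coef(rf)[2])
      t_start <- if (is.finite(slope) && slope > 0)
        -unname(stats::coef(rf)[1]) / slope else times[ir]
      t_start <- max(t_start, if (ir > 1) times[ir - 1] else times[1])
      t_start <- min(t_start, times[ipk1])
    } else {
      # rise faster than sampling: place the start between samples
      slope <- res[ipk1] / dt
      t_start <- if (ir > 1) (times[ir - 1] + times[ir]) / 2 else times[ir]
    }
    # falling flank from the last resolved peak, extended into the
    # sub-threshold tail up to the next event
    ipkL <- pk[n_pk]
    i_next <- if (g < length(groups)) runs$i0[groups[[g + 1]][1]] - 1L
              else length(res)
    ifall <- ipkL:i_next
    below <- which(res[ifall] <= max(sd_eff, 0.02 * res[ipkL]))
    if (length(below)) ifall <- ifall[seq_len(below[1] - 1)]
    tau <- NA_real_; fq <- NA_real_
    if (length(ifall) >= 3) {
      lf <- stats::lm(log(res[ifall]) ~ times[ifall])
      sl <- unname(stats::coef(lf)[2])
      if (is.finite(sl) && sl < 0) {
        tau <- -1 / sl
        fq <- suppressWarnings(summary(lf)$r.squared)
      }
    }
    if (!is.finite(tau) || tau <= 0) tau <- runs$tau0[idx[length(idx)]]
    t_end <- times[ipkL] + tau * log(max(res[ipkL], sd_eff) / sd_eff)
    t_next <- if (g < length(groups))
      times[runs$i0[groups[[g + 1]][1]]] - dt else times[length(times)]
    t_end <- min(max(t_end, times[ipkL]), t_next)
    data.frame(t_start = t_start, t_end = t_end, t_vmax = times[ipk_all],
               v_max = vmax, t_half = t_half, rise_slope = slope, tau = tau,
               fit_quality = fq, n_peaks = n_pk,
               shape = if (n_pk >= 2) "complex" else "unitary")
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty_transients())
  rownames(out) <- NULL
  out
}

empty_transients <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), t_vmax = numeric(0),
             v_max = numeric(0), t_half = numeric(0), rise_slope = numeric(0),
             tau = numeric(0), fit_quality = numeric(0),
             n_peaks = integer(0), shape = character(0))
}

# indices of resolved local maxima in a residual trace: maxima separated by
# dips of at least `min_dip` below the smaller of the two peaks
peak_indices <- function(x, min_dip) {
  n <- length(x)
  if (n < 3) return(which.max(x))
  cand <- which(x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
  if (length(cand) <= 1)
    return(if (length(cand)) cand else which.max(x))
  keep <- cand[1]
  for (i in cand[-1]) {
    trough <- min(x[keep[length(keep)]:i])
    if (trough <= min(x[keep[length(keep)]], x[i]) - min_dip)
      keep <- c(keep, i)
    else if (x[i] > x[keep[length(keep)]])
      keep[length(keep)] <- i
  }
  keep
}

#' Tether-extension step size from the servo trace
#'
#' Estimates the extension step associated with a force transient by
#' fitting least-squares lines to the servo height over windows before
#' `t_start` and after `t_end`, and taking the difference between the two
#' lines evaluated at the midpoint `(t_start + t_end)/2`.  Exact on
#' noiseless piecewise-linear-plus-step traces.
#'
#' @param times Sample times (s).
#' @param z Servo height (nm).
#' @param t_start,t_end Transient start/end times (s).
#' @param window Fit-window length on each side (s), default 0.2.
#' @param min_points Minimum samples required in each window.
#' @param limits Optional `c(lo, hi)` times beyond which the windows are
#'   truncated (e.g. boundaries of adjacent transients); truncation is
#'   flagged in `attr(, "truncated")`.
#' @return Step size `dz` in nm, with attribute `truncated`.
#' @export
measure_step <- function(times, z, t_start, t_end, window = 0.2,
                         min_points = 10, limits = NULL) {
  lo <- t_start - window
  hi <- t_end + window
  truncated <- FALSE
  if (!is.null(limits)) {
    if (is.finite(limits[1]) && limits[1] > lo) { lo <- limits[1]; truncated <- TRUE }
    if (is.finite(limits[2]) && limits[2] < hi) { hi <- limits[2]; truncated <- TRUE }
  }
  before <- times >= lo & times < t_start
  after <- times > t_end & times <= hi
  if (sum(before) < min_points || sum(after) < min_points)
    stop("step-fit window has fewer than ", min_points, " samples")
  t_mid <- (t_start + t_end) / 2
  fb <- stats::lm(z[before] ~ times[before])
  fa <- stats::lm(z[after] ~ times[after])
  pred <- function(fit, x) unname(stats::coef(fit)[1] + stats::coef(fit)[2] * x)
  dz <- pred(fa, t_mid) - pred(fb, t_mid)
  attr(dz, "truncated") <- truncated
  dz
}

#' Classify transients as force-clamp, rapid or full-dissociation events
#'
#' Applies the event taxonomy: `R` (rapid) if the transient starts before
#' the segment's setpoint was first attained, `F` (full dissociation) if
#' after the transient the deflection remains at the free-cantilever level
#' for the rest of the segment (no evidence of a pull force), `FC`
#' otherwise.  Classification is total: every transient receives exactly
#' one type.
#'
#' @param transients Data frame from [detect_transients()].
#' @param segment One row of the `clamp_segments` table (needs `t_end`,
#'   `t_reached`).
#' @param times,v The (drift-corrected) trace the transients came from.
#' @param v_free Free-cantilever deflection level (V), default 0.
#' @param noise_sd Baseline noise SD (V); estimated when `NULL`.
#' @return Character vector of `"FC"`, `"R"`, `"F"`.
#' @export
classify_event_type <- function(transients, segment, times, v, v_free = 0,
                                noise_sd = NULL) {
  if (!nrow(transients)) return(character(0))
  if (is.null(noise_sd)) noise_sd <- noise_sd_estimate(v)
  t_reached <- segment$t_reached
  vapply(seq_len(nrow(transients)), function(j) {
    tr <- transients[j, ]
    if (is.na(t_reached) || tr$t_start < t_reached) return("R")
    # full dissociation shows no pull force from just after the peak to the
    # segment end (an F "transient" never decays back to the setpoint)
    t_from <- if (!is.null(tr$t_vmax)) tr$t_vmax else tr$t_start
    tail_sel <- times > t_from + 0.1 & times < segment$t_end
    if (sum(tail_sel) >= 10) {
      vt <- v[tail_sel]
      k <- min(length(vt) - (1 - length(vt) %% 2), 21)
      vs <- if (k >= 3) stats::runmed(vt, k) else vt
      at_free <- abs(mean(vt) - v_free) < 3 * noise_sd &&
        all(abs(vs - v_free) < 5 * noise_sd)
      if (at_free) return("F")
    }
    "FC"
  }, character(1))
}

#' Size/shape class of a tether-extension event
#'
#' Combines the transient shape with the measured extension: unitary events
#' are `S` (short, `dz` < 50 nm) or `E` (extended); complex events `C_S` or
#' `C_E`.  A tie at exactly the threshold is assigned to the extended
#' class.  Events without a measurable `dz` (e.g. rapid events, recorded
#' while the piezo was in motion) get `NA`, flagged in
#' `attr(, "unsized")`.
#'
#' @param shape Character vector, `"unitary"` or `"complex"`.
#' @param dz Measured extensions (nm); may contain `NA`.
#' @param threshold Short/extended boundary (nm), default 50.
#' @return Character vector of `"S"`, `"E"`, `"C_S"`, `"C_E"` or `NA`.
#' @export
classify_shape_and_size <- function(shape, dz, threshold = 50) {
  stopifnot(length(shape) == length(dz))
  out <- ifelse(is.na(dz), NA_character_,
                ifelse(shape == "complex",
                       ifelse(dz < threshold, "C_S", "C_E"),
                       ifelse(dz < threshold, "S", "E")))
  attr(out, "unsized") <- is.na(dz)
  out
}

#' Effective force-clamp duration of a segment
#'
#' The time during which the clamp force was actually applied: from the
#' first setpoint attainment after the last rapid (R) event to the end of
#' the segment or the first full-dissociation (F) event, whichever comes
#' first.  A segment that never reached its setpoint has duration 0,
#' flagged in `attr(, "flag")`.
#'
#' @param segment One row of the `clamp_segments` table.
#' @param events Events of that segment (needs `event_type`, `t_start`,
#'   `t_end`).
#' @return Duration in seconds.
#' @export
clamp_duration <- function(segment, events) {
  if (!isTRUE(segment$reached_setpoint)) {
    out <- 0
    attr(out, "flag") <- "setpoint_not_reached"
    return(out)
  }
  t0 <- segment$t_reached
  if (nrow(events)) {
    r <- events[events$event_type == "R", , drop = FALSE]
    if (nrow(r)) t0 <- max(t0, max(r$t_end))
    f <- events[events$event_type == "F", , drop = FALSE]
    t1 <- if (nrow(f)) min(segment$t_end, min(f$t_start)) else segment$t_end
  } else t1 <- segment$t_end
  max(0, t1 - t0)
}

#' Detect and classify all tether-extension events in a recording
#'
#' Runs the full detector over every clamp segment (and its preceding
#' setpoint ramp, for rapid events) of a parsed recording: transient
#' detection against the clamp setpoint baseline, two-line step estimation
#' on the servo trace, event typing (FC/R/F) and size classification
#' (S/E/C_S/C_E).  Step-fit windows are truncated at adjacent transients
#' and flagged.
#'
#' @param recording A drift-corrected `afm_recording`.
#' @param phases Output of [parse_phases()].
#' @param threshold Detection threshold in noise SDs.
#' @param step_window Step-fit window length (s).
#' @param accept_mask Optional logical vector (recycled) or function
#'   (`function(events) logical`) implementing a manual review mask; events
#'   with mask `FALSE` are dropped.
#' @return Data frame of class `tether_events`: `segment_index`,
#'   `event_type`, `shape`, `size_class`, `dz` (nm), transient parameters,
#'   and `flags`.
#' @export
detect_events <- function(recording, phases, threshold = 4,
                          step_window = 0.2, accept_mask = NULL) {
  stopifnot(inherits(recording, "afm_recording"))
  tt <- recording$times; vv <- recording$v_defl; zz <- recording$z_servo
  segs <- phases$segments
  sched <- recording$meta$schedule
  v_free <- recording$meta$v_free %||% 0
  all_ev <- list()
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    sel <- tt >= seg$t_start & tt < seg$t_end
    noise <- noise_sd_estimate(vv[sel])
    tr <- detect_transients(tt[sel], vv[sel], baseline = seg$setpoint_v,
                            noise_sd = noise, threshold = threshold)
    # rapid events on the preceding ramp, against the scheduled ramp line
    rmp <- sched[sched$phase == "ramp" & sched$index == seg$index, ,
                 drop = FALSE]
    if (nrow(rmp) == 1) {
      rsel <- tt >= rmp$t_start & tt < rmp$t_end
      if (sum(rsel) >= 20) {
        tr_t <- tt[rsel]
        line <- seq(vv[rsel][1], seg$setpoint_v, length.out = sum(rsel))
        rtr <- try(detect_transients(tr_t, vv[rsel] - line, baseline = 0,
                                     noise_sd = noise, threshold = threshold,
                                     baseline_window = diff(range(tr_t)) / 2),
                   silent = TRUE)
        if (!inherits(rtr, "try-error") && nrow(rtr))
          tr <- rbind(rtr, tr)
      }
    }
    if (!nrow(tr)) next
    tr <- tr[order(tr$t_start), ]
    types <- classify_event_type(tr, seg, tt, vv, v_free = v_free,
                                 noise_sd = noise)
    dz <- rep(NA_real_, nrow(tr))
    flags <- character(nrow(tr))
    for (j in seq_len(nrow(tr))) {
      if (types[j] == "R") { flags[j] <- "piezo_in_motion"; next }
      lim <- c(if (j > 1) tr$t_end[j - 1] else seg$t_start,
               if (j < nrow(tr)) tr$t_start[j + 1] else seg$t_end)
      s <- try(measure_step(tt, zz, tr$t_start[j], tr$t_end[j],
                            window = step_window, limits = lim),
               silent = TRUE)
      if (inherits(s, "try-error")) {
        flags[j] <- "step_unmeasurable"
      } else {
        dz[j] <- as.numeric(s)
        if (isTRUE(attr(s, "truncated"))) flags[j] <- "window_truncated"
      }
    }
    ev <- cbind(data.frame(segment_index = seg$index, event_type = types),
                tr, data.frame(dz = dz, flags = flags))
    all_ev[[length(all_ev) + 1]] <- ev
  }
  ev <- if (length(all_ev)) do.call(rbind, all_ev) else
    cbind(data.frame(segment_index = integer(0), event_type = character(0)),
          empty_transients(),
          data.frame(dz = numeric(0), flags = character(0)))
  ev$size_class <- classify_shape_and_size(ev$shape, ev$dz)
  if (!is.null(accept_mask)) {
    keep <- if (is.function(accept_mask)) accept_mask(ev)
            else rep_len(accept_mask, nrow(ev))
    ev <- ev[keep, , drop = FALSE]
  }
  rownames(ev) <- NULL
  class(ev) <- c("tether_events", "data.frame")
  ev
}
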