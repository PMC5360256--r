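#' Deflection-rise episodes paired with servo motion
#'
#' Finds sustained increases of the (smoothed) deflection trace after a
#' given time and pairs each with the concurrent servo height change.  Used
#' by the U-segment criteria: on a segment where the tip holds nothing, any
#' apparent deflection increase is an artefact of large servo travel and
#' comes with height increases of a micrometre or more.
#'
#' @param recording An `afm_recording`.
#' @param t_from Only consider samples at or after this time (s).
#' @param noise_sd Deflection noise SD (V); estimated when `NULL`.
#' @param min_rise Minimum deflection increase to count as an episode, in
#'   noise SDs (default 5).
#' @return Data frame with columns `t0`, `t1`, `dv` (V), `dz` (nm).
#' @export
deflection_rises <- function(recording, t_from = -Inf, noise_sd = NULL,
                             min_rise = 5) {
  sel <- recording$times >= t_from
  tt <- recording$times[sel]
  vv <- recording$v_defl[sel]
  zz <- recording$z_servo[sel]
  if (is.null(noise_sd)) noise_sd <- noise_sd_estimate(vv)
  k <- min(51, length(vv) - (1 - length(vv) %% 2))
  vs <- if (k >= 3) stats::runmed(vv, k) else vv
  # episodes between running minima and subsequent maxima
  d <- diff(vs) > 0
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j] + 1
    dv <- vs[i1] - vs[i0]
    if (dv >= min_rise * max(noise_sd, 1e-12))
      out[[length(out) + 1]] <- data.frame(t0 = tt[i0], t1 = tt[i1],
                                           dv = dv, dz = zz[i1] - zz[i0])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(t0 = numeric(0), t1 = numeric(0), dv = numeric(0),
               dz = numeric(0))
}

#' Flag a clamp segment as type U (uncertain / holding nothing)
#'
#' A segment is type U when the tip was plainly not pulling on anything:
#' (1) it shows no events after its setpoint was reached, (2) no following
#' segment of the recording shows events of any type, and (3) every
#' deflection increase during or after the segment is accompanied by a
#' servo height increase of about 1 um or more.
#'
#' @param segment One row of the `clamp_segments` table.
#' @param segments The full `clamp_segments` table of the recording.
#' @param events The `tether_events` table of the recording.
#' @param rises Deflection-rise episodes during/after the segment, from
#'   [deflection_rises()]; an empty frame satisfies criterion 3.
#' @param z_rise_min Minimum accompanying height increase (nm, default
#'   1000).
#' @return `TRUE` iff all three criteria hold.
#' @export
flag_U <- function(segment, segments, events, rises = NULL,
                   z_rise_min = 1000) {
  own <- events[events$segment_index == segment$index &
                  events$event_type != "R", , drop = FALSE]
  if (nrow(own)) return(FALSE)
  later <- events[events$segment_index > segment$index, , drop = FALSE]
  if (nrow(later)) return(FALSE)
  if (is.null(rises) || !nrow(rises)) return(TRUE)
  all(rises$dz >= z_rise_min)
}

#' Segment-selection cascade with audit trail
#'
#' Applies, in order, the data-selection rules that define the analysis
#' set: drop segments that (1) did not reach the target setpoint,
#' (2) have `F` > 1000 pN, (3) `F` < -200 pN, (4) `sigma_F` > 200 pN,
#' (5) `F` < 0 pN (push forces), and (6) are of type U.  Boundary values
#' are retained (the force rules are strict inequalities); `F = 0`
#' survives the cascade but is flagged.  Each excluded segment is
#' attributed to the first rule it fails.
#'
#' @param segments Data frame with columns `reached_setpoint`, `F`,
#'   `sigma_F`, `is_U` (and anything else, carried through).
#' @return List with `survivors` (the retained rows, plus a `status`
#'   column) and `report` (class `qc_report`: per-rule removal counts and
#'   remaining totals).
#' @export
filter_segments <- function(segments) {
  need <- c("reached_setpoint", "F", "sigma_F", "is_U")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments lack columns: ", paste(miss, collapse = ", "))
  rules <- list(
    did_not_reach_setpoint = function(s) !s$reached_setpoint,
    F_above_1000_pN        = function(s) !is.na(s$F) & s$F > 1000,
    F_below_minus200_pN    = function(s) !is.na(s$F) & s$F < -200,
    sigmaF_above_200_pN    = function(s) !is.na(s$sigma_F) & s$sigma_F > 200,
    F_below_0_pN           = function(s) !is.na(s$F) & s$F < 0,
    U_segment              = function(s) isTRUE_vec(s$is_U)
  )
  n <- nrow(segments)
  status <- rep("retained", n)
  counts <- data.frame(rule = names(rules), removed = NA_integer_,
                       remaining = NA_integer_)
  for (r in seq_along(rules)) {
    fails <- rules[[r]](segments) & status == "retained"
    status[fails] <- names(rules)[r]
    counts$removed[r] <- sum(fails)
    counts$remaining[r] <- sum(status == "retained")
  }
  segments$status <- status
  segments$flag_zero_force <- !is.na(segments$F) & segments$F == 0 &
    status == "retained"
  surv <- segments[status == "retained", , drop = FALSE]
  rep <- structure(list(counts = counts, n_input = n,
                        n_survivors = nrow(surv),
                        per_segment = status), class = "qc_report")
  list(survivors = surv, report = rep)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.qc_report <- function(x, ...) {
  cat("Segment-selection cascade:", x$n_input, "segments in,",
      x$n_survivors, "retained\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Push-force sanity diagnostic
#'
#' Counts segments in the push-force range (-200 pN <= F < 0, with
#' `sigma_F` <= 200 pN) and how many of them contain R or FC events.
#' Tether events are not expected at push forces; this diagnostic supports
#' removing `F < 0` segments without acting as a filter itself.
#'
#' @param segments Segment table with `F`, `sigma_F`.
#' @param events `tether_events` table.
#' @return List with `n_push_range` and `n_with_events`.
#' @export
push_force_diagnostic <- function(segments, events) {
  sel <- !is.na(segments$F) & segments$F >= -200 & segments$F < 0 &
    !is.na(segments$sigma_F) & segments$sigma_F <= 200
  idx <- segments$index[sel]
  withev <- vapply(idx, function(i)
    any(events$segment_index == i & events$event_type %in% c("R", "FC")),
    logical(1))
  list(n_push_range = sum(sel), n_with_events = sum(withev))
}
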