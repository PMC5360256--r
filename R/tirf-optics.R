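#' Evanescent excitation field model
#'
#' Constructs the parametric model of the TIRF evanescent excitation field
#' used both to simulate vesicle fluorescence and to invert measured
#' intensities into height changes.  Under total internal reflection the
#' excitation intensity decays exponentially with height `z` above the
#' coverslip, `I(z) = I0 * exp(-z / d_tirf)`, where `d_tirf` is the decay
#' (penetration) length of the field.
#'
#' @param I0 Intensity of a surface-attached emitter at `z = 0`
#'   (camera counts).
#' @param d_tirf Decay length of the evanescent field (nm).
#' @param I_background Background intensity (counts); the residual level once
#'   the emitter has left the evanescent field.
#' @param wavelength Excitation wavelength in vacuum (nm).
#' @param theta_i Illumination angle of incidence (degrees), must exceed the
#'   critical angle `asin(n2/n1)`.
#' @param n1,n2 Refractive indices of the dense (glass/oil) and rare
#'   (aqueous) media.
#' @return An object of class `evanescent_field`.
#' @examples
#' fld <- evanescent_field(I0 = 400, d_tirf = 102, I_background = 100)
#' intensity_at_height(fld, 102) # I0 / e
#' @export
evanescent_field <- function(I0 = 400, d_tirf = 102, I_background = 100,
                             wavelength = 488, theta_i = 66.8,
                             n1 = 1.515, n2 = 1.33) {
  stopifnot(d_tirf > 0, I0 > I_background, I_background >= 0,
            n1 > n2, wavelength > 0)
  crit <- asin(n2 / n1) * 180 / pi
  if (theta_i <= crit)
    stop("theta_i (", theta_i, " deg) is at or below the critical angle (",
         round(crit, 2), " deg): no evanescent decay")
  structure(list(I0 = I0, d_tirf = d_tirf, I_background = I_background,
                 wavelength = wavelength, theta_i = theta_i,
                 n1 = n1, n2 = n2),
            class = "evanescent_field")
}

#' @export
print.evanescent_field <- function(x, ...) {
  cat("Evanescent field: I0 =", x$I0, "counts, d_tirf =", x$d_tirf,
      "nm, background =", x$I_background, "counts\n")
  cat("  lambda =", x$wavelength, "nm, theta_i =", x$theta_i,
      "deg, n1 =", x$n1, ", n2 =", x$n2, "\n")
  invisible(x)
}

#' Vesicle fluorescence intensity at a given height
#'
#' Forward model of the evanescent excitation: a vesicle at height `z` above
#' the surface emits `I0 * exp(-z / d_tirf)` counts (background not
#' included).
#'
#' @param field An [evanescent_field()] object.
#' @param z Height(s) above the surface (nm), non-negative.
#' @return Vesicle intensity in counts (vectorised over `z`).
#' @export
intensity_at_height <- function(field, z) {
  stopifnot(inherits(field, "evanescent_field"))
  if (any(z < 0)) stop("negative height z is not allowed")
  field$I0 * exp(-z / field$d_tirf)
}

#' Height change from a TIRF intensity change
#'
#' Inverts the exponential evanescent decay to convert a background-corrected
#' intensity ratio into a change in vesicle height:
#' `dz = -d_tirf * log((I_f - I_background) / (I_i - I_background))`.
#' Positive values mean the vesicle moved away from the surface.
#'
#' When a background-subtracted intensity is not positive the vesicle is
#' outside the evanescent wave and no height can be assigned: the result is
#' `NA` with attribute `out_of_field` marking the affected entries, rather
#' than an error, so that whole traces can be converted at once.
#'
#' @param I_i,I_f Initial and final ROI intensities (counts).
#' @param I_background Background intensity (counts).
#' @param d_tirf Evanescent decay length (nm).
#' @return Height change(s) in nm; `NA` where the vesicle is out of the
#'   field, flagged in `attr(, "out_of_field")`.
#' @export
delta_z_tirf <- function(I_i, I_f, I_background, d_tirf) {
  stopifnot(d_tirf > 0)
  n <- max(length(I_i), length(I_f))
  num <- rep_len(I_f - I_background, n)
  den <- rep_len(I_i - I_background, n)
  bad <- !(num > 0 & den > 0)
  dz <- rep(NA_real_, n)
  ok <- !bad
  dz[ok] <- -d_tirf * log(num[ok] / den[ok])
  attr(dz, "out_of_field") <- bad
  dz
}

#' Theoretical evanescent decay length
#'
#' Computes the decay length of the evanescent field from first principles:
#' `d = lambda / (4 * pi * sqrt(n1^2 * sin(theta)^2 - n2^2))`.
#'
#' @param wavelength Excitation wavelength (nm).
#' @param theta_i Angle of incidence (degrees).
#' @param n1,n2 Refractive indices of dense and rare media.
#' @return Decay length in nm.
#' @examples
#' theoretical_decay_length(488, 66.8, 1.515, 1.33) # ~94 nm
#' @export
theoretical_decay_length <- function(wavelength, theta_i, n1 = 1.515,
                                     n2 = 1.33) {
  stopifnot(wavelength > 0, n1 > n2)
  s <- n1^2 * sin(theta_i * pi / 180)^2 - n2^2
  if (s <= 0)
    stop("theta_i at or below the critical angle: no evanescent decay")
  wavelength / (4 * pi * sqrt(s))
}

#' Calibrate the evanescent decay length from approach data
#'
#' Fits `I(z) = A * exp(-z / d) + B` to each approach series (intensity vs
#' cantilever height recorded while a tip-attached vesicle approaches the
#' surface) and aggregates the per-series decay constants by an
#' inverse-variance weighted RMS mean, with weights taken from the fit
#' covariance of each `d` estimate.
#'
#' Series that do not show a continuous intensity increase during the
#' approach (screened by the Spearman rank correlation between `z` and `I`)
#' are excluded and reported.
#'
#' @param approaches A list of data frames with columns `z` (nm) and `I`
#'   (counts), one per approach.
#' @param rho_max Maximum allowed Spearman correlation between `z` and `I`;
#'   approaches must show intensity increasing as height decreases, i.e.
#'   strongly negative correlation (default -0.5).
#' @return A list of class `decay_calibration` with elements `d_tirf`
#'   (weighted RMS mean, nm), `sd` (weighted spread, nm), `n` (series used),
#'   `per_series` (data frame of per-series estimates) and `excluded`
#'   (indices of screened-out series).
#' @export
calibrate_decay_length <- function(approaches, rho_max = -0.5) {
  if (!length(approaches)) stop("no approach series supplied")
  est <- lapply(seq_along(approaches), function(i) {
    s <- approaches[[i]]
    stopifnot(all(c("z", "I") %in% names(s)))
    if (nrow(s) < 5) return(list(i = i, ok = FALSE, why = "too few points"))
    rho <- suppressWarnings(stats::cor(s$z, s$I, method = "spearman"))
    if (!is.finite(rho) || rho > rho_max)
      return(list(i = i, ok = FALSE, why = "not monotonically increasing"))
    B0 <- min(s$I)
    A0 <- max(s$I) - B0
    d0 <- diff(range(s$z)) / 3
    fit <- try(minpack.lm::nlsLM(
      I ~ A * exp(-z / d) + B, data = s,
      start = list(A = A0, d = max(d0, 1), B = B0),
      lower = c(A = 0, d = 1e-6, B = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(i = i, ok = FALSE, why = "fit failed"))
    co <- stats::coef(fit)
    vc <- try(stats::vcov(fit), silent = TRUE)
    vd <- if (inherits(vc, "try-error")) NA_real_ else vc["d", "d"]
    list(i = i, ok = TRUE, d = unname(co["d"]), var_d = vd)
  })
  ok <- vapply(est, `[[`, logical(1), "ok")
  if (!any(ok))
    stop("all approach series were excluded: ",
         paste(vapply(est, `[[`, character(1), "why"), collapse = "; "))
  d <- vapply(est[ok], `[[`, numeric(1), "d")
  vd <- vapply(est[ok], `[[`, numeric(1), "var_d")
  # inverse-variance weights; degenerate (zero/NA variance) fits get the
  # largest finite weight present so that exact fits still dominate sanely
  w <- 1 / vd
  if (all(!is.finite(w))) w <- rep(1, length(d))
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  d_rms <- sqrt(sum(w * d^2) / sum(w))
  n <- length(d)
  spread <- if (n > 1)
    sqrt(sum(w * (d - d_rms)^2) / sum(w) * n / (n - 1)) else 0
  structure(list(
    d_tirf = d_rms, sd = spread, n = n,
    per_series = data.frame(series = vapply(est[ok], `[[`, numeric(1), "i"),
                            d = d, var_d = vd, weight = w),
    excluded = data.frame(
      series = vapply(est[!ok], `[[`, numeric(1), "i"),
      reason = vapply(est[!ok], `[[`, character(1), "why"))),
    class = "decay_calibration")
}

#' @export
print.decay_calibration <- function(x, ...) {
  cat(sprintf("d_tirf = %.1f +/- %.1f nm (weighted RMS mean +/- sd, n = %d)\n",
              x$d_tirf, x$sd, x$n))
  if (nrow(x$excluded))
    cat("excluded series:", paste(x$excluded$series, collapse = ", "), "\n")
  invisible(x)
}

#' Mean ROI intensity trace from an image stack
#'
#' Extracts the per-frame arithmetic mean of the `roi_size` x `roi_size`
#' pixel window centred on `center` (0-based pixel coordinates, `c(x, y)`),
#' the quantity used to follow a tip-attached vesicle through a recording.
#'
#' @param stack A `tirf_stack` object (see [simulate_tirf_stack()]) or a
#'   3-D array `[y, x, frame]`.
#' @param center 0-based pixel coordinates `c(x, y)` of the central pixel.
#' @param roi_size Odd window side length in pixels (default 3).
#' @param frame_times Optional frame time base (s); taken from the stack if
#'   available.
#' @return A data frame of class `intensity_trace` with columns `time` and
#'   `intensity`, and attributes `roi_center`, `roi_size`.
#' @export
roi_mean_intensity <- function(stack, center, roi_size = 3,
                               frame_times = NULL) {
  frames <- if (inherits(stack, "tirf_stack")) stack$frames else stack
  if (is.null(frame_times) && inherits(stack, "tirf_stack"))
    frame_times <- stack$frame_times
  stopifnot(length(dim(frames)) == 3, roi_size %% 2 == 1)
  ny <- dim(frames)[1]; nx <- dim(frames)[2]; nf <- dim(frames)[3]
  h <- (roi_size - 1) / 2
  cx <- center[1]; cy <- center[2]
  if (cx - h < 0 || cy - h < 0 || cx + h > nx - 1 || cy + h > ny - 1)
    stop("ROI window clipped by the frame edge")
  xs <- (cx - h):(cx + h) + 1L  # to 1-based array indices
  ys <- (cy - h):(cy + h) + 1L
  vals <- apply(frames[ys, xs, , drop = FALSE], 3, mean)
  if (is.null(frame_times)) frame_times <- seq_len(nf) - 1
  out <- data.frame(time = frame_times, intensity = vals)
  class(out) <- c("intensity_trace", "data.frame")
  attr(out, "roi_center") <- center
  attr(out, "roi_size") <- roi_size
  out
}

#' Compare servo-reported and TIRF-derived extension traces
#'
#' Converts an ROI intensity trace into height changes via the evanescent
#' decay model and pairs it, on the TIRF frame time base, with the servo
#' extension trace.  Agreement between the two identifies genuine
#' vesicle-membrane tether extensions; servo motion without an intensity
#' change indicates stretching of the tip-vesicle link instead.
#'
#' @param servo_times,dz_servo Servo extension trace: times (s) and
#'   extension relative to the reference time (nm).
#' @param trace An `intensity_trace` (see [roi_mean_intensity()]).
#' @param field An [evanescent_field()]; supplies `d_tirf`.
#' @param I_background Background level (counts); defaults to the field's.
#' @param t_ref Reference time for the initial intensity `I_i`; defaults to
#'   the first frame inside the overlap.
#' @return Data frame with columns `time`, `dz_servo`, `dz_tirf`,
#'   `difference` (`dz_servo - dz_tirf`); `dz_tirf` is `NA` (flagged via
#'   `attr(,"out_of_field")`) where the vesicle has left the field.
#' @export
compare_extension_traces <- function(servo_times, dz_servo, trace, field,
                                     I_background = NULL, t_ref = NULL) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(field, "evanescent_field"))
  if (is.null(I_background)) I_background <- field$I_background
  lo <- max(min(servo_times), min(trace$time))
  hi <- min(max(servo_times), max(trace$time))
  if (lo >= hi) stop("servo and intensity traces do not overlap in time")
  keep <- trace$time >= lo & trace$time <= hi
  tt <- trace$time[keep]
  I <- trace$intensity[keep]
  if (is.null(t_ref)) t_ref <- tt[1]
  I_i <- I[which.min(abs(tt - t_ref))]
  dz_t <- delta_z_tirf(I_i, I, I_background, field$d_tirf)
  dz_s <- stats::approx(servo_times, dz_servo, xout = tt, rule = 2)$y
  dz_s <- dz_s - dz_s[which.min(abs(tt - t_ref))]
  out <- data.frame(time = tt, dz_servo = dz_s, dz_tirf = as.numeric(dz_t),
                    difference = dz_s - as.numeric(dz_t))
  attr(out, "out_of_field") <- attr(dz_t, "out_of_field")
  out
}
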