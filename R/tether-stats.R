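#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval from the beta quantile construction:
#' lower = `qbeta(alpha/2; k, n-k+1)` (0 when `k = 0`),
#' upper = `qbeta(1-alpha/2; k+1, n-k)` (1 when `k = n`).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.68, the 1-sigma-like band used
#'   for binned event proportions).
#' @return Numeric vector `c(lo, hi)`.
#' @export
clopper_pearson <- function(k, n, conf = 0.68) {
  stopifnot(n >= 1, k >= 0, k <= n)
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

#' Binned proportion of segments with force-clamp events
#'
#' Sorts segments into fixed-width bins of time after cell lysis and, per
#' bin, reports the mean and SD of `t_lysis`, the number of segments, the
#' proportion `P_FC` of segments containing at least one FC event, and its
#' exact central binomial confidence interval.  Empty bins are omitted.
#'
#' @param t_lysis Time after lysis for each segment (min).
#' @param has_fc Logical: does the segment contain at least one FC event?
#' @param bin_width Bin width (min), default 10.
#' @param origin Left edge of the first bin (min), default 0.
#' @param conf Confidence level of the binomial interval (default 0.68).
#' @return Data frame with columns `bin_label`, `t_mean`, `t_sd`, `n`,
#'   `k`, `p_fc`, `ci_lo`, `ci_hi`.
#' @export
bin_proportions <- function(t_lysis, has_fc, bin_width = 10, origin = 0,
                            conf = 0.68) {
  stopifnot(length(t_lysis) == length(has_fc), bin_width > 0)
  bin <- floor((t_lysis - origin) / bin_width)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    n <- sum(sel); k <- sum(has_fc[sel])
    ci <- clopper_pearson(k, n, conf)
    data.frame(
      bin_label = sprintf("[%g, %g)", origin + b * bin_width,
                          origin + (b + 1) * bin_width),
      t_mean = mean(t_lysis[sel]),
      t_sd = if (n > 1) stats::sd(t_lysis[sel]) else 0,
      n = n, k = k, p_fc = k / n, ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, out)
}

#' Unweighted linear trend of binned proportions
#'
#' Ordinary (unweighted) least-squares regression of the per-bin event
#' proportion on the per-bin mean time after lysis.
#'
#' @param bins Output of [bin_proportions()] (needs >= 3 bins).
#' @return List with `slope` (min^-1), `intercept`, `slope_se`, and the
#'   underlying `lm` fit.
#' @export
linear_trend <- function(bins) {
  if (nrow(bins) < 3) stop("need at least 3 bins for a trend")
  fit <- stats::lm(p_fc ~ t_mean, data = bins)
  co <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
       slope_se = unname(co[2, 2]), fit = fit)
}

#' Poisson event rate with standard error
#'
#' `rate = n/T` with `se = sqrt(n)/T`, the usual Poisson counting error.
#'
#' @param n_events Integer event count.
#' @param duration Total observation (clamp) time (s).
#' @return List with `rate` and `se` (both s^-1).
#' @examples
#' event_rate(53, 221) # 0.240 +/- 0.033 events/s
#' @export
event_rate <- function(n_events, duration) {
  stopifnot(duration > 0)
  if (n_events != round(n_events) || n_events < 0)
    stop("n_events must be a non-negative integer")
  list(rate = n_events / duration, se = sqrt(n_events) / duration)
}

#' Exact two-sample Poisson rate test
#'
#' Tests equality of two Poisson rates observed as `n1` events in time `T1`
#' versus `n2` in `T2` by the exact conditional construction: given
#' `N = n1 + n2`, under the null `n1 ~ Binomial(N, T1/(T1+T2))`.  The
#' two-sided p-value doubles the smaller conditional tail (capped at 1).
#'
#' @param n1,n2 Event counts.
#' @param T1,T2 Observation durations (same units).
#' @return Two-sided p-value.
#' @examples
#' poisson_rate_test(19, 238, 11, 200) # ~0.42
#' @export
poisson_rate_test <- function(n1, T1, n2, T2) {
  stopifnot(T1 > 0, T2 > 0, n1 >= 0, n2 >= 0,
            n1 == round(n1), n2 == round(n2))
  N <- n1 + n2
  if (N == 0) return(1)
  p0 <- T1 / (T1 + T2)
  lower <- stats::pbinom(n1, N, p0)
  upper <- stats::pbinom(n1 - 1, N, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Histogram of tether-extension step sizes
#'
#' Counts step sizes into bins of fixed width centred on an arithmetic grid
#' (default: the 2.5-nm grid from -8.75 to 48.75 nm; negative bins absorb
#' measurement noise).  Bin membership uses half-open intervals
#' `[centre - w/2, centre + w/2)`; values outside the grid are ignored.
#' Count errors are `sqrt(n)`.
#'
#' @param dz Step sizes (nm).
#' @param width Bin width (nm).
#' @param first_center,last_center Centres of the first and last bin (nm).
#' @return Data frame of class `step_histogram` with columns `center`,
#'   `count`, `count_error`; attributes `width`, `n_in_range`.
#' @export
step_histogram <- function(dz, width = 2.5, first_center = -8.75,
                           last_center = 48.75) {
  stopifnot(width > 0, last_center >= first_center)
  centers <- seq(first_center, last_center, by = width)
  edges <- c(centers - width / 2, centers[length(centers)] + width / 2)
  dz <- dz[!is.na(dz)]
  idx <- findInterval(dz, edges, left.open = FALSE, rightmost.closed = FALSE)
  inr <- idx >= 1 & idx <= length(centers) & dz < edges[length(edges)]
  counts <- tabulate(idx[inr], nbins = length(centers))
  out <- data.frame(center = centers, count = counts,
                    count_error = sqrt(counts))
  attr(out, "width") <- width
  attr(out, "n_in_range") <- sum(inr)
  class(out) <- c("step_histogram", "data.frame")
  out
}

#' Gaussian fit to a step-size histogram peak
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the
#' (centre, count) pairs of a step histogram, unweighted, mirroring the
#' usual treatment of event-size distributions.  The standard error of the
#' peak position comes from the fit covariance.
#'
#' @param hist A [step_histogram()] (needs >= 4 non-zero bins).
#' @return List of class `gaussian_peak_fit`: `dz_peak` (nm),
#'   `dz_peak_se`, `sd_peak`, `amplitude`, and the `nls` fit object.
#' @export
fit_gaussian_peak <- function(hist) {
  stopifnot(inherits(hist, "step_histogram") || is.data.frame(hist))
  nz <- hist$count > 0
  if (sum(nz) < 4)
    stop("need at least 4 non-zero bins to fit a Gaussian peak")
  w <- hist$count / sum(hist$count)
  mu0 <- sum(hist$center * w)
  s0 <- sqrt(max(sum((hist$center - mu0)^2 * w), attr(hist, "width")^2 / 12,
                 0.5))
  A0 <- max(hist$count)
  fit <- try(minpack.lm::nlsLM(
    count ~ A * exp(-(center - mu)^2 / (2 * sigma^2)), data = hist,
    start = list(A = A0, mu = mu0, sigma = s0),
    lower = c(A = 0, mu = -Inf, sigma = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Gaussian peak fit did not converge: ", attr(fit, "condition")$message)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(dz_peak = unname(co["mu"]), dz_peak_se = unname(se["mu"]),
                 sd_peak = unname(co["sigma"]),
                 amplitude = unname(co["A"]), fit = fit),
            class = "gaussian_peak_fit")
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  cat(sprintf("Gaussian peak: dz_peak = %.1f +/- %.1f nm, SD = %.1f nm\n",
              x$dz_peak, x$dz_peak_se, x$sd_peak))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with an explicit error for degenerate
#' (zero-variance) input, used to verify independence of experimental
#' covariates such as time after lysis and pull force.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient `r`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Extension gained by unfolding an alpha-helix
#'
#' An unfolded polypeptide has a contour length of about 0.365 nm per
#' amino acid, while a folded alpha-helix rises only about 0.15 nm per
#' residue; unfolding therefore gains their difference (0.215 nm/residue).
#' Helices of 25-40 residues, the typical length in helical-bundle
#' tethering complexes, give 5.4-8.6 nm per unfolded helix.
#'
#' @param n_residues Number of residues (>= 0).
#' @param contour_per_aa Unfolded contour length per residue (nm).
#' @param rise_per_aa Folded helical rise per residue (nm).
#' @return Extension gain in nm.
#' @examples
#' helix_extension(1)  # 0.215 nm per residue
#' helix_extension(40) # 8.6 nm for a long helix
#' @export
helix_extension <- function(n_residues, contour_per_aa = 0.365,
                            rise_per_aa = 0.15) {
  if (any(n_residues < 0)) stop("n_residues must be non-negative")
  n_residues * (contour_per_aa - rise_per_aa)
}

#' Fully unfolded contour length of a polypeptide
#'
#' @param n_residues Number of residues (>= 0).
#' @param contour_per_aa Contour length per residue (nm).
#' @return Contour length in nm.
#' @examples
#' unfolded_contour(6216) # ~2.3 um for the whole eight-subunit exocyst
#' @export
unfolded_contour <- function(n_residues, contour_per_aa = 0.365) {
  if (any(n_residues < 0)) stop("n_residues must be non-negative")
  n_residues * contour_per_aa
}

#' Camera pixel size in the sample plane
#'
#' @param chip_pixel_um Physical pixel size on the camera chip (um).
#' @param magnification Objective magnification.
#' @return Pixel size in the sample plane (nm).
#' @examples
#' camera_pixel_size(16, 100) # 160 nm
#' @export
camera_pixel_size <- function(chip_pixel_um = 16, magnification = 100) {
  stopifnot(chip_pixel_um > 0, magnification > 0)
  chip_pixel_um / magnification * 1000
}
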