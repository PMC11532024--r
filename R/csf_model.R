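#' Truncated log-parabola contrast sensitivity function
#'
#' Parameter container for the four-parameter CSF model used throughout the
#' package: a log-parabola in log spatial frequency, truncated to a plateau
#' on the low-frequency side.
#'
#' @param gain Peak contrast sensitivity, linear units (reciprocal of the
#'   contrast threshold at the peak). Must exceed 1.
#' @param peak_sf Spatial frequency of peak sensitivity, cycles/degree.
#' @param bandwidth Full width at half-maximum sensitivity, octaves.
#' @param truncation Depth of the low-frequency plateau below the peak,
#'   log10 sensitivity units (>= 0).
#'
#' @return An object of class `csf_params`.
#' @examples
#' p <- csf_params(gain = 100, peak_sf = 2, bandwidth = 4, truncation = 0.5)
#' sensitivity(p, 2)   # 100 at the peak
#' @export
csf_params <- function(gain, peak_sf, bandwidth, truncation) {
  stopifnot(is.numeric(gain), is.numeric(peak_sf),
            is.numeric(bandwidth), is.numeric(truncation))
  if (!(gain > 1)) stop("gain must be > 1 (peak threshold below 100% contrast)")
  if (!(peak_sf > 0)) stop("peak_sf must be positive")
  if (!(bandwidth > 0)) stop("bandwidth must be positive")
  if (truncation < 0) stop("truncation must be >= 0")
  structure(list(gain = gain, peak_sf = peak_sf,
                 bandwidth = bandwidth, truncation = truncation),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "CSF: gain %.3g, peak %.3g c/deg, bandwidth %.3g oct, truncation %.3g\n",
    x$gain, x$peak_sf, x$bandwidth, x$truncation))
  invisible(x)
}

check_csf_params <- function(params) {
  if (!inherits(params, "csf_params"))
    stop("params must be a csf_params object")
  params
}

#' Log10 contrast sensitivity at a spatial frequency
#'
#' The model is a parabola in log2 spatial frequency with apex
#' `log10(gain)` at `peak_sf`, losing log10(2) (a factor of two in
#' sensitivity) at `bandwidth / 2` octaves from the peak.  Below the peak
#' the curve is floored at `log10(gain) - truncation`; the truncation never
#' applies above the peak.  Values may be negative: sensitivity below 1
#' means a threshold above 100% contrast.
#'
#' @param params A [csf_params()] object.
#' @param f Spatial frequency, cycles/degree (vectorised, all > 0).
#' @return log10 sensitivity, same length as `f`.
#' @export
log_sensitivity <- function(params, f) {
  check_csf_params(params)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("f must be positive and finite")
  lg <- log10(params$gain)
  d <- log2(f / params$peak_sf)
  parab <- lg - log10(2) * (2 * d / params$bandwidth)^2
  ifelse(f < params$peak_sf, pmax(parab, lg - params$truncation), parab)
}

#' Linear contrast sensitivity
#'
#' @inheritParams log_sensitivity
#' @return `10^log_sensitivity(params, f)`, strictly positive.
#' @export
sensitivity <- function(params, f) 10^log_sensitivity(params, f)

#' Contrast threshold (reciprocal sensitivity)
#'
#' May exceed 1 (threshold above full contrast) — this is reported as is,
#' not clamped, so that floor effects can be detected downstream.
#'
#' @inheritParams log_sensitivity
#' @return Threshold contrast as a Weber/Michelson fraction.
#' @export
threshold_contrast <- function(params, f) 1 / sensitivity(params, f)

#' Area under the log contrast sensitivity function
#'
#' Integrates `max(log10 sensitivity, 0)` over log10 spatial frequency
#' between `f_min` and `f_max` with a composite trapezoid rule.  Negative
#' log sensitivity (threshold above 100% contrast) contributes nothing.
#'
#' @inheritParams log_sensitivity
#' @param f_min,f_max Integration limits in cycles/degree, `0 < f_min < f_max`.
#' @param n Number of uniform points on the log10-SF axis (>= 512).
#' @return Area in log10-sensitivity x log10-SF units.
#' @export
aulcsf <- function(params, f_min, f_max, n = 1024L) {
  check_csf_params(params)
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max")
  n <- max(as.integer(n), 512L)
  x <- seq(log10(f_min), log10(f_max), length.out = n)
  y <- pmax(log_sensitivity(params, 10^x), 0)
  h <- (x[n] - x[1]) / (n - 1)
  h * (sum(y) - (y[1] + y[n]) / 2)
}

#' Cut-off spatial frequency
#'
#' The spatial frequency above the peak where threshold contrast reaches
#' `criterion` (default 0.5, i.e. sensitivity 2), found by bisection in
#' log10 frequency.  If sensitivity never falls to the criterion below
#' `f_max_search` the search bound is returned with `censored = TRUE`; if
#' the peak itself is below criterion, `peak_sf` is returned flagged
#' `"below-criterion-at-peak"`.
#'
#' @inheritParams log_sensitivity
#' @param criterion Threshold-contrast criterion in (0, 1].
#' @param f_max_search Upper search bound, cycles/degree (> peak_sf).
#' @param tol Bisection tolerance on log10 frequency.
#' @return A list with `cutoff` (cycles/degree), `censored` (logical) and
#'   `flag` (character, `"ok"`, `"censored"` or `"below-criterion-at-peak"`).
#' @export
cutoff_sf <- function(params, criterion = 0.5, f_max_search = 64,
                      tol = 1e-5) {
  check_csf_params(params)
  if (!(criterion > 0 && criterion <= 1)) stop("criterion must be in (0, 1]")
  if (!(f_max_search > params$peak_sf))
    stop("f_max_search must exceed peak_sf")
  target <- log10(1 / criterion)   # required log10 sensitivity
  if (log10(params$gain) < target - 1e-12)
    return(list(cutoff = params$peak_sf, censored = FALSE,
                flag = "below-criterion-at-peak"))
  if (log10(params$gain) <= target + 1e-12)   # criterion met at the peak
    return(list(cutoff = params$peak_sf, censored = FALSE, flag = "ok"))
  g <- function(lf) log_sensitivity(params, 10^lf) - target
  lo <- log10(params$peak_sf)
  hi <- log10(f_max_search)
  if (g(hi) > 0)
    return(list(cutoff = f_max_search, censored = TRUE, flag = "censored"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) lo <- mid else hi <- mid
  }
  list(cutoff = 10^((lo + hi) / 2), censored = FALSE, flag = "ok")
}

#' Geometric spatial-frequency grid
#'
#' The test grid is geometric: constant ratio `(f_max/f_min)^(1/(n-1))`
#' between consecutive frequencies, endpoints exact.
#'
#' @param f_min,f_max Range in cycles/degree, `0 < f_min < f_max`.
#' @param n_levels Number of frequencies (>= 2).
#' @return An object of class `sf_grid` with fields `f_min`, `f_max`,
#'   `n_levels`, `values`.
#' @examples
#' g <- make_sf_grid(0.31, 11.77, 12)
#' format_sf(g$values)   # printed labels, e.g. "0.83", "1.16"
#' @export
make_sf_grid <- function(f_min, f_max, n_levels) {
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  v <- f_min * (f_max / f_min)^((seq_len(n_levels) - 1L) / (n_levels - 1L))
  v[1] <- f_min
  v[n_levels] <- f_max
  structure(list(f_min = f_min, f_max = f_max, n_levels = n_levels,
                 values = v), class = "sf_grid")
}

#' @export
print.sf_grid <- function(x, ...) {
  cat(sprintf("SF grid: %d levels, %s c/deg\n", x$n_levels,
              paste(format_sf(x$values), collapse = " ")))
  invisible(x)
}

#' Display labels for spatial frequencies
#'
#' Frequencies are labelled truncated (floored) to two decimals, the
#' convention used on the test grid (0.8359 prints as "0.83", 1.6197 as
#' "1.61").
#'
#' @param f Spatial frequencies, cycles/degree.
#' @return Character vector of labels.
#' @export
format_sf <- function(f) sprintf("%.2f", floor(f * 100 + 1e-9) / 100)
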