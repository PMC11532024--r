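#' Band-pass filtered noise stimuli
#'
#' Stimuli are represented as matrices of luminance deviation from the
#' background, in Weber fraction units: 0 is the background, +1 is
#' double the background luminance.  Metadata (pixels per degree, nominal
#' frequency, polarity, orientation, nominal contrast, seed) travel as
#' attributes under class `stimulus_image`.
#'
#' @name stimulus_image
NULL

new_stimulus_image <- function(px, ppd, nominal_sf, polarity, orientation,
                               nominal_contrast, seed, sigma_deg = NA_real_) {
  structure(px, class = c("stimulus_image", "matrix", "array"),
            ppd = ppd, nominal_sf = nominal_sf, polarity = polarity,
            orientation = orientation, nominal_contrast = nominal_contrast,
            seed = seed, sigma_deg = sigma_deg)
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf(
    "stimulus: %dx%d px, %.3g c/deg, %s, %s, contrast %.3g, %.3g px/deg\n",
    nrow(x), ncol(x), attr(x, "nominal_sf"), attr(x, "polarity"),
    attr(x, "orientation"), attr(x, "nominal_contrast"), attr(x, "ppd")))
  invisible(x)
}

# Gabor spatial sigma (degrees) from half-amplitude bandwidth in octaves:
# the half-amplitude half-width of the Gabor's Gaussian spectrum is
# sqrt(2 ln 2) / (2 pi sigma_x); a bandwidth of b octaves places the
# half-amplitude points at f (2^b - 1)/(2^b + 1) either side of f.
gabor_sigma_deg <- function(sf, octave_bandwidth) {
  k <- (2^octave_bandwidth - 1) / (2^octave_bandwidth + 1)
  sqrt(2 * log(2)) / (2 * pi * k * sf)
}

# 2-D circular convolution via FFT (kernel centred).
fft_convolve <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  kpad <- matrix(0, n, m)
  kn <- nrow(kernel); km <- ncol(kernel)
  kpad[1:kn, 1:km] <- kernel
  # centre the kernel at (1, 1) so convolution does not translate
  ci <- (kn + 1) %/% 2; cj <- (km + 1) %/% 2
  kpad <- kpad[c(ci:n, seq_len(ci - 1)), c(cj:m, seq_len(cj - 1))]
  Re(stats::fft(stats::fft(img) * stats::fft(kpad), inverse = TRUE)) / (n * m)
}

#' Balanced band-pass noise from a Gabor-filtered white-noise field
#'
#' White Gaussian noise is convolved with an oriented Gabor kernel whose
#' half-amplitude spectral full width is `octave_bandwidth` octaves, then
#' mean-subtracted and peak-normalised to +/- 1.  A `"vertical"` stimulus
#' carries luminance modulation along the horizontal axis (vertical
#' stripes); `"horizontal"` is its exact transpose for the same seed.
#'
#' @param sf Centre spatial frequency, cycles/degree (below Nyquist,
#'   `ppd / 2`).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param size_px Image side, pixels.
#' @param ppd Pixels per degree.
#' @param octave_bandwidth Filter half-amplitude bandwidth, octaves.
#' @param seed Integer seed for the noise field.
#' @return A balanced, unit-normalised `stimulus_image`.
#' @export
make_bandpass_noise <- function(sf, orientation = c("vertical", "horizontal"),
                                size_px = 256L, ppd = 32,
                                octave_bandwidth = 1.84, seed = 1L) {
  orientation <- match.arg(orientation)
  if (sf >= ppd / 2) stop("sf must be below the Nyquist frequency ppd/2")
  if (size_px / ppd * sf < 4)
    stop("image too small: fewer than 4 cycles at this frequency")
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(size_px^2), size_px, size_px)
  sigma_px <- gabor_sigma_deg(sf, octave_bandwidth) * ppd
  half <- max(3L, ceiling(3 * sigma_px))
  u <- (-half):half
  gauss <- exp(-u^2 / (2 * sigma_px^2))
  carrier <- cos(2 * pi * sf / ppd * u)
  # separable oriented Gabor: modulation along x, Gaussian along y
  kernel <- outer(gauss, gauss * carrier)
  img <- fft_convolve(noise, kernel)
  img <- img - mean(img)
  img <- img / max(abs(img))
  if (orientation == "horizontal") img <- t(img)
  new_stimulus_image(img, ppd, sf, "balanced", orientation,
                     nominal_contrast = 1, seed = as.integer(seed))
}

#' Apply a Gaussian spatial window
#'
#' Pixelwise multiplication by `exp(-r^2 / (2 sigma^2))` centred on the
#' image; background pixels (0) are unchanged.
#'
#' @param img A `stimulus_image`.
#' @param sigma_deg Window sigma in degrees (> 0).
#' @return The windowed `stimulus_image`.
#' @export
apply_gaussian_window <- function(img, sigma_deg) {
  stopifnot(inherits(img, "stimulus_image"), sigma_deg > 0)
  ppd <- attr(img, "ppd")
  n <- nrow(img); m <- ncol(img)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  xs <- (seq_len(n) - cx) / ppd
  ys <- (seq_len(m) - cy) / ppd
  env <- exp(-outer(xs^2, ys^2, `+`) / (2 * sigma_deg^2))
  out <- unclass(img) * env
  attrs <- attributes(img)
  attributes(out) <- attrs
  attr(out, "sigma_deg") <- sigma_deg
  out
}

#' Set stimulus polarity and calibrate contrast
#'
#' From a balanced (zero-mean, +/- 1 normalised) image: `"balanced"`
#' rescales so the peak absolute deviation equals `nominal_contrast`;
#' `"increment"` half-wave rectifies (positive lobes only) and rescales so
#' the maximum equals `nominal_contrast`; `"decrement"` keeps the negative
#' lobes and rescales so the minimum equals `-nominal_contrast`.
#'
#' @param img A balanced `stimulus_image`.
#' @param mode `"balanced"`, `"increment"` or `"decrement"`.
#' @param nominal_contrast Peak Weber contrast in (0, 1].
#' @return The polarised, calibrated `stimulus_image`.
#' @export
polarize <- function(img, mode = c("balanced", "increment", "decrement"),
                     nominal_contrast) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "stimulus_image"))
  if (!(nominal_contrast > 0 && nominal_contrast <= 1))
    stop("nominal_contrast must be in (0, 1]")
  if (attr(img, "polarity") != "balanced")
    stop("polarize expects a balanced input image")
  px <- unclass(img)
  px <- switch(mode,
    balanced  = px / max(abs(px)) * nominal_contrast,
    increment = {
      p <- pmax(px, 0)
      p / max(p) * nominal_contrast
    },
    decrement = {
      p <- pmin(px, 0)
      p / abs(min(p)) * nominal_contrast
    })
  out <- px
  attributes(out) <- attributes(img)
  attr(out, "polarity") <- mode
  attr(out, "nominal_contrast") <- nominal_contrast
  out
}

#' Measure stimulus contrast
#'
#' @param img A `stimulus_image`.
#' @return A list with `peak_weber` (max absolute deviation) and `rms`
#'   (standard deviation of the pixel deviations).
#' @export
measure_contrast <- function(img) {
  px <- as.vector(unclass(img))
  list(peak_weber = max(abs(px)), rms = stats::sd(px))
}

#' Radial amplitude spectrum
#'
#' Diagnostic used to verify the passband of synthesised stimuli: the FFT
#' amplitude integrated over annuli of radial frequency (for an oriented
#' passband this profile peaks at the filter's centre frequency; a plain
#' per-pixel annulus mean would be biased low by the growing annulus
#' circumference).
#'
#' @param img A `stimulus_image`.
#' @return Data frame with columns `f_cpd` and `amplitude`.
#' @export
radial_spectrum <- function(img) {
  n <- nrow(img)
  am <- Mod(stats::fft(unclass(img)))
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n  # cycles/pixel
  r <- sqrt(outer(fx^2, fx^2, `+`)) * attr(img, "ppd")  # cycles/degree
  breaks <- seq(0, max(r), length.out = n %/% 2)
  bins <- cut(as.vector(r), breaks = breaks, include.lowest = TRUE)
  amp <- tapply(as.vector(am), bins, sum)
  amp[is.na(amp)] <- 0
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  data.frame(f_cpd = mid, amplitude = as.vector(amp))
}

#' Export a stimulus as an 8-bit PNG with a JSON sidecar
#'
#' The background (0) maps to mid-grey (128/255); deviations are scaled by
#' Weber contrast so +1 maps to white.  The sidecar records seed,
#' frequency, polarity, orientation and measured contrasts.
#'
#' @param img A `stimulus_image`.
#' @param path Output PNG path; the sidecar is written alongside with
#'   extension `.json`.
#' @return Invisibly, the sidecar list.
#' @export
write_stimulus_png <- function(img, path) {
  px <- unclass(img)
  gray <- pmin(pmax((px + 1) / 2, 0), 1)
  png::writePNG(gray, target = path)
  mc <- measure_contrast(img)
  sidecar <- list(seed = attr(img, "seed"), sf_cpd = attr(img, "nominal_sf"),
                  polarity = attr(img, "polarity"),
                  orientation = attr(img, "orientation"),
                  nominal_contrast = attr(img, "nominal_contrast"),
                  peak_weber = mc$peak_weber, rms = mc$rms,
                  min_pixel = min(px), max_pixel = max(px),
                  ppd = attr(img, "ppd"), size_px = dim(px))
  jsonlite::write_json(sidecar, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
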