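#' Minimum R-R interval implied by a heart-rate ceiling
#'
#' The R-wave detector refuses peaks closer together than the shortest
#' plausible cardiac cycle. For a ceiling of 110 beats per minute this is
#' 60/110 = 0.545 s.
#'
#' @param max_bpm Heart-rate ceiling in beats per minute.
#' @return Minimum R-R interval in seconds.
#' @export
#' @examples
#' min_rr_interval(110)
min_rr_interval <- function(max_bpm = 110) {
  stopifnot(is.numeric(max_bpm), max_bpm > 0)
  60 / max_bpm
}

#' Frame exposure expressed in biosignal samples
#'
#' At a video frame rate `fps` and biosignal sampling rate `fs`, one frame
#' period (and, in the acquisition system emulated here, the exposure time)
#' spans `fs / fps` biosignal samples: 40 samples at 25 fps and 1000 Hz.
#'
#' @param fs Biosignal sampling rate in Hz.
#' @param fps Video frame rate in Hz.
#' @return Integer number of samples per frame.
#' @export
#' @examples
#' exposure_samples(1000, 25)
exposure_samples <- function(fs = 1000, fps = 25) {
  stopifnot(fs > 0, fps > 0)
  as.integer(round(fs / fps))
}

#' Retinal irradiance of the illuminated field
#'
#' Dosimetry helper for the emulated acquisition geometry: a light power
#' `power_uW` (measured in the pupil plane) spread over a retinal field of
#' `field_mm[1] x field_mm[2]` millimetres. The study's numbers — 15 uW over
#' a 6 x 5 mm field (0.3 cm^2) — give 50 uW/cm^2.
#'
#' @param power_uW Light power in microwatts.
#' @param field_mm Length-2 numeric, illuminated retinal field in mm.
#' @return Irradiance in uW/cm^2.
#' @export
#' @examples
#' retinal_irradiance(15, c(6, 5))
retinal_irradiance <- function(power_uW = 15, field_mm = c(6, 5)) {
  stopifnot(power_uW >= 0, length(field_mm) == 2, all(field_mm > 0))
  area_cm2 <- prod(field_mm / 10)
  power_uW / area_cm2
}

# ---- 1-D filters ------------------------------------------------------------

# Reflect padding (edge sample repeated into the mirror): c b a | a b c ...
reflect_pad <- function(x, left, right = left) {
  n <- length(x)
  lp <- if (left > 0) x[pmin(n, left:1)] else numeric(0)
  rp <- if (right > 0) x[pmax(1, n:(n - right + 1))][seq_len(right)] else numeric(0)
  c(lp, x, rp)
}

#' Median filter (sliding window, reflect padding)
#'
#' Windows of even length are supported (the study's ECG prefilter uses
#' size 10); the window then sits one sample left of centre and the median
#' of an even count is the mean of the two central order statistics.
#'
#' @param x Numeric vector.
#' @param size Window length in samples.
#' @return Filtered vector, same length as `x`.
#' @export
median_filter <- function(x, size) {
  stopifnot(is.numeric(x), size >= 1)
  if (size == 1 || length(x) == 1) return(x)
  as.numeric(.run_median(as.numeric(x), as.integer(size)))
}

#' Gaussian smoothing filter
#'
#' Convolution with a normalised Gaussian kernel truncated at 4 standard
#' deviations, reflect padding at the boundaries.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in samples.
#' @return Smoothed vector, same length as `x`.
#' @export
gaussian_filter <- function(x, sigma) {
  stopifnot(is.numeric(x), sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  xp <- reflect_pad(as.numeric(x), r)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(r + 1):(r + length(x))])
}

# Centred moving average with reflect padding; n must be odd.
moving_average_filter <- function(x, n) {
  stopifnot(n %% 2 == 1, n >= 1)
  if (n == 1) return(as.numeric(x))
  r <- (n - 1) / 2
  xp <- reflect_pad(as.numeric(x), r)
  out <- stats::filter(xp, rep(1 / n, n), sides = 2)
  as.numeric(out[(r + 1):(r + length(x))])
}

# ---- robust local maxima detector -------------------------------------------

# Local maxima with plateau handling: a run of equal values flanked by lower
# values is one peak reported at the run's first sample (earlier tie-break).
local_maxima <- function(x, boundary = FALSE) {
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 2) return(integer(0))
  starts <- cumsum(c(1, r$lengths[-nr]))
  peaks <- integer(0)
  if (nr >= 3) {
    j <- 2:(nr - 1)
    is_peak <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    peaks <- starts[j][is_peak]
  }
  if (boundary) {
    if (r$values[1] > r$values[2]) peaks <- c(1L, peaks)
    if (r$values[nr] > r$values[nr - 1]) peaks <- c(peaks, starts[nr])
  }
  sort(peaks)
}

# Topographic prominence of peak at index p: height above the higher of the
# two key saddles (minimum between the peak and the nearest higher ground on
# each side; the signal end if none).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    li <- if (p > 1) seq(p - 1, 1) else integer(0)
    higher <- li[x[li] > h]
    lmin <- if (length(higher)) min(x[seq(p - 1, higher[1])]) else
      if (length(li)) min(x[li]) else h
    ri <- if (p < length(x)) seq(p + 1, length(x)) else integer(0)
    higher <- ri[x[ri] > h]
    rmin <- if (length(higher)) min(x[seq(p + 1, higher[1])]) else
      if (length(ri)) min(x[ri]) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Robust local maxima detection
#'
#' Peak picking with an absolute height threshold, a topographic prominence
#' requirement, and a minimum peak separation. Peaks are kept greedily from
#' the highest down; among equal heights the earlier peak wins. A plateau of
#' equal samples counts as a single peak at its first sample.
#'
#' @param x Numeric vector.
#' @param threshold Minimum peak height (`NULL` to skip).
#' @param prominence Minimum topographic prominence (`NULL` to skip).
#' @param min_distance Minimum separation between kept peaks, in samples
#'   (`NULL` to skip). Peaks exactly `min_distance` apart are both kept.
#' @param boundary Also consider the first/last sample a peak when it
#'   exceeds its single neighbour (used for edge detection on a
#'   first-order difference).
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, threshold = NULL, prominence = NULL,
                       min_distance = NULL, boundary = FALSE) {
  x <- as.numeric(x)
  peaks <- local_maxima(x, boundary = boundary)
  if (!is.null(threshold)) peaks <- peaks[x[peaks] >= threshold]
  if (length(peaks) && !is.null(prominence)) {
    peaks <- peaks[peak_prominence(x, peaks) >= prominence]
  }
  if (length(peaks) > 1 && !is.null(min_distance)) {
    ord <- peaks[order(-x[peaks], peaks)]
    keep <- integer(0)
    for (p in ord) {
      if (!length(keep) || all(abs(keep - p) >= min_distance)) {
        keep <- c(keep, p)
      }
    }
    peaks <- sort(keep)
  }
  as.integer(peaks)
}
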