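# Phase-correlation translation estimate of `img` relative to `ref`
# (positive dy/dx: img content moved down/right). The integer shift comes
# from the whitened cross-power spectrum (sharp, unambiguous peak); the
# sub-pixel refinement fits a parabola to the plain cross-correlation
# around that peak, whose broad lobe is stable under pixel noise (the
# whitened peak is a delta whose neighbours carry no signal).
phase_corr_shift <- function(ref, img) {
  # Hann window: suppresses the non-periodic boundary mismatch that would
  # otherwise dominate the whitened spectrum's low-energy bins
  h <- nrow(ref); w <- ncol(ref)
  win <- outer(0.5 - 0.5 * cos(2 * pi * seq_len(h) / (h + 1)),
               0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1)))
  ref <- (ref - mean(ref)) * win
  img <- (img - mean(img)) * win
  F1 <- fft(ref); F2 <- fft(img)
  R <- F1 * Conj(F2)
  # regularized whitening: bins with negligible cross-power (noise-only,
  # outside the image band) are damped instead of amplified to unit weight
  eps <- 1e-2 * mean(Mod(R))
  r_pc <- Re(fft(R / (Mod(R) + eps), inverse = TRUE)) / length(R)
  r_cc <- Re(fft(R, inverse = TRUE)) / length(R)
  pk <- which(r_pc == max(r_pc), arr.ind = TRUE)[1, ]
  h <- nrow(r_pc); w <- ncol(r_pc)
  subpix <- function(vals) {
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den >= 0 || vals[2] < max(vals[1], vals[3])) return(0)
    max(-0.5, min(0.5, 0.5 * (vals[1] - vals[3]) / den))
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- subpix(r_cc[wrap(pk[1] + c(-1, 0, 1), h), pk[2]])
  dx <- subpix(r_cc[pk[1], wrap(pk[2] + c(-1, 0, 1), w)])
  to_signed <- function(i, n) if (i - 1 > n / 2) i - 1 - n else i - 1
  # sign convention: positive dy/dx means img content moved down/right
  c(dy = -(to_signed(pk[1], h) + dy), dx = -(to_signed(pk[2], w) + dx))
}

# Translate a matrix by a real-valued (dy, dx) using bilinear
# interpolation, replicating edge pixels; exact for integer shifts.
shift_matrix_subpix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  yi <- seq_len(h) - dy
  xi <- seq_len(w) - dx
  y0 <- pmin(pmax(floor(yi), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xi), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yi - y0, 0), 1);   fx <- pmin(pmax(xi - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' Align frames to the first frame
#'
#' Translation-only registration of every frame to the first frame by
#' phase correlation with sub-pixel refinement; frames are shifted back by
#' the sub-pixel estimate using bilinear interpolation (edge pixels
#' replicated; exact for integer shifts). The rotational
#' vessel-tracking registration used for clinical sequences is out of
#' scope; this removes the translational component, which dominates at the
#' optic nerve head over a 10-15 s recording.
#'
#' @param video A [vp_video()].
#' @return A list with `video` (aligned) and `shifts`, a tibble with
#'   columns `frame`, `dy`, `dx` (estimated sub-pixel shifts).
#' @export
align_frames <- function(video) {
  stopifnot(inherits(video, "vp_video"))
  if (video$n_frames < 2) {
    abort("need at least 2 frames to align.", class = "veinpulse_input_error")
  }
  ref <- video$frames[, , 1]
  if (sd(ref) == 0) {
    warn("reference frame is constant; alignment skipped.")
    return(list(video = video,
                shifts = tibble(frame = seq_len(video$n_frames), dy = 0, dx = 0)))
  }
  n <- video$n_frames
  shifts <- matrix(0, n, 2)
  out <- video$frames
  for (i in seq(2, n)) {
    fr <- video$frames[, , i]
    if (sd(fr) == 0) next
    s <- phase_corr_shift(ref, fr)
    shifts[i, ] <- s
    if (any(abs(s) > 1e-3)) out[, , i] <- shift_matrix_subpix(fr, -s[1], -s[2])
  }
  list(video = vp_video(out, video$valid),
       shifts = tibble(frame = seq_len(n), dy = shifts[, 1], dx = shifts[, 2]))
}

#' Distance of each frame to its local median image
#'
#' For frame i, the median image is computed pixel-wise over a window of
#' `window` frames centred on i (truncated at the sequence boundaries;
#' frame i itself included), and the Euclidean distance between frame i
#' and that median image is returned. Distorted frames (blinks, blurs)
#' stand out because they differ from the median of their neighbourhood.
#'
#' @param video A [vp_video()].
#' @param window Window length in frames (71 in the study).
#' @return Numeric vector of per-frame distances.
#' @export
local_median_distance <- function(video, window = 71) {
  stopifnot(inherits(video, "vp_video"), window >= 1)
  px <- matrix(video$frames, video$height * video$width, video$n_frames)
  as.numeric(.ed_local_median(px, as.integer(window)))
}

#' Rosner's generalized extreme Studentized deviate test
#'
#' Iteratively removes the value furthest from the mean (in standard
#' deviations), computing the test statistic `R_j` at each step and
#' comparing it to the critical value `lambda_j` built from Student-t
#' quantiles at level `alpha`; the declared outliers are the first `j*`
#' removals, where `j*` is the largest step with `R_j > lambda_j`. Suited
#' to approximately normal data with up to `max_outliers` outliers.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level.
#' @param max_outliers Upper bound on the number of outliers tested
#'   (must be < `length(values)/2`).
#' @return Integer indices of the detected outliers (original positions),
#'   increasing; empty if none.
#' @export
#' @examples
#' gesd_test(c(1.0, 1.1, 0.9, 1.05, 12.0), alpha = 0.05, max_outliers = 2)
gesd_test <- function(values, alpha = 0.05, max_outliers) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) abort("need at least 3 values.", class = "veinpulse_input_error")
  max_outliers <- as.integer(max_outliers)
  if (max_outliers < 1 || max_outliers >= n / 2) {
    abort("max_outliers must be in [1, length(values)/2).",
          class = "veinpulse_input_error")
  }
  idx <- seq_len(n)
  removed <- integer(0)
  R <- lambda <- numeric(0)
  for (j in seq_len(max_outliers)) {
    m <- mean(x); s <- sd(x)
    if (s == 0) break
    dev <- abs(x - m)
    i_max <- which.max(dev)
    R[j] <- dev[i_max] / s
    nn <- n - j + 1                       # sample size at this step
    p <- 1 - alpha / (2 * nn)
    tq <- qt(p, nn - 2)
    lambda[j] <- (nn - 1) * tq / sqrt((nn - 2 + tq^2) * nn)
    removed[j] <- idx[i_max]
    x <- x[-i_max]; idx <- idx[-i_max]
  }
  n_out <- if (length(R)) max(c(0L, which(R > lambda))) else 0L
  sort(removed[seq_len(n_out)])
}

#' Detect distorted (blink or blurred) frames
#'
#' Composes [local_median_distance()] (window 71) with [gesd_test()] on
#' the per-frame distances; flagged frames are marked invalid. An optional
#' `manual_bad` index list replaces the study's manual refinement by
#' visual inspection.
#'
#' @param video A [vp_video()] (aligned).
#' @param alpha GESD significance level.
#' @param max_outliers Outlier cap; defaults to `ceiling(0.1 * n_frames)`
#'   (blinks rarely exceed 10% of frames).
#' @param window Median-image window in frames.
#' @param manual_bad Extra frame indices to mark invalid.
#' @return A list with `video` (validity updated) and `report`, a tibble
#'   with columns `frame`, `ed`, `flagged`; attributes `alpha` and
#'   `max_outliers`.
#' @export
detect_distorted_frames <- function(video, alpha = 0.05, max_outliers = NULL,
                                    window = 71, manual_bad = integer(0)) {
  stopifnot(inherits(video, "vp_video"))
  if (video$n_frames < 10) {
    abort("need at least 10 frames for distortion detection.",
          class = "veinpulse_input_error")
  }
  max_outliers <- max_outliers %||% ceiling(0.1 * video$n_frames)
  ed <- local_median_distance(video, window)
  out <- gesd_test(ed, alpha = alpha, max_outliers = max_outliers)
  flagged <- sort(union(out, as.integer(manual_bad)))
  valid <- video$valid
  valid[flagged] <- FALSE
  report <- tibble(frame = seq_len(video$n_frames), ed = ed,
                   flagged = seq_len(video$n_frames) %in% flagged)
  attr(report, "alpha") <- alpha
  attr(report, "max_outliers") <- max_outliers
  list(video = vp_video(video$frames, valid), report = report)
}

#' Extract the vein pulsation signal from a video
#'
#' Mean intensity of every frame over the vein ROI pixels — the raw vein
#' pulsation signal I_VP(n). Invalid frames are included (they are
#' interpolated downstream); their validity travels in the `valid` column.
#'
#' @param video A [vp_video()].
#' @param roi Logical (or 0/1) matrix with the frame geometry; `TRUE`
#'   pixels belong to the vein ROI.
#' @return Tibble with columns `frame`, `i_vp`, `valid`.
#' @export
extract_vp_signal <- function(video, roi) {
  stopifnot(inherits(video, "vp_video"))
  roi <- roi > 0
  if (!identical(dim(roi), c(video$height, video$width))) {
    abort("ROI mask shape does not match the frames.",
          class = "veinpulse_input_error")
  }
  if (!any(roi)) abort("empty ROI mask.", class = "veinpulse_input_error")
  px <- matrix(video$frames, video$height * video$width, video$n_frames)
  tibble(frame = seq_len(video$n_frames),
         i_vp = colMeans(px[as.vector(roi), , drop = FALSE]),
         valid = video$valid)
}
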