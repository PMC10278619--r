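#' Video sequence container
#'
#' A minimal container for an ordered grayscale frame stack: a
#' `height x width x n_frames` numeric array of intensities on the [0, 1]
#' scale plus a per-frame validity flag.
#'
#' @param frames 3-D numeric array (`h x w x n`) or a list of equally sized
#'   matrices.
#' @param valid Logical vector of length `n`; defaults to all `TRUE`.
#' @return A `vp_video` object.
#' @export
vp_video <- function(frames, valid = NULL) {
  if (is.list(frames)) {
    dims <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1)))) {
      abort("all frames must have the same shape.", class = "veinpulse_input_error")
    }
    frames <- array(unlist(frames), dim = c(dims, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[3]
  valid <- valid %||% rep(TRUE, n)
  stopifnot(length(valid) == n)
  structure(list(frames = frames, valid = valid,
                 n_frames = n, height = dim(frames)[1], width = dim(frames)[2]),
            class = "vp_video")
}

#' @export
print.vp_video <- function(x, ...) {
  cat(sprintf("<vp_video> %d frames, %d x %d px, %d flagged invalid\n",
              x$n_frames, x$height, x$width, sum(!x$valid)))
  invisible(x)
}

# Translate a matrix by integer (dy, dx) pixels, replicating edge rows/cols.
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Render a synthetic fundus video with a pulsating vein
#'
#' Renders, per frame, a static textured background crossed by a dark
#' curvilinear vein whose local width is modulated so that the mean
#' intensity over the vein ROI follows the analytic trace of
#' [generate_vp_trace()]: narrow (bright ROI) at vein collapse, widest half
#' a cycle later. Optionally injects `blink_count` near-black frames at
#' recorded indices and small integer per-frame translations for
#' exercising alignment. The true vein ROI mask is returned alongside.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_ecg()].
#' @return A list with `video` (a [vp_video()]), `roi_mask` (logical
#'   matrix) and the updated `truth` (blink indices in
#'   `distorted_frame_indices`, injected shifts in `shifts`).
#' @export
generate_video <- function(config, truth) {
  validate_sim_config(config)
  h <- config$frame_size[1]; w <- config$frame_size[2]
  if (h < 64 || w < 64) {
    abort("frame_size must be at least 64 x 64 px.",
          class = "veinpulse_config_error")
  }
  vt <- generate_vp_trace(config, truth)
  truth <- vt$truth
  n_frames <- nrow(vt$trace)
  tt <- vt$trace$time_s
  v <- vein_volume_waveform(tt, truth)
  gain <- truth$illumination_profile

  with_sim_rng(config$seed + 2L, {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    ph <- runif(4, 0, 2 * pi)
    bg <- 0.55 +
      0.05 * sin(2 * pi * xx / w * 1.7 + ph[1]) +
      0.05 * sin(2 * pi * yy / h * 2.3 + ph[2]) +
      0.03 * sin(2 * pi * (xx + yy) / (w + h) * 3.1 + ph[3])
    # static fine-grained retinal texture (capillaries, nerve fibre striation;
    # also what frame registration locks onto)
    tex <- matrix(rnorm(h * w), h, w)
    tex <- apply(tex, 2, function(col) gaussian_filter(col, 1.5))
    tex <- t(apply(tex, 1, function(row) gaussian_filter(row, 1.5)))
    bg <- bg + 0.04 * tex / sd(tex)

    # vein: vertical sinuous centreline, Gaussian cross-section
    cx <- w / 2 + 0.08 * w * sin(2 * pi * seq_len(h) / h * 1.3 + ph[4])
    d <- xx - matrix(cx, h, w)
    sigma0 <- 0.025 * w
    depth <- 0.35
    roi_mask <- abs(d) <= 2.5 * sigma0 & yy >= 0.25 * h & yy <= 0.75 * h
    if (!any(roi_mask)) {
      abort("vein ROI has zero pixels.", class = "veinpulse_generation_error")
    }

    # width modulation amplitude chosen so the relative ROI-mean modulation
    # matches pulsation_amplitude (ROI mean is near-linear in vein width)
    g0 <- mean(depth * exp(-0.5 * (d[roi_mask] / sigma0)^2))
    b0 <- mean(bg[roi_mask])
    wa <- min(0.45, config$pulsation_amplitude * b0 / g0)

    blink_idx <- integer(0)
    if (config$blink_count > 0) {
      lo <- min(4L, n_frames); hi <- max(lo, n_frames - 3L)
      blink_idx <- sort(sample(seq(lo, hi), config$blink_count))
    }
    shifts <- matrix(0L, n_frames, 2)
    if (config$jitter_px > 0 && n_frames > 1) {
      shifts[-1, ] <- sample(seq(-config$jitter_px, config$jitter_px),
                             2 * (n_frames - 1), replace = TRUE)
    }

    frames <- array(0, dim = c(h, w, n_frames))
    for (i in seq_len(n_frames)) {
      sig <- sigma0 * (1 - wa * (1 - v[i]))
      img <- gain[i] * (bg - depth * exp(-0.5 * (d / sig)^2))
      if (any(shifts[i, ] != 0L)) img <- shift_matrix(img, shifts[i, 1], shifts[i, 2])
      if (i %in% blink_idx) img <- img * 0.05
      if (config$noise_sd > 0) img <- img + rnorm(h * w, 0, config$noise_sd)
      frames[, , i] <- pmin(pmax(img, 0), 1)
    }

    truth$distorted_frame_indices <- blink_idx
    truth$roi_mask <- roi_mask
    truth$shifts <- shifts
    list(video = vp_video(frames), roi_mask = roi_mask, truth = truth)
  })
}

#' Simulate one complete recording session
#'
#' Convenience wrapper chaining [generate_ecg()], [generate_trigger()],
#' [generate_vp_trace()] and (optionally) [generate_video()] into one
#' synchronized bundle with ground truth.
#'
#' @param config A [sim_config()].
#' @param render_video Render the frame stack? Signal-level studies can
#'   skip it.
#' @return A `vp_simulation` list: `biosignal` (tibble `time_s`, `ecg`,
#'   `trigger`), `fs`, `fps`, `trace`, `video`, `roi_mask`, `truth`,
#'   `config`.
#' @export
simulate_subject <- function(config = sim_config(), render_video = TRUE) {
  ecg <- generate_ecg(config)
  trig <- generate_trigger(config)
  truth <- ecg$truth
  video <- NULL; roi_mask <- NULL
  if (render_video) {
    gv <- generate_video(config, truth)
    video <- gv$video; roi_mask <- gv$roi_mask; truth <- gv$truth
  }
  # with a rendered video the analytic trace is the noise-free reference
  # (noise enters per pixel at render time); signal-level runs carry the
  # noise on the trace itself
  vt <- generate_vp_trace(config, truth, noise = !render_video)
  truth <- vt$truth
  structure(list(
    biosignal = dplyr::mutate(ecg$signal, trigger = trig),
    fs = config$fs_bio, fps = config$fps,
    trace = vt$trace, video = video, roi_mask = roi_mask,
    truth = truth, config = config
  ), class = "vp_simulation")
}
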