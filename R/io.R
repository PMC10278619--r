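#' Read a biosignal CSV
#'
#' Expects a header row with columns `time_s`, `ecg`, `trigger` (one row
#' per sample, uniformly sampled).
#'
#' @param path CSV file path.
#' @return Tibble with attribute `fs` (Hz), inferred from `time_s`.
#' @export
read_biosignal <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("biosignal file not found: %s", path),
          class = "veinpulse_input_error")
  }
  bio <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "ecg", "trigger")
  if (!all(need %in% names(bio))) {
    abort(sprintf("biosignal CSV must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "veinpulse_input_error")
  }
  attr(bio, "fs") <- round(1 / median(diff(bio$time_s)))
  bio
}

#' @rdname read_biosignal
#' @param biosignal Tibble with columns `time_s`, `ecg`, `trigger`.
#' @export
write_biosignal <- function(biosignal, path) {
  readr::write_csv(biosignal, path)
  invisible(path)
}

#' Read a multi-page TIFF video
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF into a [vp_video()];
#' intensities are rescaled to [0, 1] regardless of source bit depth
#' (RGB pages are averaged to grayscale).
#'
#' @param path TIFF file path.
#' @return A [vp_video()].
#' @export
read_video_tiff <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("video file not found: %s", path),
          class = "veinpulse_input_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) apply(p, c(1, 2), mean) else p
  })
  vp_video(pages)
}

#' @rdname read_video_tiff
#' @param video A [vp_video()].
#' @param bits Bits per sample (8 or 16).
#' @export
write_video_tiff <- function(video, path, bits = 16) {
  stopifnot(inherits(video, "vp_video"))
  pages <- lapply(seq_len(video$n_frames), function(i) {
    pmin(pmax(video$frames[, , i], 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read or write a binary ROI mask
#'
#' PNG or (single-page) TIFF; any pixel above 0.5 is part of the ROI.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @return Logical matrix.
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("ROI mask not found: %s", path),
          class = "veinpulse_input_error")
  }
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- img > 0.5
  if (!any(m)) abort("ROI mask is empty.", class = "veinpulse_input_error")
  m
}

#' @rdname read_roi_mask
#' @param mask Logical (or 0/1) matrix.
#' @export
write_roi_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a simulated recording session to disk
#'
#' Emits the on-disk form of one simulated subject: `video.tiff`
#' (multi-page grayscale), `biosignal.csv` (`time_s`, `ecg`, `trigger`),
#' `roi.png`, and `truth.json` (ground truth sidecar) plus `config.json`.
#'
#' @param sim A `vp_simulation` from [simulate_subject()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "vp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_biosignal(sim$biosignal, file.path(dir, "biosignal.csv"))
  if (!is.null(sim$video)) {
    write_video_tiff(sim$video, file.path(dir, "video.tiff"))
    write_roi_mask(sim$roi_mask, file.path(dir, "roi.png"))
  }
  truth <- unclass(sim$truth)
  truth$roi_mask <- NULL  # stored as roi.png
  truth$shifts <- if (!is.null(truth$shifts)) as.data.frame(truth$shifts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
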