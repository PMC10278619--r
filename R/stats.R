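#' Standard deviation of R-R intervals (SDRR)
#'
#' The sample standard deviation (n - 1 denominator) of the R-R
#' intervals — the heart-rate-variability summary used alongside the
#' timing results.
#'
#' @param rr_values_s Numeric R-R intervals in seconds (>= 2 values).
#' @return SDRR in seconds.
#' @export
compute_sdrr <- function(rr_values_s) {
  rr <- as.numeric(rr_values_s)
  if (length(rr) < 2) {
    abort("need at least 2 R-R intervals.", class = "veinpulse_input_error")
  }
  sd(rr)
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties; the two-sided
#' p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' With zero rank variance in either vector the correlation is undefined
#' and reported as `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with columns `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 pairs.", class = "veinpulse_input_error")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("zero rank variance: Spearman correlation undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Per-subject summary of time to vein collapse
#'
#' Median, Tukey (inclusive-median) quartiles, and range of `tvc_ms` and
#' `tvc_rel_pct` per subject, plus a pooled row across all subjects.
#' Subjects without any valid cycle are omitted with a warning.
#'
#' @param cycles Per-cycle tibble with columns `subject_id`, `tvc_ms`,
#'   `tvc_rel_pct` (and optionally `valid`, used to filter).
#' @return Tibble, one row per subject plus one `"pooled"` row, with
#'   columns `subject_id`, `n_cycles` and `<var>_{min,q1,median,q3,max}`
#'   for both variables.
#' @export
subject_summary <- function(cycles) {
  if (!nrow(cycles)) abort("no cycles.", class = "veinpulse_input_error")
  all_subjects <- unique(cycles$subject_id)
  if ("valid" %in% names(cycles)) cycles <- dplyr::filter(cycles, .data$valid)
  empty <- setdiff(all_subjects, unique(cycles$subject_id))
  if (length(empty)) {
    warn(sprintf("subject(s) without valid cycles omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  five <- function(v, prefix) {
    f <- fivenum(v)
    stats::setNames(as.list(f), paste0(prefix, c("_min", "_q1", "_median", "_q3", "_max")))
  }
  one <- function(df, id) {
    tibble(subject_id = id, n_cycles = nrow(df)) |>
      dplyr::bind_cols(as_tibble(five(df$tvc_ms, "tvc_ms")),
                       as_tibble(five(df$tvc_rel_pct, "tvc_rel_pct")))
  }
  per <- cycles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(~ one(.x, .y$subject_id)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per, one(cycles, "pooled"))
}

#' Per-cycle scatter of cycle length against collapse time
#'
#' Flattens all subjects' cycles into one table of
#' `(rr_s, tvc_ms, subject_id)` and computes the Spearman correlation
#' between cycle length and collapse time across all cycles — the check
#' that collapse timing is (or is not) tied to the cardiac cycle length.
#'
#' @param cycles Per-cycle tibble with columns `subject_id`, `rr_s`,
#'   `tvc_ms` (rows with `valid == FALSE` are dropped when present).
#' @return A list with `table` (the flattened tibble) and `correlation`
#'   (tibble from [spearman_cor()], or all-`NA` if fewer than 3 cycles).
#' @export
cycle_scatter <- function(cycles) {
  if ("valid" %in% names(cycles)) cycles <- dplyr::filter(cycles, .data$valid)
  tab <- dplyr::select(cycles, "subject_id", "rr_s", "tvc_ms")
  corr <- if (nrow(tab) >= 3) {
    spearman_cor(tab$rr_s, tab$tvc_ms)
  } else {
    tibble(rho = NA_real_, p_value = NA_real_, n = nrow(tab))
  }
  list(table = tab, correlation = corr)
}

#' Correlate per-subject collapse time with clinical covariates
#'
#' One Spearman correlation per covariate between the per-subject summary
#' statistic of `tvc_ms` (the median by default) and each covariate
#' column. Raw p-values are reported; set `adjust = "holm"` for a
#' familywise correction.
#'
#' @param subjects Tibble with one row per subject: `subject_id`,
#'   `tvc_ms` (per-subject summary value) and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return Tibble with columns `covariate`, `rho`, `p_value`, `n`.
#' @export
covariate_correlations <- function(subjects,
                                   covariates = setdiff(names(subjects),
                                                        c("subject_id", "tvc_ms")),
                                   adjust = "none") {
  out <- purrr::map_dfr(covariates, function(cv) {
    res <- spearman_cor(subjects$tvc_ms, subjects[[cv]])
    dplyr::mutate(res, covariate = cv, .before = 1)
  })
  if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
  out
}
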