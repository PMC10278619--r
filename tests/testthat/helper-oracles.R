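# Independent oracles used across the suite.

# Rosner's 54-point benchmark dataset; the published analysis declares
# exactly 3 outliers (the three largest values).
rosner54 <- c(
  -0.25, 0.68, 0.94, 1.15, 1.20, 1.26, 1.26, 1.34, 1.38, 1.43, 1.49, 1.49,
  1.55, 1.56, 1.58, 1.65, 1.69, 1.70, 1.76, 1.77, 1.81, 1.91, 1.94, 1.96,
  1.99, 2.06, 2.09, 2.10, 2.14, 2.15, 2.23, 2.24, 2.26, 2.35, 2.37, 2.40,
  2.47, 2.54, 2.62, 2.64, 2.90, 2.92, 2.92, 2.93, 3.21, 3.26, 3.30, 3.59,
  3.68, 4.30, 4.64, 5.34, 5.42, 6.01)

# Plain transcription of the generalized ESD test from its published
# definition, written independently of the package implementation (explicit
# per-step recomputation of R_i and lambda_i on the reduced sample).
ref_gesd <- function(x, alpha, r) {
  n <- length(x)
  kept <- seq_len(n)
  out_order <- integer(0)
  Rs <- lam <- numeric(0)
  for (i in seq_len(r)) {
    xi <- x[kept]
    s <- stats::sd(xi)
    if (is.na(s) || s == 0) break
    z <- abs(xi - mean(xi)) / s
    w <- which.max(z)
    Rs[i] <- z[w]
    ni <- length(xi)
    pp <- 1 - alpha / (2 * ni)
    tv <- stats::qt(pp, ni - 2)
    lam[i] <- (ni - 1) * tv / sqrt((ni - 2 + tv^2) * ni)
    out_order[i] <- kept[w]
    kept <- kept[-w]
  }
  last <- if (length(Rs)) max(c(0L, which(Rs > lam))) else 0L
  sort(out_order[seq_len(last)])
}

# Brute-force per-pixel local median image distance for tiny sequences.
ref_local_median_distance <- function(frames, window) {
  n <- dim(frames)[3]
  half <- (window - 1) %/% 2
  sapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    med <- apply(frames[, , w, drop = FALSE], c(1, 2), median)
    sqrt(sum((frames[, , i] - med)^2))
  })
}

# Match detections to ground-truth event times within a tolerance;
# returns sensitivity and positive predictive value.
match_events <- function(detected_s, truth_s, tol_s = 0.010) {
  hit <- vapply(truth_s, function(t) any(abs(detected_s - t) <= tol_s), logical(1))
  extra <- vapply(detected_s, function(t) !any(abs(truth_s - t) <= tol_s), logical(1))
  c(sensitivity = mean(hit), ppv = 1 - mean(extra))
}
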