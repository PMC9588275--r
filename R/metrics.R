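#' Root mean squared error between normalised images
#'
#' `sqrt(mean((reference - test)^2))` over all pixels. Images are expected
#' on the \[0, 1\] normalised scale (see [normalize_hu()]).
#'
#' @param reference,test numeric arrays of identical shape.
#' @return Scalar RMSE.
#' @export
rmse <- function(reference, test) {
  reference <- as.array(reference); test <- as.array(test)
  if (!identical(dim(reference), dim(test))) {
    stopf("image shapes differ: %s vs %s",
          paste(dim(reference), collapse = "x"),
          paste(dim(test), collapse = "x"))
  }
  sqrt(mean((reference - test)^2))
}

#' Signal-to-noise ratio in decibels
#'
#' Amplitude-ratio definition
#' `20 * log10(||reference|| / ||reference - test||)`. Identical images
#' yield `Inf` (reported explicitly rather than erroring); an all-zero
#' reference is rejected. The definition is recorded in the result's
#' `definition` attribute so alternatives can be swapped without touching
#' callers.
#'
#' @param reference,test numeric arrays of identical shape.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(reference, test) {
  reference <- as.array(reference); test <- as.array(test)
  if (!identical(dim(reference), dim(test))) {
    stopf("image shapes differ")
  }
  sig <- sqrt(sum(reference^2))
  if (sig == 0) stopf("all-zero reference: SNR undefined")
  noise <- sqrt(sum((reference - test)^2))
  out <- if (noise == 0) Inf else 20 * log10(sig / noise)
  structure(out, definition = "20*log10(||ref|| / ||ref - test||)")
}

#' Lin's concordance correlation coefficient
#'
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, following Lin's original estimator: agreement between
#' paired measurements, combining correlation with penalties for mean and
#' scale shifts. If both vectors are constant with equal means the
#' denominator vanishes; `NA` is returned with a warning.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return CCC in \[-1, 1\], or `NA` in the degenerate case.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 2L) stopf("need at least 2 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) {
    warning("degenerate CCC: both inputs constant with equal means")
    return(NA_real_)
  }
  2 * sxy / den
}

#' Per-feature CCC between two feature tables
#'
#' Computes one CCC per shared non-shape feature, aligning subjects by id
#' (row order is irrelevant). Shape features are excluded: they are
#' computed from the mask only and unaffected by denoising, so they carry
#' no reproducibility information.
#'
#' @param table_a,table_b [extract_feature_table()] results with matching
#'   subjects and feature columns.
#' @return A data frame with columns `feature`, `class`, `ccc`.
#' @export
ccc_table <- function(table_a, table_b) {
  ids_a <- table_a$subject_id; ids_b <- table_b$subject_id
  if (!setequal(ids_a, ids_b)) {
    stopf("subject sets differ: only in A: %s; only in B: %s",
          paste(setdiff(ids_a, ids_b), collapse = ","),
          paste(setdiff(ids_b, ids_a), collapse = ","))
  }
  table_b <- table_b[match(ids_a, ids_b), , drop = FALSE]
  cls_a <- attr(table_a, "feature_class")
  feats <- setdiff(names(table_a), "subject_id")
  if (!setequal(feats, setdiff(names(table_b), "subject_id"))) {
    stopf("feature columns differ between tables")
  }
  keep <- feats[cls_a[feats] != "shape"]
  data.frame(
    feature = keep,
    class = unname(cls_a[keep]),
    ccc = vapply(keep, function(f) ccc(table_a[[f]], table_b[[f]]),
                 numeric(1)),
    row.names = NULL
  )
}

#' Bin CCC values into reproducibility categories
#'
#' Poor: CCC < 0.65; medium: 0.65 <= CCC < 0.85; good: CCC >= 0.85.
#'
#' @param values numeric vector of CCC values in \[-1, 1\].
#' @return Named numeric vector of fractions (`poor`, `medium`, `good`)
#'   summing to 1.
#' @export
categorize_ccc <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stopf("no CCC values to categorise")
  c(poor = sum(values < 0.65) / n,
    medium = sum(values >= 0.65 & values < 0.85) / n,
    good = sum(values >= 0.85) / n)
}

#' Mean CCC with a bootstrap confidence interval
#'
#' Mean of the per-feature CCCs with a seeded percentile bootstrap over
#' features (resampling feature indices with replacement).
#'
#' @param values per-feature CCC vector (length >= 2).
#' @param n_boot bootstrap resamples (a warning is issued below 100).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return Named vector `mean`, `lo`, `hi`.
#' @export
mean_ccc_ci <- function(values, n_boot = 2000L, seed = 1L, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stopf("need >= 2 CCC values")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable intervals")
  m <- mean(values)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  qs <- unname(quantile(boots, c(a, 1 - a), type = 7))
  c(mean = m, lo = qs[1], hi = qs[2])
}

#' Two-sample Wilcoxon rank-sum comparison of CCC distributions
#'
#' Two-sided rank-sum (Mann-Whitney) test using the tie-corrected normal
#' approximation with continuity correction: ranks are computed on the
#' pooled sample (midranks for ties), the statistic is the rank sum of the
#' first sample, and the p-value follows from the normal limit with the
#' tie-adjusted variance.
#'
#' @param a,b numeric vectors (e.g. per-feature CCCs of two models).
#' @return A list with `statistic` (rank sum of `a`), `u` (Mann-Whitney U),
#'   `p_value`, and the group sizes.
#' @export
compare_ccc_distributions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stopf("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2
  n <- na + nb
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) {
    warning("degenerate rank-sum comparison: all pooled values identical")
    return(list(statistic = w, u = u, p_value = NA_real_, n_a = na, n_b = nb))
  }
  mu <- na * nb / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  if (u == mu) z <- 0
  p <- 2 * pnorm(-abs(z))
  list(statistic = w, u = u, p_value = min(1, p), n_a = na, n_b = nb)
}

#' Empirical CDF of CCC values
#'
#' Right-continuous empirical distribution function over the sorted unique
#' values, as used to compare reproducibility profiles of different
#' models.
#'
#' @param values numeric vector.
#' @return A data frame with columns `value` (sorted unique support) and
#'   `cdf` (cumulative fraction, reaching 1 at the maximum).
#' @export
ccc_cdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stopf("no values")
  sup <- sort(unique(values))
  data.frame(value = sup,
             cdf = vapply(sup, function(v) mean(values <= v), numeric(1)))
}

#' Image-pair evaluation metrics
#'
#' RMSE, perceptual distance and SNR for a pair of volumes on the
#' normalised \[0, 1\] scale, averaged over slices.
#'
#' @param reference,test [ct_volume()]s in HU.
#' @param fx a [feature_extractor()] for the perceptual distance.
#' @param norm_spec a [normalization_spec()].
#' @return A list `rmse`, `perceptual`, `snr_db`, `n_pixels`.
#' @export
image_pair_metrics <- function(reference, test, fx,
                               norm_spec = normalization_spec()) {
  stopifnot(inherits(reference, "ct_volume"), inherits(test, "ct_volume"))
  d <- dim(reference$voxels)
  if (!identical(d, dim(test$voxels))) stopf("volume shapes differ")
  rn <- normalize_hu(reference$voxels, norm_spec)
  tn <- normalize_hu(test$voxels, norm_spec)
  per_slice <- vapply(seq_len(d[3]), function(iz) {
    c(rmse(rn[, , iz], tn[, , iz]),
      perceptual_distance(tn[, , iz], rn[, , iz], fx),
      as.numeric(snr_db(rn[, , iz], tn[, , iz])))
  }, numeric(3))
  list(rmse = mean(per_slice[1, ]), perceptual = mean(per_slice[2, ]),
       snr_db = mean(per_slice[3, ]), n_pixels = d[1] * d[2])
}
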