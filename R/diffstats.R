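drop_incomplete_pairs <- function(case_values, control_values) {
  if (length(case_values) != length(control_values))
    stop("case and control vectors must have equal length")
  ok <- !is.na(case_values) & !is.na(control_values)
  list(case = case_values[ok], control = control_values[ok])
}

#' Paired t-test p-value
#'
#' Two-sided paired t-test on the supplied per-pair values (the pipeline
#' passes log2 intensities). Pairs with a missing member are dropped.
#' Zero variance of the differences is degenerate: p = 1 with attribute
#' `degenerate = TRUE`.
#'
#' @param case_values,control_values numeric vectors, one entry per
#'   matched pair.
#' @return p-value in (0, 1]; `NA` if fewer than 3 complete pairs.
#' @export
paired_t <- function(case_values, control_values) {
  v <- drop_incomplete_pairs(case_values, control_values)
  d <- v$case - v$control
  n <- length(d)
  if (n < 3) return(NA_real_)
  s <- stats::sd(d)
  if (s == 0) return(structure(1, degenerate = TRUE))
  tval <- mean(d) / (s / sqrt(n))
  2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
}

# Exact null distribution of the signed-rank statistic W (sum of ranks of
# positive differences) for a fixed multiset of midranks; ties handled by
# doubling the ranks so subset sums stay integral. Returns P(T = t) over
# t = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  dp <- numeric(total + 1)
  dp[1] <- 1
  for (w in ranks2) {
    shifted <- c(numeric(w), dp[seq_len(total + 1 - w)])
    dp <- dp + shifted
  }
  dp / 2^length(ranks2)
}

#' Wilcoxon signed-rank test p-value
#'
#' Two-sided matched-pair signed-rank test. Zero differences are dropped.
#' For n <= 25 usable pairs the exact null distribution is used
#' (dynamic-programming enumeration of all sign patterns, midranks for
#' ties); above that, the normal approximation with tie and continuity
#' corrections.
#'
#' @inheritParams paired_t
#' @return p-value; `NA` if fewer than 3 non-zero differences.
#' @export
wilcoxon_signed_rank <- function(case_values, control_values) {
  v <- drop_incomplete_pairs(case_values, control_values)
  d <- v$case - v$control
  d <- d[d != 0]
  n <- length(d)
  if (n < 3) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25) {
    dist <- signed_rank_null(as.integer(round(2 * r)))
    tt <- seq_along(dist) - 1                  # support of 2W
    dev <- abs(tt - 2 * mu)
    p <- sum(dist[dev >= abs(2 * w - 2 * mu) - 1e-9])
    return(min(1, p))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Exact sign (binomial) test p-value
#'
#' Two-sided exact binomial test on the direction of the paired
#' differences: with k positive of n non-zero differences,
#' p = min(1, 2 min(P(X <= k), P(X >= k))) for X ~ Binomial(n, 1/2).
#'
#' @inheritParams paired_t
#' @return p-value; `NA` if no non-zero differences remain.
#' @export
sign_test <- function(case_values, control_values) {
  v <- drop_incomplete_pairs(case_values, control_values)
  d <- v$case - v$control
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) return(NA_real_)
  k <- sum(d > 0)
  lo <- stats::pbinom(k, n, 0.5)
  hi <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up adjusted p-values: sorted ascending,
#' adj_i = min_{j >= i} p_j m / j, capped at 1, original order restored.
#' `NA` entries (undefined tests) are excluded from m and returned
#' unchanged.
#'
#' @param pvalues numeric vector in (0, 1], possibly with `NA`s.
#' @return adjusted vector, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  out <- pvalues
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' One-step Tukey biweight fold change
#'
#' Per matched pair the case/control intensity ratio r is folded to the
#' signed scale f = r if r >= 1, else -1/r (so -2 means two-fold down),
#' and the one-step Tukey biweight location of the signed folds is
#' returned: M = median(f), u = (f - M) / (c MAD + eps) with c = 5,
#' eps = 1e-4, MAD unscaled; weights (1 - u^2)^2 for |u| < 1, else 0.
#' Robust to outlying pairs; magnitudes below 1 can arise when pairs
#' disagree in direction.
#'
#' @inheritParams paired_t
#' @param c_tuning biweight tuning constant (default 5).
#' @param eps stabilizer added to c * MAD (default 1e-4).
#' @return signed tFC (numeric scalar).
#' @export
tukey_biweight_fc <- function(case_values, control_values, c_tuning = 5,
                              eps = 1e-4) {
  v <- drop_incomplete_pairs(case_values, control_values)
  if (any(v$case <= 0) || any(v$control <= 0))
    stop("fold changes require strictly positive raw intensities")
  if (length(v$case) < 3) stop("fewer than 3 usable pairs")
  r <- v$case / v$control
  f <- ifelse(r >= 1, r, -1 / r)
  m <- stats::median(f)
  s <- stats::mad(f, constant = 1)
  u <- (f - m) / (c_tuning * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * f) / sum(w)
}

#' Build differential records
#'
#' Low-level constructor for the per-feature differential summary used
#' throughout the package (also by the bundled example table, where only
#' the minimum p-value, its BH value and the tFC are published).
#'
#' @param feature_id,layer character vectors.
#' @param p_paired_t,p_wilcoxon,p_sign per-test p-values (optional).
#' @param min_p smallest available p-value; computed from the three tests
#'   when omitted.
#' @param bh_paired_t,bh_wilcoxon,bh_sign per-test BH-adjusted values.
#' @param bh_min BH value belonging to the test achieving `min_p`.
#' @param tfc signed Tukey-biweight fold change.
#' @param alpha significance level for the roll-up flag (default 0.05).
#' @param significant optional logical override of the roll-up flag, for
#'   published tables whose p-values are printed at limited precision
#'   (e.g. a row printed as p = 0.050 that the source reports as
#'   significant).
#' @return data.frame of class `differential_record`, one row per feature.
#' @export
differential_records <- function(feature_id, layer,
                                 p_paired_t = NA_real_, p_wilcoxon = NA_real_,
                                 p_sign = NA_real_, min_p = NULL,
                                 bh_paired_t = NA_real_, bh_wilcoxon = NA_real_,
                                 bh_sign = NA_real_, bh_min = NA_real_,
                                 tfc = NA_real_, alpha = 0.05,
                                 significant = NULL) {
  n <- length(feature_id)
  df <- data.frame(feature_id = as.character(feature_id),
                   layer = rep_len(as.character(layer), n),
                   p_paired_t = rep_len(as.numeric(p_paired_t), n),
                   p_wilcoxon = rep_len(as.numeric(p_wilcoxon), n),
                   p_sign = rep_len(as.numeric(p_sign), n),
                   stringsAsFactors = FALSE)
  if (is.null(min_p)) {
    pm <- as.matrix(df[, c("p_paired_t", "p_wilcoxon", "p_sign")])
    min_p <- suppressWarnings(apply(pm, 1, min, na.rm = TRUE))
    min_p[!is.finite(min_p)] <- NA_real_
  }
  df$min_p <- rep_len(as.numeric(min_p), n)
  df$bh_paired_t <- rep_len(as.numeric(bh_paired_t), n)
  df$bh_wilcoxon <- rep_len(as.numeric(bh_wilcoxon), n)
  df$bh_sign <- rep_len(as.numeric(bh_sign), n)
  df$bh_min <- rep_len(as.numeric(bh_min), n)
  df$tfc <- rep_len(as.numeric(tfc), n)
  df$significant <- if (is.null(significant))
    !is.na(df$min_p) & df$min_p < alpha
  else rep_len(as.logical(significant), n)
  class(df) <- c("differential_record", "data.frame")
  df
}

#' Matched-pair differential table
#'
#' Runs all three paired tests per feature (t-test on log2 intensities;
#' signed-rank and sign tests on raw differences), BH-adjusts each test
#' separately within each omics layer, computes the signed
#' Tukey-biweight fold change, and flags features whose smallest nominal
#' p-value is below `alpha`. Pairs with a missing member are dropped per
#' feature. Output is sorted by tFC, descending.
#'
#' @param ds preprocessed [omics_dataset()].
#' @param design a [matched_design()].
#' @param alpha nominal significance level (default 0.05).
#' @return A `differential_record` data.frame, one row per feature.
#' @export
differential_table <- function(ds, design, alpha = 0.05) {
  validate_omics_dataset(ds)
  idx <- design_indices(ds, design)
  x <- ds$intensities
  caseM <- x[, idx$case, drop = FALSE]
  ctrlM <- x[, idx$control, drop = FALSE]
  nfeat <- nrow(x)
  pt_ <- pw <- ps <- fc <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    cs <- caseM[i, ]; ct <- ctrlM[i, ]
    pt_[i] <- as.numeric(paired_t(log2(cs), log2(ct)))
    pw[i] <- wilcoxon_signed_rank(cs, ct)
    ps[i] <- sign_test(cs, ct)
    ok <- !is.na(cs) & !is.na(ct)
    if (sum(ok) >= 3 && all(cs[ok] > 0) && all(ct[ok] > 0))
      fc[i] <- tukey_biweight_fc(cs[ok], ct[ok])
  }
  layer <- ds$feature_meta$layer
  bt <- bw <- bs <- rep(NA_real_, nfeat)
  for (ly in unique(layer)) {
    sel <- layer == ly
    bt[sel] <- bh_adjust(pt_[sel])
    bw[sel] <- bh_adjust(pw[sel])
    bs[sel] <- bh_adjust(ps[sel])
  }
  pm <- cbind(pt_, pw, ps)
  bm <- cbind(bt, bw, bs)
  which_min <- apply(pm, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  bh_min <- vapply(seq_len(nfeat), function(i)
    if (is.na(which_min[i])) NA_real_ else bm[i, which_min[i]], numeric(1))
  rec <- differential_records(ds$feature_meta$feature_id, layer,
                              p_paired_t = pt_, p_wilcoxon = pw, p_sign = ps,
                              bh_paired_t = bt, bh_wilcoxon = bw, bh_sign = bs,
                              bh_min = bh_min, tfc = fc, alpha = alpha)
  rec[order(-rec$tfc, rec$feature_id, na.last = TRUE), , drop = FALSE]
}
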