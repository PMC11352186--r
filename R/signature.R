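#' Select a high-fold-change signature
#'
#' Keeps the significant features whose robust fold change magnitude
#' strictly exceeds `cutoff` (|tFC| > cutoff; a feature at exactly the
#' cutoff is excluded).
#'
#' @param records a `differential_record` data.frame (see
#'   [differential_table()]).
#' @param cutoff fold-change magnitude threshold (default 1.5).
#' @return object of class `signature_set`: `features` (data.frame with
#'   `feature_id`, `layer`, `tfc`), the selection `rule`, and per-layer
#'   counts.
#' @export
fc_threshold_select <- function(records, cutoff = 1.5) {
  keep <- records$significant & !is.na(records$tfc) & abs(records$tfc) > cutoff
  feats <- records[keep, c("feature_id", "layer", "tfc"), drop = FALSE]
  rownames(feats) <- NULL
  structure(list(features = feats, rule = "threshold", cutoff = cutoff,
                 n_models = NA_integer_,
                 counts_by_layer = table(factor(feats$layer,
                   levels = c("metabolite", "lipid", "protein")))),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d features (%s rule)\n",
              nrow(x$features), x$rule))
  print(x$counts_by_layer)
  invisible(x)
}

# 31-bit string hash for seed-keyed, order-invariant fold assignment.
id_hash <- function(ids) {
  vapply(ids, function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1))
}

fold_assignment <- function(sample_ids, y, cv_folds, seed) {
  for (shift in 0:50) {
    f <- (id_hash(sample_ids) + seed + shift) %% cv_folds + 1
    tab <- table(factor(f, levels = seq_len(cv_folds)), y)
    if (all(tab > 0)) {
      if (shift > 0)
        warning("single-class CV fold; fold assignment re-drawn (shift ",
                shift, ")")
      return(as.integer(f))
    }
  }
  stop("could not find a fold assignment with both classes in every fold")
}

#' Elastic-net leave-one-out stability selection (matrix interface)
#'
#' One leave-one-out iteration per sample: the elastic-net logistic path
#' is fit on the remaining samples, lambda is picked at the minimum
#' 3-fold cross-validated deviance, and the features with non-zero
#' coefficients are recorded. Features included in strictly more than
#' half of the iterations form the stable set. CV fold membership is
#' keyed to sample ids hashed with the seed, so results do not depend on
#' sample or feature order.
#'
#' @param x numeric matrix, samples x features (already transformed /
#'   standardized as desired).
#' @param y factor or character with levels CNT/DEL (DEL = positive).
#' @param alpha_mix elastic-net mixing parameter (default 0.5).
#' @param n_lambda path length (default 100, ratio 1e-4).
#' @param cv_folds folds for the deviance curve (default 3).
#' @param seed integer seed.
#' @return `signature_set` with per-feature `inclusion_count` out of
#'   `n_models` iterations; `features` holds the majority set.
#' @export
stability_selection <- function(x, y, alpha_mix = 0.5, n_lambda = 100,
                                cv_folds = 3, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  y <- factor(as.character(y), levels = c("CNT", "DEL"))
  if (anyNA(y)) stop("labels must be DEL or CNT")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  # canonical sample/feature order: glmnet's coordinate descent is not
  # exactly permutation-invariant, so invariance is enforced by sorting
  if (!is.null(colnames(x))) x <- x[, order(colnames(x)), drop = FALSE]
  ro <- order(ids)
  x <- x[ro, , drop = FALSE]; y <- y[ro]; ids <- ids[ro]
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    if (length(unique(yt)) < 2) next
    foldid <- fold_assignment(ids[-i], yt, cv_folds,
                              sub_seed(seed, "en-folds"))
    cvfit <- glmnet::cv.glmnet(xt, yt, family = "binomial",
                               alpha = alpha_mix, nlambda = n_lambda,
                               lambda.min.ratio = 1e-4, foldid = foldid,
                               type.measure = "deviance",
                               standardize = FALSE)
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
    counts <- counts + as.integer(cf != 0)
  }
  majority <- counts > n / 2
  feats <- data.frame(feature_id = names(counts)[majority],
                      inclusion_count = unname(counts[majority]),
                      stringsAsFactors = FALSE)
  structure(list(features = feats, rule = "stability",
                 inclusion_count = counts, n_models = n,
                 counts_by_layer = NULL,
                 alpha_mix = alpha_mix, cv_folds = cv_folds, seed = seed),
            class = "signature_set")
}

#' Refine a signature by elastic-net leave-one-out stability
#'
#' Dataset-level wrapper around [stability_selection()]: restricts the
#' dataset to the signature features and the design's samples, log2
#' transforms and feature-standardizes, and runs the leave-one-out
#' elastic-net majority-inclusion procedure.
#'
#' @param ds an [omics_dataset()] (or a pre-combined multi-omics one).
#' @param design a [matched_design()].
#' @param signature a `signature_set` (or character feature ids).
#' @inheritParams stability_selection
#' @return `signature_set` with layers annotated.
#' @export
elastic_net_stability <- function(ds, design, signature, alpha_mix = 0.5,
                                  n_lambda = 100, cv_folds = 3, seed = 1) {
  ids <- if (inherits(signature, "signature_set"))
    signature$features$feature_id else as.character(signature)
  sub <- subset_dataset(ds, features = ids,
                        samples = c(design$case, design$control))
  x <- t(log2(sub$intensities))
  x <- scale(x)
  x[is.nan(x)] <- 0
  y <- sub$sample_meta$group[match(rownames(x), sub$sample_meta$sample_id)]
  out <- stability_selection(x, y, alpha_mix = alpha_mix,
                             n_lambda = n_lambda, cv_folds = cv_folds,
                             seed = seed)
  out$features$layer <- sub$feature_meta$layer[
    match(out$features$feature_id, sub$feature_meta$feature_id)]
  out$counts_by_layer <- table(factor(out$features$layer,
    levels = c("metabolite", "lipid", "protein")))
  out
}
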