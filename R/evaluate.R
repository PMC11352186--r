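signature_ids <- function(features) {
  if (inherits(features, "signature_set")) features$features$feature_id
  else as.character(features)
}

#' UPGMA clustering of samples on a signature
#'
#' Rows (features) are standardized to zero mean / unit variance across
#' samples; the sample-sample distance is 1 - Pearson correlation of the
#' standardized profiles; agglomeration is average linkage (UPGMA) and
#' the tree is cut into exactly two clusters. Samples are processed in
#' lexicographic id order so ties break deterministically. Constant
#' features are dropped with a warning.
#'
#' @param ds an [omics_dataset()] (study samples are clustered).
#' @param features a `signature_set` or character vector of feature ids.
#' @param k number of clusters for the cut (default 2).
#' @return list with `assignment` (named integer vector), `tree`
#'   (hclust) and the sample `labels` (group per sample).
#' @export
upgma_cluster <- function(ds, features, k = 2) {
  ids <- signature_ids(features)
  sm <- ds$sample_meta
  study <- sort(sm$sample_id[sm$role == "study"])
  if (length(study) < 2) stop("need at least 2 samples to cluster")
  sub <- subset_dataset(ds, features = ids, samples = study)
  x <- log2(sub$intensities)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping ", sum(sds == 0 | is.na(sds)),
            " constant feature(s) before correlation")
    x <- x[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  xz <- t(scale(t(x)))
  d <- stats::as.dist(1 - stats::cor(xz, use = "pairwise.complete.obs"))
  tree <- stats::hclust(d, method = "average")
  assignment <- if (ncol(xz) == k) stats::setNames(seq_len(k), colnames(xz))
                else stats::cutree(tree, k = k)
  labels <- stats::setNames(sub$sample_meta$group, sub$sample_meta$sample_id)
  list(assignment = assignment, tree = tree, labels = labels[names(assignment)])
}

#' Evaluate a 2-cluster cut against the phenotype
#'
#' `misclustered_count` is the minimum number of mismatches over the two
#' possible cluster-to-label assignments; `fisher_p` the two-sided Fisher
#' exact p-value of the 2x2 cluster-by-label table.
#'
#' @param assignment integer cluster vector (values 1/2), named by sample.
#' @param labels DEL/CNT per sample (same order or named).
#' @return list of class `cluster_eval` with `misclustered_count`,
#'   `fisher_p`, `table`.
#' @export
cluster_eval <- function(assignment, labels) {
  if (!is.null(names(labels)) && !is.null(names(assignment)))
    labels <- labels[names(assignment)]
  if (length(unique(assignment)) != 2) stop("need exactly 2 non-empty clusters")
  tab <- table(cluster = assignment, label = factor(labels, c("CNT", "DEL")))
  mis <- min(tab[1, "DEL"] + tab[2, "CNT"], tab[1, "CNT"] + tab[2, "DEL"])
  p <- stats::fisher.test(tab)$p.value
  structure(list(misclustered_count = as.integer(mis), fisher_p = min(1, p),
                 table = tab),
            class = "cluster_eval")
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat(sprintf("<cluster_eval> %d/%d misclustered, Fisher p = %.3g\n",
              x$misclustered_count, sum(x$table), x$fisher_p))
  invisible(x)
}

#' Rank-based ROC AUC with stratified bootstrap CI
#'
#' AUC by the Mann-Whitney formulation with midrank tie handling; the
#' 95% confidence interval is a stratified percentile bootstrap
#' (resampling cases and controls separately), truncated to [0, 1].
#'
#' @param decision_values numeric scores (larger = more case-like).
#' @param labels DEL/CNT (DEL is the positive class).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(decision_values, labels, n_boot = 2000, seed = 1) {
  pos <- labels == "DEL"; neg <- labels == "CNT"
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  auc_of <- function(sp, sn) {
    r <- rank(c(sp, sn))
    np <- length(sp)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(sn))
  }
  sp <- decision_values[pos]; sn <- decision_values[neg]
  auc <- auc_of(sp, sn)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b)
      auc_of(sample(sp, replace = TRUE), sample(sn, replace = TRUE)),
      numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]))
}

#' PCA + SVM leave-one-out classification
#'
#' For each left-out sample the log2 data are mean-centered per feature
#' (training-fold means with `pca_scope = "per_fold"`, full-data means
#' with `"global"`), projected onto the top principal components, and a
#' C-SVC (C = 1) with the requested kernel is trained on the remaining
#' samples and scores the held-out one. The Gaussian kernel width is
#' 1/(n_components x mean feature variance); the polynomial kernel is
#' cubic. The `global` scope reproduces single-projection decision-plane
#' analyses at the cost of a mild information leak; `per_fold` is the
#' leakage-free default.
#'
#' @param ds an [omics_dataset()].
#' @param features `signature_set` or feature ids.
#' @param kernel `"linear"`, `"poly"` or `"rbf"`.
#' @param n_components principal components kept (default 2; clamped to
#'   the data rank with a warning).
#' @param pca_scope `"per_fold"` (default) or `"global"`.
#' @param seed seed (used by the AUC bootstrap).
#' @return list of class `classifier_eval`: per-sample `decision_values`,
#'   `predicted`, `l1o_accuracy` (percent), `auc`, `auc_ci`, `kernel`,
#'   `n_components`.
#' @export
pca_svm_l1o <- function(ds, features, kernel = c("linear", "poly", "rbf"),
                        n_components = 2, pca_scope = c("per_fold", "global"),
                        seed = 1) {
  kernel <- match.arg(kernel)
  pca_scope <- match.arg(pca_scope)
  ids <- signature_ids(features)
  sm <- ds$sample_meta
  study <- sm$sample_id[sm$role == "study" & sm$group %in% c("DEL", "CNT")]
  sub <- subset_dataset(ds, features = ids, samples = study)
  x <- t(log2(sub$intensities))       # samples x features
  y <- sub$sample_meta$group
  n <- nrow(x)
  if (n < 6) stop("need at least 6 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  d <- min(n_components, ncol(x), n - 2)
  if (d < n_components)
    warning("n_components clamped to ", d, " (data rank)")
  yy <- ifelse(y == "DEL", 1, -1)
  dec <- numeric(n)
  if (pca_scope == "global") {
    xc <- scale(x, center = TRUE, scale = FALSE)
    pc <- svd(xc, nu = 0, nv = d)
    Z <- xc %*% pc$v
  }
  for (i in seq_len(n)) {
    if (pca_scope == "per_fold") {
      mu <- colMeans(x[-i, , drop = FALSE])
      xc <- sweep(x, 2, mu)
      pc <- svd(xc[-i, , drop = FALSE], nu = 0, nv = d)
      Ztr <- xc[-i, , drop = FALSE] %*% pc$v
      Zte <- xc[i, , drop = FALSE] %*% pc$v
    } else {
      Ztr <- Z[-i, , drop = FALSE]
      Zte <- Z[i, , drop = FALSE]
    }
    fit <- svm_fit(Ztr, yy[-i], kernel = kernel)
    dec[i] <- svm_decision(fit, Zte)
  }
  predicted <- ifelse(dec >= 0, "DEL", "CNT")
  acc <- 100 * mean(predicted == y)
  roc <- roc_auc(dec, y, seed = sub_seed(seed, "auc"))
  structure(list(decision_values = stats::setNames(dec, rownames(x)),
                 predicted = predicted, labels = y,
                 l1o_accuracy = acc, auc = roc$auc,
                 auc_ci = c(roc$ci_low, roc$ci_high),
                 kernel = kernel, n_components = d,
                 pca_scope = pca_scope),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(
    "<classifier_eval> kernel=%s  L1O accuracy %.2f%%  AUC %.4f [%.2f-%.2f]\n",
    x$kernel, x$l1o_accuracy, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Best-kernel PCA+SVM evaluation
#'
#' Runs [pca_svm_l1o()] with the linear, polynomial and Gaussian kernels
#' and returns the best by leave-one-out accuracy, ties broken
#' linear > poly > rbf.
#'
#' @inheritParams pca_svm_l1o
#' @return the winning `classifier_eval`, with the full per-kernel list
#'   in `$all_kernels`.
#' @export
pca_svm_best <- function(ds, features, n_components = 2,
                         pca_scope = "per_fold", seed = 1) {
  kernels <- c("linear", "poly", "rbf")
  evals <- lapply(kernels, function(k)
    pca_svm_l1o(ds, features, kernel = k, n_components = n_components,
                pca_scope = pca_scope, seed = seed))
  accs <- vapply(evals, `[[`, numeric(1), "l1o_accuracy")
  best <- evals[[which.max(accs)]]          # which.max keeps first = linear
  best$all_kernels <- stats::setNames(evals, kernels)
  best
}
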