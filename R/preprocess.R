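#' Consolidate split lipid signal lines
#'
#' Untargeted lipidomics can report one lipid over several output lines;
#' rows of the lipid layer sharing a non-empty `consolidation_key` are
#' replaced by a single row whose per-sample value is the sum of the
#' non-missing contributions. A consolidated cell is missing only when
#' every contributing cell is missing. Rows with a unique key, an empty
#' key, or a non-lipid layer pass through unchanged; a merged row takes
#' its key as feature id.
#'
#' @param ds an [omics_dataset()].
#' @return consolidated `omics_dataset`.
#' @export
consolidate_lipid_lines <- function(ds) {
  validate_omics_dataset(ds)
  fm <- ds$feature_meta
  key <- ifelse(fm$layer == "lipid" & fm$consolidation_key != "",
                fm$consolidation_key, NA_character_)
  groups <- split(seq_len(nrow(fm)), key)
  multi <- groups[lengths(groups) > 1]
  if (!length(multi)) return(ds)
  drop_rows <- integer()
  x <- ds$intensities
  for (k in names(multi)) {
    rows <- multi[[k]]
    isflag <- fm$is_internal_standard[rows]
    if (length(unique(isflag)) > 1)
      stop("conflicting is_internal_standard within consolidation key ", k)
    block <- x[rows, , drop = FALSE]
    summed <- colSums(block, na.rm = TRUE)
    summed[colSums(!is.na(block)) == 0] <- NA_real_
    keep <- rows[1]
    x[keep, ] <- summed
    fm$feature_id[keep] <- k
    drop_rows <- c(drop_rows, rows[-1])
  }
  if (length(drop_rows)) {
    x <- x[-drop_rows, , drop = FALSE]
    fm <- fm[-drop_rows, , drop = FALSE]
  }
  omics_dataset(x, fm, ds$sample_meta)
}

#' Presence filter
#'
#' A feature is "present" when measured in at least `min_frac` of the
#' study samples of a phenotypic group. With `rule = "any"` (default) a
#' feature is kept when present in DEL or in CNT, which retains
#' group-specific analytes; `rule = "both"` requires both. Pooled-QC
#' samples are not counted and internal standards are always kept.
#'
#' @param ds an [omics_dataset()] with group labels on study samples.
#' @param design a [matched_design()] (validated against the dataset).
#' @param min_frac minimum non-missing fraction within a group (default 0.5).
#' @param rule `"any"` or `"both"`.
#' @return list with elements `dataset` (filtered) and `report`
#'   (a `preprocess_report` listing dropped features).
#' @export
presence_filter <- function(ds, design, min_frac = 0.5,
                            rule = c("any", "both")) {
  rule <- match.arg(rule)
  validate_omics_dataset(ds)
  design_indices(ds, design)
  sm <- ds$sample_meta
  del <- which(sm$role == "study" & sm$group == "DEL")
  cnt <- which(sm$role == "study" & sm$group == "CNT")
  if (!length(del) || !length(cnt))
    stop("presence filter needs study samples in both groups")
  x <- ds$intensities
  frac_del <- rowMeans(!is.na(x[, del, drop = FALSE]))
  frac_cnt <- rowMeans(!is.na(x[, cnt, drop = FALSE]))
  present <- if (rule == "any") frac_del >= min_frac | frac_cnt >= min_frac
             else frac_del >= min_frac & frac_cnt >= min_frac
  keep <- present | ds$feature_meta$is_internal_standard
  dropped <- data.frame(
    feature_id = ds$feature_meta$feature_id[!keep],
    reason = sprintf("present in %.0f%% DEL / %.0f%% CNT (< %.0f%%)",
                     100 * frac_del[!keep], 100 * frac_cnt[!keep],
                     100 * min_frac),
    stringsAsFactors = FALSE)
  out <- subset_dataset(ds, features = which(keep))
  list(dataset = out,
       report = preprocess_report("presence_filter", out, dropped))
}

#' Pooled-QC random-forest signal-drift correction (QC-RFSC)
#'
#' Per feature, a random-forest regression of the pooled-QC intensities
#' on injection order models the instrument drift d(o); every sample's
#' intensity is rescaled by ref / d(o), where ref is the median (or
#' mean) of the feature's raw QC values. Features with fewer than 3
#' non-missing QC values pass through unchanged and are flagged in the
#' `qc_rfsc_skipped` attribute. Missing values stay missing.
#'
#' @param ds an [omics_dataset()] with pooled-QC samples.
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed for bootstrap resampling inside the forest.
#' @param node_size minimum terminal node size (default 5).
#' @param reference `"median"` (default) or `"mean"` QC level to rescale to.
#' @return corrected `omics_dataset`.
#' @export
qc_rfsc_correct <- function(ds, n_trees = 500, seed = 1, node_size = 5,
                            reference = c("median", "mean")) {
  reference <- match.arg(reference)
  validate_omics_dataset(ds)
  sm <- ds$sample_meta
  qc <- which(sm$role == "pooled_qc")
  if (!length(qc)) stop("no pooled-QC samples in dataset")
  x <- ds$intensities
  n_qc_ok <- rowSums(!is.na(x[, qc, drop = FALSE]))
  if (all(n_qc_ok == 0))
    stop("all QC values missing for every feature: mis-specified dataset?")
  orders <- as.numeric(sm$injection_order)
  skipped <- character()
  for (i in seq_len(nrow(x))) {
    if (n_qc_ok[i] < 3) {
      skipped <- c(skipped, ds$feature_meta$feature_id[i])
      next
    }
    ok <- qc[!is.na(x[i, qc])]
    yq <- x[i, ok]
    drift <- rf1d_predict_cpp(orders[ok], yq, orders,
                              as.integer(n_trees), as.integer(node_size),
                              as.integer(sub_seed(seed, i) %% 2147483647L))
    ref <- if (reference == "median") stats::median(yq) else mean(yq)
    x[i, ] <- x[i, ] * ref / drift
  }
  out <- omics_dataset(x, ds$feature_meta, sm)
  attr(out, "qc_rfsc_skipped") <- skipped
  out
}

#' k-nearest-neighbour imputation
#'
#' Feature-wise knn on log2 intensities: for each feature with missing
#' entries, the k nearest features by Euclidean distance over jointly
#' observed samples (scaled to per-sample units) provide a
#' distance-weighted average at the missing sample, back-transformed to
#' the raw scale. Observed values are never altered. Features missing in
#' every sample are dropped and reported.
#'
#' @param ds an [omics_dataset()].
#' @param k number of neighbours (default 10; clamped with a warning when
#'   fewer candidates exist).
#' @return list with `dataset` (imputed) and `report`.
#' @export
knn_impute <- function(ds, k = 10) {
  if (k < 1) stop("k must be >= 1")
  validate_omics_dataset(ds)
  x <- ds$intensities
  all_missing <- rowSums(!is.na(x)) == 0
  dropped <- data.frame(feature_id = ds$feature_meta$feature_id[all_missing],
                        reason = rep("missing in every sample", sum(all_missing)),
                        stringsAsFactors = FALSE)
  if (any(all_missing)) ds <- subset_dataset(ds, features = which(!all_missing))
  x <- log2(ds$intensities)
  nf <- nrow(x)
  todo <- which(rowSums(is.na(x)) > 0)
  if (length(todo) && nf - 1 < k) {
    warning("k clamped from ", k, " to ", max(1, nf - 1))
    k <- max(1, nf - 1)
  }
  if (length(todo)) {
    obs <- !is.na(x)
    for (i in todo) {
      joint <- obs & matrix(obs[i, ], nf, ncol(x), byrow = TRUE)
      nj <- rowSums(joint)
      diff2 <- sweep(x, 2, x[i, ])^2
      diff2[!joint] <- 0
      d <- sqrt(rowSums(diff2, na.rm = TRUE) / pmax(nj, 1))
      d[i] <- Inf
      d[nj < 2] <- Inf
      for (s in which(is.na(x[i, ]))) {
        cand <- which(obs[, s] & is.finite(d))
        if (!length(cand)) next
        cand <- cand[order(d[cand], cand)]
        nb <- cand[seq_len(min(k, length(cand)))]
        w <- 1 / (d[nb] + 1e-9)
        x[i, s] <- sum(w * x[nb, s]) / sum(w)
      }
      if (anyNA(x[i, ])) {
        x[i, is.na(x[i, ])] <- mean(x[i, ], na.rm = TRUE)
      }
    }
  }
  out <- omics_dataset(2^x, ds$feature_meta, ds$sample_meta)
  list(dataset = out, report = preprocess_report("knn_impute", out, dropped))
}

#' NOMIS normalization against multiple internal standards
#'
#' Removes the variation each feature shares with the spiked internal
#' standards: on the log2 scale, with S the sample-centered matrix of
#' internal-standard intensities, each feature x is replaced by
#' x - S b, where b is the least-squares solution of
#' min ||x_centered - S b||^2 (feature mean restored). Internal
#' standards are removed from the output. A rank-deficient S (duplicated
#' standards) falls back to ridge with lambda = 1e-8 and a warning.
#'
#' @param ds an [omics_dataset()] with no missing values in the standards.
#' @param standards feature ids of the internal standards; defaults to
#'   the features flagged `is_internal_standard`.
#' @return normalized `omics_dataset` without the standard rows.
#' @export
nomis_normalize <- function(ds, standards = NULL) {
  validate_omics_dataset(ds)
  fm <- ds$feature_meta
  if (is.null(standards)) standards <- fm$feature_id[fm$is_internal_standard]
  si <- match(standards, fm$feature_id)
  if (!length(si) || anyNA(si)) stop("internal standards not found in dataset")
  if (length(si) >= ncol(ds$intensities))
    stop("need fewer internal standards than samples")
  x <- log2(ds$intensities)
  if (anyNA(x[si, ])) stop("internal standards must be complete (impute first)")
  S <- t(x[si, , drop = FALSE])              # samples x IS
  S <- scale(S, center = TRUE, scale = FALSE)
  G <- crossprod(S)
  rk <- qr(S)$rank
  if (rk < ncol(S)) {
    warning("rank-deficient internal-standard matrix; ridge fallback (lambda = 1e-8)")
    G <- G + diag(1e-8, ncol(S))
  }
  Ginv_St <- solve(G, t(S))
  keep <- setdiff(seq_len(nrow(x)), si)
  for (i in keep) {
    xi <- x[i, ]
    ok <- !is.na(xi)
    if (sum(ok) < 2) next
    xc <- xi[ok] - mean(xi[ok])
    b <- if (all(ok)) Ginv_St %*% xc else {
      Ss <- S[ok, , drop = FALSE]
      solve(crossprod(Ss) + diag(1e-8, ncol(Ss)), crossprod(Ss, xc))
    }
    fit <- if (all(ok)) as.numeric(S %*% b) else as.numeric(S[ok, , drop = FALSE] %*% b)
    x[i, ok] <- xi[ok] - fit
  }
  omics_dataset(2^x[keep, , drop = FALSE], fm[keep, , drop = FALSE],
                ds$sample_meta)
}

#' Pooled-QC coefficient of variation
#'
#' Raw-scale CV (percent) over the non-missing pooled-QC intensities of
#' each feature: 100 * sd / mean. Features with fewer than 2 QC values
#' are reported as `NA` (undefined).
#'
#' @param ds an [omics_dataset()].
#' @return named numeric vector (percent), one entry per feature.
#' @export
qc_cv <- function(ds) {
  validate_omics_dataset(ds)
  qc <- which(ds$sample_meta$role == "pooled_qc")
  if (length(qc) < 2) stop("need at least 2 pooled-QC samples")
  apply(ds$intensities[, qc, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
}

preprocess_report <- function(step, ds, dropped = NULL) {
  structure(list(steps = data.frame(step = step,
                                    n_features = nrow(ds$intensities),
                                    stringsAsFactors = FALSE),
                 qc_cv = list(),
                 dropped = if (is.null(dropped))
                   data.frame(feature_id = character(), reason = character())
                 else dropped),
            class = "preprocess_report")
}

merge_reports <- function(...) {
  reps <- list(...)
  structure(list(steps = do.call(rbind, lapply(reps, `[[`, "steps")),
                 qc_cv = do.call(c, lapply(reps, `[[`, "qc_cv")),
                 dropped = do.call(rbind, lapply(reps, `[[`, "dropped"))),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  for (i in seq_len(nrow(x$steps))) {
    cv <- x$qc_cv[[x$steps$step[i]]]
    cat(sprintf("  %-18s %4d features%s\n", x$steps$step[i],
                x$steps$n_features[i],
                if (!is.null(cv)) sprintf("  median QC CV %.2f%%",
                                          stats::median(cv, na.rm = TRUE)) else ""))
  }
  if (nrow(x$dropped)) cat("  dropped:", nrow(x$dropped), "features\n")
  invisible(x)
}

#' Full preprocessing chain
#'
#' Runs, in order: lipid line consolidation, presence filter, QC-RFSC
#' drift correction, knn imputation and NOMIS normalization, recording
#' the per-step feature count and pooled-QC CV distribution. Each step
#' can be switched off. Proteomics layers, which arrive
#' vendor-normalized, are conventionally run with all LC-MS steps
#' disabled.
#'
#' @param ds an [omics_dataset()].
#' @param design a [matched_design()].
#' @param steps character subset of
#'   `c("consolidate", "presence", "drift", "impute", "normalize")`.
#' @param min_frac,presence_rule passed to [presence_filter()].
#' @param n_trees,reference passed to [qc_rfsc_correct()].
#' @param k passed to [knn_impute()].
#' @param seed RNG seed for the drift forests.
#' @return list with `dataset` and `report` (per-step QC CV included).
#' @export
preprocess <- function(ds, design,
                       steps = c("consolidate", "presence", "drift",
                                 "impute", "normalize"),
                       min_frac = 0.5, presence_rule = "any",
                       n_trees = 500, reference = "median", k = 10,
                       seed = 1) {
  reports <- list(preprocess_report("input", ds))
  has_qc <- sum(ds$sample_meta$role == "pooled_qc") >= 2
  record_cv <- function(rep_, d) {
    if (has_qc) rep_$qc_cv <- stats::setNames(list(qc_cv(d)), rep_$steps$step)
    rep_
  }
  reports[[1]] <- record_cv(reports[[1]], ds)
  if ("consolidate" %in% steps) {
    ds <- consolidate_lipid_lines(ds)
    reports <- c(reports, list(record_cv(preprocess_report("consolidate", ds), ds)))
  }
  if ("presence" %in% steps) {
    pf <- presence_filter(ds, design, min_frac = min_frac,
                          rule = presence_rule)
    ds <- pf$dataset
    reports <- c(reports, list(record_cv(pf$report, ds)))
  }
  if ("drift" %in% steps && has_qc) {
    ds <- qc_rfsc_correct(ds, n_trees = n_trees, seed = seed,
                          reference = reference)
    reports <- c(reports, list(record_cv(preprocess_report("drift", ds), ds)))
  }
  if ("impute" %in% steps) {
    im <- knn_impute(ds, k = k)
    ds <- im$dataset
    reports <- c(reports, list(record_cv(im$report, ds)))
  }
  if ("normalize" %in% steps &&
      any(ds$feature_meta$is_internal_standard)) {
    ds <- nomis_normalize(ds)
    reports <- c(reports, list(record_cv(preprocess_report("normalize", ds), ds)))
  }
  list(dataset = ds, report = do.call(merge_reports, reports))
}
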