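check_bn_input <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%03d", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  if (any(!is.finite(x))) stop("non-finite values in network input")
  if (nrow(x) < 3) stop("need at least 3 samples for structure learning")
  x
}

#' Hill-climbing Gaussian Bayesian-network structure learning
#'
#' Greedy search over directed acyclic graphs maximizing the Gaussian
#' BIC score, starting from the empty graph with add/remove/reverse
#' operators and the in-degree capped at `max_parents`. Candidate order
#' is shuffled by the seed (ties are then deterministic); columns are
#' canonicalized by feature name first, so the result does not depend on
#' input column order.
#'
#' @param data numeric matrix, samples x features (log2-transformed,
#'   standardized continuous data).
#' @param max_parents in-degree cap (default 4).
#' @param seed integer seed.
#' @return adjacency matrix (parent row -> child column), dimnames =
#'   feature names in the input's column order.
#' @export
learn_structure <- function(data, max_parents = 4, seed = 1) {
  x <- check_bn_input(data)
  ord <- order(colnames(x))
  adj <- hc_cpp(x[, ord, drop = FALSE], as.integer(max_parents),
                as.integer(seed %% 2147483647))
  adj <- matrix(as.integer(adj), ncol(x), ncol(x),
                dimnames = list(colnames(x)[ord], colnames(x)[ord]))
  adj[colnames(x), colnames(x)]
}

#' Bootstrap model-averaged edge strengths
#'
#' Learns a structure on `B` bootstrap resamples and reports, for every
#' feature pair, the fraction of bootstrap DAGs whose skeleton contains
#' the edge (direction discarded). Resampling draws whole samples with
#' replacement, or whole matched pairs when `resample_unit = "pair"`.
#'
#' @inheritParams learn_structure
#' @param B bootstrap replicates (default 1000).
#' @param resample_unit `"sample"` or `"pair"`.
#' @param pair_of with `"pair"`: vector mapping each row of `data` to its
#'   pair id.
#' @return data.frame `from`, `to`, `strength_raw` for every pair with
#'   non-zero strength (`from < to`), with attribute `"n_features"`.
#' @export
bootstrap_strengths <- function(data, B = 1000,
                                resample_unit = c("sample", "pair"),
                                pair_of = NULL, max_parents = 4, seed = 1) {
  resample_unit <- match.arg(resample_unit)
  if (B < 1) stop("B must be >= 1")
  x <- check_bn_input(data)
  n <- nrow(x)
  ord <- order(colnames(x))
  xs <- x[, ord, drop = FALSE]
  idx <- with_seed(sub_seed(seed, "boot-idx"), {
    if (resample_unit == "sample") {
      matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    } else {
      if (is.null(pair_of) || length(pair_of) != n)
        stop("pair resampling needs pair_of for every row")
      groups <- split(seq_len(n), pair_of)
      ng <- length(groups)
      do.call(cbind, lapply(seq_len(B), function(b)
        unlist(groups[sample.int(ng, ng, replace = TRUE)], use.names = FALSE)))
    }
  })
  strength <- hc_bootstrap_cpp(xs, idx, as.integer(max_parents),
                               as.integer(seed %% 2147483647))
  dimnames(strength) <- list(colnames(xs), colnames(xs))
  ut <- which(upper.tri(strength) & strength > 0, arr.ind = TRUE)
  out <- data.frame(from = rownames(strength)[ut[, 1]],
                    to = colnames(strength)[ut[, 2]],
                    strength_raw = strength[ut],
                    stringsAsFactors = FALSE)
  sw <- out$from > out$to
  tmp <- out$from[sw]; out$from[sw] <- out$to[sw]; out$to[sw] <- tmp
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_features") <- ncol(x)
  attr(out, "feature_names") <- colnames(x)
  out
}

#' Boost edge strengths with external knowledge
#'
#' Default boost form: modified = 1 - (1 - raw)(1 - weight k), with k = 1
#' when the edge appears in the knowledge graph and 0 otherwise — maps
#' [0,1] to [0,1], is monotone in both arguments, and never penalizes
#' unlisted edges. The alternative `"mixture"` mode is the convex blend
#' (1 - weight) raw + weight k. Knowledge edges between known features
#' that the bootstrap never produced are added with raw strength 0 so a
#' strong prior can still surface them.
#'
#' @param strengths data.frame from [bootstrap_strengths()].
#' @param kg a [knowledge_graph()] (or NULL for no modification).
#' @param weight prior weight in [0,1] (default 0.3).
#' @param mode `"boost"` (default) or `"mixture"`.
#' @return the data.frame with a `strength_modified` column appended.
#' @export
apply_knowledge <- function(strengths, kg = NULL, weight = 0.3,
                            mode = c("boost", "mixture")) {
  mode <- match.arg(mode)
  if (weight < 0 || weight > 1) stop("weight must be in [0,1]")
  out <- strengths
  if (is.null(kg) || !nrow(kg)) {
    # no knowledge supplied: no modification, in either mode
    out$strength_modified <- out$strength_raw
    return(out)
  }
  feats <- attr(strengths, "feature_names")
  kk <- kg[!is.na(match(kg$from, feats)) & !is.na(match(kg$to, feats)), ,
           drop = FALSE]
  new <- kk[!(edge_key(kk$from, kk$to) %in% edge_key(out$from, out$to)), ,
            drop = FALSE]
  if (nrow(new)) {
    add <- data.frame(from = pmin(new$from, new$to),
                      to = pmax(new$from, new$to),
                      strength_raw = 0, stringsAsFactors = FALSE)
    atts <- attributes(out)
    out <- rbind(out, add)
    attr(out, "n_features") <- atts$n_features
    attr(out, "feature_names") <- atts$feature_names
  }
  kappa <- as.numeric(edge_key(out$from, out$to) %in% edge_key(kg$from, kg$to))
  out$strength_modified <- if (mode == "boost")
    1 - (1 - out$strength_raw) * (1 - weight * kappa)
  else (1 - weight) * out$strength_raw + weight * kappa
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Data-driven edge-strength significance threshold
#'
#' Matches the empirical CDF of the strengths to the nearest (in L1)
#' ideal two-point CDF: q-hat minimizes the integral over s in [0,1] of
#' |F(s) - q|, i.e. it is the length-weighted median of the step values
#' of F; the threshold is the q-hat quantile of the strengths
#' (interpolating type-7 quantile). Edges strictly above the threshold
#' are significant. All-equal strengths are degenerate: the threshold is
#' that value and nothing is significant.
#'
#' @param strengths numeric vector in [0,1].
#' @return list `threshold`, `qhat`, `degenerate`.
#' @export
scutari_threshold <- function(strengths) {
  s <- strengths[!is.na(strengths)]
  if (!length(s)) stop("need at least one strength value")
  if (any(s < 0 | s > 1)) stop("strengths must lie in [0,1]")
  if (length(unique(s)) == 1)
    return(list(threshold = s[1], qhat = NA_real_, degenerate = TRUE))
  v <- sort(unique(s))
  Fv <- stats::ecdf(s)(v)
  # step pieces of F over [0,1]: value 0 on [0, v1), Fk on [vk, v(k+1)), 1 tail
  vals <- c(0, Fv)
  wts <- c(v[1], diff(c(v, 1)))
  keep <- wts > 0
  vals <- vals[keep]; wts <- wts[keep]
  cw <- cumsum(wts) / sum(wts)
  qhat <- vals[which(cw >= 0.5)[1]]
  list(threshold = unname(stats::quantile(s, qhat, type = 7)),
       qhat = qhat, degenerate = FALSE)
}

consensus_network_object <- function(nodes, edges, threshold,
                                     subnetworks = NULL, qhat = NA_real_) {
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 qhat = qhat, subnetworks = subnetworks),
            class = "consensus_network")
}

#' Assemble the consensus multi-omics network
#'
#' Retains the edges with modified strength strictly above the threshold,
#' takes their endpoints as nodes, and reports the connected components
#' with at least two molecules (largest first), flagging heterogeneous
#' components that span more than one omics layer.
#'
#' @param strengths data.frame with `strength_modified` (from
#'   [apply_knowledge()]).
#' @param threshold numeric cutoff (from [scutari_threshold()]).
#' @param feature_meta data.frame with `feature_id` and `layer` covering
#'   the edge endpoints.
#' @return a `consensus_network`: `nodes`, `edges`, `threshold`,
#'   `subnetworks` (list of data.frames with a `heterogeneous` attribute).
#' @export
consensus_network <- function(strengths, threshold, feature_meta) {
  keep <- strengths$strength_modified > threshold
  edges <- strengths[keep, c("from", "to", "strength_raw",
                             "strength_modified"), drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$from, edges$to)))
  layer <- feature_meta$layer[match(ids, feature_meta$feature_id)]
  nodes <- data.frame(feature_id = ids, layer = layer,
                      stringsAsFactors = FALSE)
  subnets <- list()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE, vertices = ids)
    comp <- igraph::components(g)
    ord <- order(-comp$csize)
    for (ci in ord[comp$csize[ord] >= 2]) {
      members <- ids[comp$membership == ci]
      sub <- nodes[nodes$feature_id %in% members, , drop = FALSE]
      attr(sub, "heterogeneous") <- length(unique(sub$layer)) >= 2
      subnets <- c(subnets, list(sub))
    }
  }
  consensus_network_object(nodes, edges, threshold, subnets)
}

#' @export
print.consensus_network <- function(x, ...) {
  het <- sum(vapply(x$subnetworks, function(s)
    isTRUE(attr(s, "heterogeneous")), logical(1)))
  cat(sprintf(
    "<consensus_network> %d nodes, %d edges (threshold %.3f), %d subnetworks (%d heterogeneous)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, length(x$subnetworks), het))
  invisible(x)
}

#' End-to-end multi-omics network integration
#'
#' Standardizes the log2 molecule table, bootstraps edge strengths,
#' applies external-knowledge boosting, estimates the significance
#' threshold on the modified strengths, and assembles the consensus
#' network.
#'
#' @param ds an [omics_dataset()] (typically [combine_layers()] output
#'   restricted to the significant molecules).
#' @param kg optional [knowledge_graph()].
#' @param B bootstrap replicates (default 1000).
#' @param weight knowledge weight (default 0.3).
#' @param knowledge_mode `"boost"` (default; knowledge can only raise
#'   strengths) or `"mixture"` (knowledge both supports listed edges and
#'   shrinks unlisted ones) — see [apply_knowledge()].
#' @param resample_unit,max_parents,seed see [bootstrap_strengths()].
#' @return a `consensus_network`.
#' @export
network_integration <- function(ds, kg = NULL, B = 1000, weight = 0.3,
                                knowledge_mode = "boost",
                                resample_unit = "sample", max_parents = 4,
                                seed = 1) {
  validate_omics_dataset(ds)
  sm <- ds$sample_meta
  study <- sm$sample_id[sm$role == "study"]
  sub <- subset_dataset(ds, samples = study)
  x <- t(scale(t(log2(sub$intensities))))
  x <- x[apply(x, 1, function(r) all(is.finite(r))), , drop = FALSE]
  data <- t(x)
  pair_of <- sub$sample_meta$pair_id[match(rownames(data),
                                           sub$sample_meta$sample_id)]
  raw <- bootstrap_strengths(data, B = B, resample_unit = resample_unit,
                             pair_of = pair_of, max_parents = max_parents,
                             seed = seed)
  mod <- apply_knowledge(raw, kg, weight = weight, mode = knowledge_mode)
  # threshold estimated on the data-driven (raw) strengths — so adding
  # knowledge is monotone in boost mode: it can only admit edges, never
  # raise the bar they must clear — over ALL feature pairs: pairs never
  # produced by any bootstrap count as strength 0, which is what lets
  # the estimator return "nothing significant" on structureless data
  p <- attr(raw, "n_features")
  all_strengths <- c(raw$strength_raw,
                     numeric(p * (p - 1) / 2 - nrow(raw)))
  thr <- scutari_threshold(all_strengths)
  net <- consensus_network(mod, thr$threshold, ds$feature_meta)
  net$qhat <- thr$qhat
  net
}
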