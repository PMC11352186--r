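#' Simulation configuration
#'
#' Parameters of the matched case-control multi-omics generator. The
#' defaults emulate a preoperative-CSF acquisition: 15 matched pairs
#' measured on three layers (219 metabolites, 161 lipids, 1305
#' proteins), log-normal intensities spanning orders of magnitude,
#' interleaved pooled-QC injections with a smooth injection-order drift
#' on the LC-MS layers, intensity-dependent (MNAR) missingness, spiked
#' internal standards without group effects, a planted differential set
#' with signed log2 fold changes around 0.8 (typical robust fold changes
#' 1.1-2.5), and a planted cross-layer interaction network realized by
#' per-edge shared latent factors (pairwise correlation ~0.66 at
#' defaults).
#'
#' @param n_pairs matched pairs.
#' @param n_features,n_differential,n_internal_standards named integer
#'   vectors over layers `metabolite`, `lipid`, `protein`.
#' @param effect_log2fc,effect_sd mean and sd of planted |log2 FC|.
#' @param base_log_mean,base_log_sd feature baseline distribution (log2).
#' @param drift_amplitude relative drift amplitude a of the multiplier
#'   1 + a (o/o_max) + 0.3 a sin(2 pi o/o_max); applied to the LC-MS
#'   layers (metabolites, lipids) only.
#' @param n_qc pooled-QC injections per LC-MS layer (>= 3).
#' @param missing_rate,missing_mnar_strength MNAR mechanism: missingness
#'   probability `missing_rate * plogis(-missing_mnar_strength * z)`, z
#'   the within-layer z-score of the log2 intensity.
#' @param network_edges planted cross-layer edges (a random disjoint
#'   matching over non-standard features).
#' @param noise_log_sd residual per-measurement log2 sd.
#' @param pair_sd log2 sd of the random effect shared by both members of
#'   a pair (what makes paired tests more powerful here).
#' @param tech_sd log2 sd of the per-sample technical factor loading on
#'   every feature of a layer (what NOMIS removes).
#' @param factor_sd log2 sd of the per-edge latent factor.
#' @param qc_noise_sd technical log2 noise of QC injections; suppressed
#'   when `drift_amplitude == 0 && missing_rate == 0` so the no-noise
#'   limit is exact.
#' @param seed integer; identical seeds give bit-identical studies.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 15,
                              n_features = c(metabolite = 219, lipid = 161,
                                             protein = 1305),
                              n_differential = c(metabolite = 20, lipid = 12,
                                                 protein = 20),
                              n_internal_standards = c(metabolite = 4,
                                                       lipid = 4, protein = 0),
                              effect_log2fc = 0.8, effect_sd = 0.3,
                              base_log_mean = 20, base_log_sd = 2,
                              drift_amplitude = 0.2, n_qc = 8,
                              missing_rate = 0.05, missing_mnar_strength = 1,
                              network_edges = 40, noise_log_sd = 0.25,
                              pair_sd = 0.4, tech_sd = 0.2, factor_sd = 0.55,
                              qc_noise_sd = 0.02, seed = 1) {
  cfg <- as.list(environment())
  layers <- c("metabolite", "lipid", "protein")
  for (f in c("n_features", "n_differential", "n_internal_standards")) {
    v <- cfg[[f]]
    if (is.null(names(v))) names(v) <- layers[seq_along(v)]
    cfg[[f]] <- v[layers]
    cfg[[f]][is.na(cfg[[f]])] <- 0
    names(cfg[[f]]) <- layers
  }
  if (any(cfg$n_differential + cfg$n_internal_standards > cfg$n_features))
    stop("n_differential + internal standards exceeds n_features")
  if (n_qc < 3) stop("n_qc must be >= 3")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (missing_mnar_strength < 0) stop("missing_mnar_strength must be >= 0")
  structure(cfg, class = "simulation_config")
}

drift_multiplier <- function(order, max_order, amplitude) {
  1 + amplitude * (order / max_order) +
    0.3 * amplitude * sin(2 * pi * order / max_order)
}

#' Generate a matched case-control multi-omics study
#'
#' Draws one dataset per omics layer plus the matched design and the
#' ground truth needed for parameter recovery. Study intensities are
#' 2^(baseline + pair effect + sample technical factor + planted group
#' effect + edge latent factors + noise), multiplied by the
#' injection-order drift on LC-MS layers, then masked MNAR. Pooled-QC
#' injections are the across-study-sample mean of the pre-drift signal,
#' placed at evenly spaced injection positions. Internal standards carry
#' only the technical factor and small noise (no biology).
#'
#' @param config a [simulation_config()].
#' @return list with `datasets` (named list of [omics_dataset()]),
#'   `design` ([matched_design()]) and `truth` (class `synthetic_truth`:
#'   `differential`, `planted_network`, `drift_curve`, `missing_mask`,
#'   `pair_effects`, `config`).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  layers <- c("metabolite", "lipid", "protein")
  prefix <- c(metabolite = "met", lipid = "lip", protein = "pro")
  np <- cfg$n_pairs
  case_ids <- sprintf("case_%02d", seq_len(np))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(np))
  pair_ids <- sprintf("pair_%02d", seq_len(np))
  design <- matched_design(case_ids, ctrl_ids)
  study_ids <- c(rbind(case_ids, ctrl_ids))   # interleaved case/ctrl
  pair_of <- rep(pair_ids, each = 2)
  group_of <- rep(c("DEL", "CNT"), np)

  # per-pair effect-size multipliers, shared across layers
  m_pair <- stats::rnorm(np, 1, 0.2)
  names(m_pair) <- pair_ids

  feat <- list()
  for (ly in layers) {
    nf <- cfg$n_features[[ly]]
    if (nf == 0) next
    nis <- cfg$n_internal_standards[[ly]]
    ids <- sprintf("%s_%03d", prefix[[ly]], seq_len(nf))
    is_is <- rep(FALSE, nf)
    if (nis > 0) {
      is_is[seq_len(nis)] <- TRUE
      ids[seq_len(nis)] <- sprintf("%s_IS%d", prefix[[ly]], seq_len(nis))
    }
    feat[[ly]] <- data.frame(feature_id = ids, layer = ly,
                             is_internal_standard = is_is,
                             consolidation_key = "",
                             stringsAsFactors = FALSE)
  }
  all_feat <- do.call(rbind, feat)
  eligible <- all_feat$feature_id[!all_feat$is_internal_standard]

  differential <- do.call(rbind, lapply(layers, function(ly) {
    fm <- feat[[ly]]
    if (is.null(fm)) return(NULL)
    nd <- cfg$n_differential[[ly]]
    if (nd == 0) return(NULL)
    pick <- sample(fm$feature_id[!fm$is_internal_standard], nd)
    mag <- pmax(0.2, stats::rnorm(nd, cfg$effect_log2fc, cfg$effect_sd))
    sgn <- sample(c(-1, 1), nd, replace = TRUE)
    data.frame(feature_id = pick, layer = ly, log2fc = sgn * mag,
               stringsAsFactors = FALSE)
  }))
  if (is.null(differential))
    differential <- data.frame(feature_id = character(), layer = character(),
                               log2fc = numeric(), stringsAsFactors = FALSE)

  ne <- min(cfg$network_edges, floor(length(eligible) / 2))
  net_nodes <- sample(eligible, 2 * ne)
  planted_network <- data.frame(
    from = pmin(net_nodes[seq_len(ne) * 2 - 1], net_nodes[seq_len(ne) * 2]),
    to = pmax(net_nodes[seq_len(ne) * 2 - 1], net_nodes[seq_len(ne) * 2]),
    stringsAsFactors = FALSE)
  g_factor <- matrix(stats::rnorm(ne * 2 * np, 0, cfg$factor_sd),
                     nrow = ne, ncol = 2 * np,
                     dimnames = list(NULL, study_ids))

  exact_limit <- cfg$drift_amplitude == 0 && cfg$missing_rate == 0
  datasets <- list()
  drift_curve <- list()
  missing_mask <- list()
  for (ly in layers) {
    fm <- feat[[ly]]
    if (is.null(fm)) next
    nf <- nrow(fm)
    lcms <- ly != "protein"
    n_qc <- if (lcms) cfg$n_qc else 0
    nsamp <- 2 * np + n_qc
    b <- stats::rnorm(nf, cfg$base_log_mean, cfg$base_log_sd)
    t_s <- stats::rnorm(2 * np, 0, cfg$tech_sd)

    L <- matrix(b, nf, 2 * np)               # log2 latent study signal
    L <- L + matrix(t_s, nf, 2 * np, byrow = TRUE)
    bio <- !fm$is_internal_standard
    # subject-level biology shared within a pair, independent per feature:
    # this is what makes paired tests strictly more powerful here
    U <- matrix(stats::rnorm(nf * np, 0, cfg$pair_sd), nf, np)
    L[bio, ] <- L[bio, ] + U[bio, match(pair_of, pair_ids)]
    d_ly <- differential[differential$layer == ly, , drop = FALSE]
    if (nrow(d_ly)) {
      ridx <- match(d_ly$feature_id, fm$feature_id)
      del_cols <- which(group_of == "DEL")
      L[ridx, del_cols] <- L[ridx, del_cols] +
        outer(d_ly$log2fc, m_pair[pair_of[del_cols]])
    }
    on_edge <- cbind(match(planted_network$from, fm$feature_id),
                     match(planted_network$to, fm$feature_id))
    for (e in seq_len(ne)) {
      for (side in 1:2) {
        ri <- on_edge[e, side]
        if (!is.na(ri)) L[ri, ] <- L[ri, ] + g_factor[e, ]
      }
    }
    noise_sd <- ifelse(fm$is_internal_standard, 0.02, cfg$noise_log_sd)
    L <- L + matrix(stats::rnorm(nf * 2 * np), nf) * noise_sd

    # pooled QC: mean of study pre-drift raw signals; each injection gets
    # its own technical factor (same kind NOMIS removes) plus small noise,
    # both suppressed in the exact no-noise limit
    qc_log <- NULL
    if (n_qc > 0) {
      qc_base <- log2(rowMeans(2^L))
      qc_log <- matrix(qc_base, nf, n_qc)
      if (!exact_limit) {
        t_qc <- stats::rnorm(n_qc, 0, cfg$tech_sd)
        qc_log <- qc_log + matrix(t_qc, nf, n_qc, byrow = TRUE) +
          matrix(stats::rnorm(nf * n_qc, 0, cfg$qc_noise_sd), nf)
      }
    }

    # injection layout: QC at evenly spaced positions, study shuffled
    qc_pos <- if (n_qc > 0) unique(round(seq(1, nsamp, length.out = n_qc))) else integer()
    while (length(qc_pos) < n_qc)             # guard tiny layouts
      qc_pos <- sort(unique(c(qc_pos, sample(setdiff(seq_len(nsamp), qc_pos), 1))))
    study_pos <- sample(setdiff(seq_len(nsamp), qc_pos))
    X <- 2^cbind(L, qc_log)
    orders <- c(study_pos, qc_pos)
    dc <- rep(1, nsamp)
    if (lcms && cfg$drift_amplitude > 0)
      dc <- drift_multiplier(seq_len(nsamp), nsamp, cfg$drift_amplitude)
    X <- X * matrix(dc[orders], nf, ncol(X), byrow = TRUE)
    drift_curve[[ly]] <- dc

    mask <- matrix(FALSE, nf, ncol(X))
    if (cfg$missing_rate > 0 && lcms) {
      lx <- log2(X)
      z <- (lx - mean(lx)) / stats::sd(lx)
      pm <- cfg$missing_rate * stats::plogis(-cfg$missing_mnar_strength * z)
      pm[fm$is_internal_standard, ] <- 0
      mask <- matrix(stats::runif(length(pm)) < pm, nf)
      X[mask] <- NA_real_
    }
    rownames(mask) <- fm$feature_id
    missing_mask[[ly]] <- mask

    sm <- data.frame(
      sample_id = c(study_ids,
                    if (n_qc) sprintf("qc_%s_%02d", prefix[[ly]], seq_len(n_qc))),
      role = c(rep("study", 2 * np), rep("pooled_qc", n_qc)),
      group = c(group_of, rep("none", n_qc)),
      pair_id = c(pair_of, rep("", n_qc)),
      injection_order = as.integer(orders),
      stringsAsFactors = FALSE)
    datasets[[ly]] <- omics_dataset(X, fm, sm)
  }

  truth <- structure(list(differential = differential,
                          planted_network = planted_network,
                          drift_curve = drift_curve,
                          missing_mask = missing_mask,
                          pair_effects = m_pair,
                          config = cfg),
                     class = "synthetic_truth")
  list(datasets = datasets, design = design, truth = truth)
}

#' Generate a synthetic external knowledge graph
#'
#' Stand-in for curated pathway-database edges: each planted edge is
#' included independently with probability `recall`, and
#' `round(spurious_fraction * n_planted)` random non-planted edges over
#' the same feature universe are added.
#'
#' @param truth `synthetic_truth` from [generate_study()].
#' @param recall inclusion probability of each planted edge.
#' @param spurious_fraction spurious edges as a fraction of the planted
#'   edge count.
#' @param seed integer seed.
#' @return a [knowledge_graph()] with sources `"planted"` / `"spurious"`.
#' @export
generate_knowledge_graph <- function(truth, recall = 0.8,
                                     spurious_fraction = 0.5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (recall < 0 || recall > 1) stop("recall must be in [0,1]")
  if (spurious_fraction < 0) stop("spurious_fraction must be >= 0")
  pn <- truth$planted_network
  with_seed(seed, {
    keep <- stats::runif(nrow(pn)) < recall
    n_sp <- round(spurious_fraction * nrow(pn))
    univ <- unlist(lapply(truth$missing_mask, rownames), use.names = FALSE)
    if (is.null(univ) || !length(univ))
      univ <- unique(c(pn$from, pn$to))
    planted_keys <- edge_key(pn$from, pn$to)
    sp_from <- character(); sp_to <- character()
    guard <- 0
    while (length(sp_from) < n_sp && guard < 100 * max(n_sp, 1)) {
      guard <- guard + 1
      pick <- sample(univ, 2)
      k <- edge_key(pick[1], pick[2])
      if (pick[1] == pick[2] || k %in% planted_keys ||
          k %in% edge_key(sp_from, sp_to)) next
      sp_from <- c(sp_from, pick[1]); sp_to <- c(sp_to, pick[2])
    }
    knowledge_graph(c(pn$from[keep], sp_from), c(pn$to[keep], sp_to),
                    c(rep("planted", sum(keep)), rep("spurious", length(sp_from))))
  })
}

#' Combine per-layer datasets over their shared study samples
#'
#' Stacks the feature tables of several layers over the intersection of
#' their study sample ids (pooled-QC injections are layer-specific and
#' are dropped). Used to assemble the multi-omics molecule table for
#' network integration and multi-omics signatures.
#'
#' @param datasets named list of [omics_dataset()] objects.
#' @return a single `omics_dataset`.
#' @export
combine_layers <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  ids <- Reduce(intersect, lapply(datasets, function(d)
    d$sample_meta$sample_id[d$sample_meta$role == "study"]))
  if (!length(ids)) stop("no shared study samples across layers")
  parts <- lapply(datasets, function(d) subset_dataset(d, samples = ids))
  omics_dataset(do.call(rbind, lapply(parts, `[[`, "intensities")),
                do.call(rbind, lapply(parts, `[[`, "feature_meta")),
                parts[[1]]$sample_meta)
}
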