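# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# A small hand-built dataset: nf features x (2*np study + n_qc QC)
# samples, constant baseline unless intensities are supplied.
toy_dataset <- function(nf = 4, np = 3, n_qc = 3, intensities = NULL,
                        layer = "metabolite", is_std = rep(FALSE, nf),
                        consolidation_key = rep("", nf)) {
  ns <- 2 * np + n_qc
  if (is.null(intensities))
    intensities <- matrix(100, nf, ns)
  fm <- data.frame(feature_id = sprintf("f%02d", seq_len(nf)),
                   layer = layer, is_internal_standard = is_std,
                   consolidation_key = consolidation_key,
                   stringsAsFactors = FALSE)
  sm <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(np)),
                  sprintf("ctrl_%02d", seq_len(np)),
                  if (n_qc) sprintf("qc_%02d", seq_len(n_qc))),
    role = c(rep("study", 2 * np), rep("pooled_qc", n_qc)),
    group = c(rep("DEL", np), rep("CNT", np), rep("none", n_qc)),
    pair_id = c(sprintf("p%02d", seq_len(np)), sprintf("p%02d", seq_len(np)),
                rep("", n_qc)),
    injection_order = seq_len(ns),
    stringsAsFactors = FALSE)
  omics_dataset(intensities, fm, sm)
}

toy_design <- function(np = 3) {
  matched_design(sprintf("case_%02d", seq_len(np)),
                 sprintf("ctrl_%02d", seq_len(np)))
}

# Independent brute-force oracles ------------------------------------

# BH via the "smallest achievable FDR over rejection thresholds" rule.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi - 1e-15]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t + 1e-15),
                      numeric(1))))
  }, numeric(1))
}

# Exact two-sided signed-rank p by full 2^n enumeration (midranks).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# L1 objective between the empirical strength CDF and the constant q,
# plus its dense-grid minimizer. The minimizer can be an interval, so
# implementation agreement is asserted on the objective value (and q
# within one grid step of some grid minimizer), not on the threshold.
scutari_l1_obj <- function(s, q) {
  sv <- sort(unique(s))
  Fv <- ecdf(s)(sv)
  vals <- c(0, Fv)
  wts <- c(sv[1], diff(c(sv, 1)))
  sum(wts * abs(vals - q))
}

scutari_grid_oracle <- function(s, grid_n = 1001) {
  qs <- seq(0, 1, length.out = grid_n)
  obj <- vapply(qs, function(q) scutari_l1_obj(s, q), numeric(1))
  list(qs_min = qs[obj <= min(obj) + 1e-12], obj_min = min(obj),
       step = qs[2] - qs[1])
}

edge_f1 <- function(net, planted) {
  got <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  want <- paste(pmin(planted$from, planted$to),
                pmax(planted$from, planted$to))
  if (!length(got) && !length(want)) return(1)
  2 * sum(got %in% want) / (length(got) + length(want))
}
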