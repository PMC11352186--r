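---
title: "Methods: matched-pair multi-omics analysis with pairomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-pair multi-omics analysis with pairomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairomics)
```

# Scope and model

pairomics analyses matched case-control multi-omics studies in which
metabolites and lipids are quantified by LC-MS with interleaved pooled-QC
injections, proteins arrive as a vendor-normalized affinity panel, and
every case (DEL) is paired with one control (CNT). The pipeline has five
stages: LC-MS preprocessing, paired differential statistics, signature
selection, clustering/classification evaluation, and probabilistic-graph
network integration. A simulator with planted ground truth backs the
test suite.

# Preprocessing

The chain runs consolidate → presence filter → drift correction →
imputation → normalization, each step optional. Logs are base 2
throughout.

**Lipid line consolidation.** Untargeted lipidomics can split one lipid
over several output lines; rows sharing a `consolidation_key` are summed
per sample before anything else, a cell being missing only when all
contributing cells are. The merged row adopts the key as its id.

**Presence filter.** A feature is "present" when measured in at least
50% of the study samples of a phenotypic group. We read "within a
phenotypic group" as *at least one* group (configurable to *both*): a
group-specific analyte — detectable in cases, absent in controls — is
exactly the kind of signal a matched design can use, so the permissive
reading is the default. Internal standards are always kept.

**QC-RFSC drift correction.** Per feature, a random-forest regression of
the pooled-QC intensities on injection order estimates the drift d(o);
intensities are rescaled by ref/d(o). The rescaling reference is not
fixed by the method's common description, so we default to the *median*
of the feature's QC values (robust to a stray QC injection;
configurable to the mean). The forest has 500 trees, node size 5, and a
single predictor (mtry is trivially 1); with fewer than 3 QC values the
feature passes through, flagged. Because the forest is fit and evaluated
on few points, it partially absorbs injection-specific QC noise — QC CV
after correction is therefore an optimistic estimate of the residual
technical variance, a property shared with any in-sample drift fit. A
visible consequence: for a minority of simulated runs the correction
absorbs so much of the shared per-injection QC factor that the later
normalization step has less shared variance left to remove at the QC
columns than its own least-squares estimation noise adds, so the
per-step QC-CV trajectory is monotone in its *typical* (across-seed
median) form, not for every single run; the corresponding invariant
test asserts exactly that.

**knn imputation.** Feature-wise k-nearest-neighbour imputation on log2
intensities (k = 10): neighbours are *features*, compared by Euclidean
distance per jointly observed sample, and a missing entry is the
inverse-distance-weighted average of the neighbours' values at that
sample. The orientation (feature-wise vs sample-wise) is a design
choice: with tens of samples and hundreds of features, feature
neighbourhoods are far better populated. Observed values are never
altered; features observed nowhere are dropped and reported.

**NOMIS normalization.** On the log2 scale, with S the sample-centered
matrix of internal-standard intensities, each feature x is replaced by
x − S b̂ with b̂ the least-squares solution of min ‖x_c − S b‖²; the
feature mean is restored and the standards removed from the output. A
rank-deficient S (duplicated standards) falls back to ridge with
λ = 1e-8 and a warning. Two exact consequences anchor the tests: a
feature equal to a standard plus a constant is flattened to numerical
zero variance, and a feature orthogonal to the centered standards is
untouched.

**Proteomics bypass.** Whether an affinity proteomics panel should
re-enter the LC-MS chain is not determined by the data model; the
default is that proteins bypass preprocessing (they arrive
vendor-normalized and complete), configurable per run.

# Paired differential statistics

Three tests per feature capture degree, rank and direction of the
paired difference: the paired t-test (on log2 intensities — the scale
on which LC-MS effects are approximately additive), the Wilcoxon
signed-rank test and the exact sign test (both on raw differences;
their statistics depend only on signs and ranks, so any monotone
rescaling gives the same p). The signed-rank null is computed exactly
for n ≤ 25 usable pairs by dynamic programming over doubled midranks
(ties handled exactly); beyond that, the normal approximation with tie
and continuity corrections, which agrees with the exact distribution to
< 0.005 at the boundary. BH correction is applied per test *within each
omics layer*, since each layer's panel is its own family of hypotheses;
the reported `bh_min` is the BH value of the test that achieved the
minimum p. A feature is flagged significant when its smallest nominal p
is below α = 0.05.

**Robust fold change.** Per pair the DEL/CNT ratio r is mapped to the
signed fold f = r (r ≥ 1) or −1/r (r < 1), and the one-step Tukey
biweight location of {f} is reported (c = 5, ε = 1e-4, unscaled MAD —
the classic one-step constants). The signed-fold-then-biweight order
matters: averaging signed folds of disagreeing pairs can land inside
(−1, 1), which pure ratio-then-sign transforms cannot produce, and such
magnitudes do occur in practice. A constant ratio is returned exactly;
a wild pair gets weight ≈ 0.

# Signature selection

The high-fold-change signature keeps significant features with
|tFC| strictly above 1.5. Refinement runs one elastic-net logistic fit
per leave-one-out iteration (α_mix = 0.5 — unspecified upstream, exposed
in the configuration), picking λ at the minimum 3-fold cross-validated
deviance on a 100-point path down to λ_max·1e-4, and keeps features with
non-zero coefficients in strictly more than half of the iterations.
CV fold membership is derived by hashing sample ids with the seed, so
results are invariant to sample and feature order and reproducible
across machines; a fold that would contain one class is re-drawn with a
warning.

# Evaluation

**UPGMA.** Features are standardized across samples, sample distance is
1 − Pearson correlation, linkage is average, and the tree is cut at
k = 2. The misclustered count minimizes over the two cluster↔label
assignments; cluster-phenotype association is the two-sided Fisher
exact test.

**PCA+SVM.** Log2 data are mean-centered per feature and projected onto
the top 2 principal components (2 matches the common decision-plane
visualization; configurable) before a C-SVC with linear, cubic
polynomial, or Gaussian kernel (C = 1; Gaussian width
1/(n_components × mean feature variance)). Centering and projection are
computed inside each leave-one-out fold by default (`per_fold`); the
`global` scope — one projection from all samples — is provided for
comparability with published single-projection analyses and is the mode
used when reproducing external headline numbers, with the leakage
caveat documented. The SVM is solved by a deterministic SMO (no random
working-set selection), so repeated runs agree bit-for-bit. The
reported headline is the best of the three kernels by leave-one-out
accuracy, ties broken linear > poly > rbf. AUC uses midranks; its 95%
CI is a stratified percentile bootstrap (2000 resamples, seeded) —
the CI method upstream analyses rarely state, so bootstrap was chosen
for its lack of distributional assumptions.

# Network integration

The significant molecules from all layers are standardized and fed to
hill-climbing Gaussian Bayesian-network structure learning (BIC score,
add/remove/reverse operators, empty start, in-degree ≤ 4 — a
tractability cap at ~100 nodes and ~30 samples). Structure learning is
repeated on B = 1000 bootstrap resamples (whole samples by default;
whole matched pairs selectable, since samples of a pair are not
independent); an edge's raw strength is the fraction of bootstrap
skeletons containing it, direction discarded because the final object
is an undirected interaction network. External knowledge boosts
strengths by s′ = 1 − (1 − s)(1 − wκ), κ the knowledge-graph indicator
and w = 0.3: this maps [0,1] to [0,1], is monotone in both arguments,
never penalizes unlisted edges, and fixes s = 1; a convex-mixture mode
(1 − w)s + wκ is selectable, in which knowledge also *shrinks* edges it
does not list. Supplying no knowledge graph leaves strengths unmodified
in either mode. The published description of the knowledge-modification
step defers to its software reference, so this boost form is a declared
substitute, not a reconstruction. The two modes matter in different
regimes: when the data alone already recover every true interaction
(large n, strong correlations), a boost-only prior can only add edges
and therefore cannot improve F1 — the mixture mode is then the one that
helps, by pruning data-driven false positives lacking knowledge
support; when data are weak, the boost rescues true edges the
bootstrap undersupports. The
significance threshold matches the empirical strength CDF to the
L1-closest ideal two-point CDF — the optimal q is the length-weighted
median of the CDF's step values, and the threshold is the interpolating
(type-7) quantile at q; the interpolating quantile is forced by the
bimodal case, where the threshold must fall strictly between the two
modes. The threshold is estimated on the *raw* (data-driven) strengths
of **all** feature pairs — pairs no bootstrap network ever produced
enter at strength 0, which is what lets the estimator return "nothing
significant" on structureless data — and is then applied to the
modified strengths: estimating it on the modified values would let the
knowledge prior raise the very bar its edges must clear, making
knowledge integration non-monotone and, in simulation, erasing its
recovery benefit. Edges strictly above the
threshold form the consensus network,
reported as connected components of ≥ 2 molecules, heterogeneous when
they span layers. When every strength is equal the threshold is
degenerate and nothing is significant.

# The simulator: what it emulates, and what it does not

`generate_study()` draws, per layer, log2 intensities

baseline_f + pair_{f,j} + tech_s + Δ_f·m_j·[DEL ∧ f planted] + Σ_e g_{e,s} + ε_{f,s}

exponentiated, multiplied by the drift curve
1 + a·(o/o_max) + 0.3a·sin(2π o/o_max) on the LC-MS layers, then masked
missing-not-at-random with probability
missing_rate · logistic(−strength · z(log2 intensity)).

Defaults and why:

* **15 pairs; 219/161/1305 features; 8 QC injections** — the scale of a
  single-site matched CSF study on targeted metabolomics, untargeted
  lipidomics and a 1.3k affinity panel.
* **Planted |log2 FC| ~ N(0.8, 0.3)** — makes robust fold-change
  magnitudes of 1.1–2.5 typical, the range such studies report; no
  published effect-size distribution exists to copy.
* **pair sd 0.4 per feature** — subject-level biology shared within a
  pair; this is precisely what makes paired tests more powerful here.
  It is per-feature: a global per-sample shift would correlate all
  features and misrepresent matched biology.
* **technical factor sd 0.2 per sample (and per QC injection)** — the
  component NOMIS removes. 20% multiplicative technical variation is
  realistic for un-normalized LC-MS, and it is the scale at which the
  QC-CV trajectory across preprocessing steps is monotone decreasing
  and ends below 10%, as QC-monitored studies report. QC injections
  carry their own factor plus log2-sd-0.02 replicate noise, both
  suppressed in the exact drift-free/missingness-free limit so that the
  zero-CV limiting case is exact.
* **residual noise sd 0.25; baselines N(20, 2)** — intensities spanning
  orders of magnitude with within-feature biological scatter.
* **planted network: 40 edges as a random disjoint matching, per-edge
  latent factor sd 0.55** — disjoint pairs keep the per-edge
  correlation interpretable; 0.55 makes it ≈ 0.61 at defaults. Real
  interactomes have hubs and longer paths; recovering those is *not*
  established by a green test here.
* **internal standards** — spiked constants carrying only the technical
  factor and small noise; never differential, never masked (spiked
  concentrations sit far above detection limits).

Limitations worth naming: pooled-QC samples are exact averages of the
study samples' pre-drift signals; drift is smooth and shared by all
features of a layer (no retention-time-specific drift); missingness
depends only on intensity; proteins are complete and drift-free. A
green test establishes parameter recovery under this stated world, not
under every real acquisition pathology.

# Numerical choices and degenerate inputs

Zero-variance paired differences give p = 1 with a degeneracy flag;
fewer than 3 usable pairs give an undefined marker that BH passes
through unchanged. Constant features are dropped (with a warning)
before correlation clustering. `n_components` is clamped to the data
rank. Equal-strength vectors make the network threshold degenerate. All
randomness flows through explicit seeds (forest bootstraps, CV folds,
SVM-free deterministic SMO, bootstrap resampling, candidate-order
shuffling keyed by feature *names* so column order never matters), and
the caller's RNG state is always restored.

# Known open points

The composition of the refined stability signature reported by the
study this design emulates is internally inconsistent between its text
(4 lipids, 11 metabolites, 1 protein = 16) and a figure caption
(5 lipids, 11 metabolites, 1 protein = 17); nothing in this package
depends on the resolution, and the refined set size on the published
per-sample data can only be checked when that non-deposited table is
supplied (see the acceptance suite). The per-sample headline metrics
additionally depend on the kernel and PCA scope, which upstream
descriptions leave open; we evaluate all kernels and report the best
under the `global` scope when reproducing them.
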