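test_that("paired t matches the closed form and its degenerate rules", {
  # log2 differences (1, 2, 3): t = 2 / (1/sqrt(3)), df = 2
  p <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(as.numeric(p), 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(as.numeric(p), 4), 0.0742)
  expect_equal(paired_t(c(0, 0, 0), c(1, 2, 3)), p)    # symmetry
  z <- paired_t(c(5, 6, 7), c(4, 5, 6))                # constant differences
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))
  expect_true(is.na(paired_t(c(1, 2), c(0, 0))))
  # missing pairs are dropped
  expect_equal(paired_t(c(1, 2, 3, NA), c(0, 0, 0, 5)), p)
})

test_that("signed-rank test: exact small-sample values and enumeration oracle", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5)), 2 / 32)
  d <- c(3, -1, 4, 1, -5, 9, 2, 6)
  expect_equal(wilcoxon_signed_rank(d, rep(0, 8)),
               wilcoxon_signed_rank(-d, rep(0, 8)))   # sign symmetry
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:11, 1)
    d <- round(rnorm(n, 0.3), if (rep %% 2) 3 else 0)  # even reps force ties
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(wilcoxon_signed_rank(d, rep(0, length(d))),
                 wilcoxon_enum_oracle(d), tolerance = 1e-12)
  }
  expect_true(is.na(wilcoxon_signed_rank(c(1, 1), c(1, 1))))
})

test_that("signed-rank normal approximation agrees with exact at the n=26 boundary", {
  set.seed(7)
  d <- rnorm(26, 0.2)
  approx_p <- wilcoxon_signed_rank(d, rep(0, 26))
  # exact null via generating-polynomial convolution (independent coding)
  r <- 2 * rank(abs(d))
  poly <- 1
  for (w in r) {
    nxt <- numeric(length(poly) + w)
    nxt[seq_along(poly)] <- poly
    nxt[seq_along(poly) + w] <- nxt[seq_along(poly) + w] + poly
    poly <- nxt
  }
  poly <- poly / 2^26
  tt <- seq_along(poly) - 1
  mu2 <- sum(r) / 2
  w_obs2 <- 2 * sum(rank(abs(d))[d > 0])
  exact_p <- sum(poly[abs(tt - mu2) >= abs(w_obs2 - mu2) - 1e-9])
  expect_lt(abs(approx_p - exact_p), 0.005)
})

test_that("sign test reproduces the exact binomial tail arithmetic", {
  # n = 15, k = 13 positive: p = 2 (105 + 15 + 1) / 2^15
  d <- c(rep(1, 13), rep(-1, 2))
  expect_equal(sign_test(d, rep(0, 15)), 242 / 32768)
  expect_equal(sign_test(c(rep(1, 8), rep(-1, 8)), rep(0, 16)), 1)
  d2 <- c(rep(1, 2), rep(-1, 13))                     # k and n-k symmetric
  expect_equal(sign_test(d2, rep(0, 15)), 242 / 32768)
  expect_true(is.na(sign_test(c(1, 2), c(1, 2))))
})

test_that("BH step-up matches hand values and the rejection-set oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_equal(bh_adjust(c(0.5, NA, 0.1)), c(0.5, NA, 0.2))
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 1)
  set.seed(1)
  for (k in 1:6) {
    combos <- matrix(utils::combn(length(grid) + k - 1, k,
                                  function(ix) grid[ix - seq_len(k) + 1]),
                     nrow = k)
    for (j in seq_len(ncol(combos))) {
      p <- sample(combos[, j])        # scramble order too
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("Tukey biweight fold change is robust and signed as specified", {
  expect_equal(tukey_biweight_fc(c(2, 4, 8), c(1, 2, 4)), 2)
  # one wild pair: outlier annihilated, estimate stays at 2
  out <- tukey_biweight_fc(c(2, 2, 2, 2, 20), c(1, 1, 1, 1, 1))
  expect_equal(out, 2)
  expect_lt(out, mean(c(2, 2, 2, 2, 20)))
  # mixed directions: result bounded by the data range, |tFC| < 1 reachable
  mixed <- tukey_biweight_fc(c(1.2, 1, 1.3), c(1, 1.1, 1))
  expect_gt(mixed, -1.1); expect_lt(mixed, 1.3)
  small <- tukey_biweight_fc(c(1.05, 1, 1, 1.08), c(1, 1.1, 1.12, 1))
  expect_lt(abs(small), 1)
  expect_error(tukey_biweight_fc(c(1, -1, 2), c(1, 1, 1)), "positive")
  expect_error(tukey_biweight_fc(c(1, 2), c(1, 1)), "3 usable")
})

test_that("null features have near-unit signed folds across seeds", {
  meds <- vapply(1:20, function(s) {
    set.seed(100 + s)
    ctrl <- rlnorm(15, 6, 0.4)
    case <- ctrl * rlnorm(15, 0, 0.3)
    tukey_biweight_fc(case, ctrl)
  }, numeric(1))
  expect_lte(abs(median(meds)), 1.1)
  expect_true(all(abs(meds) < 2))
})

test_that("raising DEL intensities drives tFC monotonically upward", {
  set.seed(3)
  ctrl <- rlnorm(12, 5, 0.4)
  case <- ctrl * rlnorm(12, 0, 0.1)
  fcs <- vapply(c(1, 1.3, 1.8, 2.5, 4), function(g)
    tukey_biweight_fc(case * g, ctrl), numeric(1))
  expect_true(all(diff(fcs) > 0))
})

test_that("differential_table rolls the three tests up as specified", {
  st <- generate_study(simulation_config(
    n_pairs = 15, n_features = c(50, 0, 0), n_differential = c(8, 0, 0),
    n_internal_standards = c(0, 0, 0), network_edges = 0,
    drift_amplitude = 0, missing_rate = 0.03, seed = 17))
  rec <- differential_table(st$datasets$metabolite, st$design)
  pm <- as.matrix(rec[, c("p_paired_t", "p_wilcoxon", "p_sign")])
  expect_equal(rec$min_p, unname(apply(pm, 1, min, na.rm = TRUE)),
               tolerance = 1e-12)
  expect_equal(rec$significant, rec$min_p < 0.05)
  expect_true(all(rec$bh_paired_t >= rec$p_paired_t - 1e-12, na.rm = TRUE))
  expect_true(all(diff(rec$tfc[!is.na(rec$tfc)]) <= 1e-12)) # sorted desc
  expect_equal(rec$bh_paired_t[!is.na(rec$p_paired_t)],
               unname(bh_oracle(rec$p_paired_t[!is.na(rec$p_paired_t)])),
               tolerance = 1e-9)
  # planted features dominate the top of the min_p ranking
  planted <- st$truth$differential$feature_id
  rk <- rank(rec$min_p)[rec$feature_id %in% planted]
  expect_lt(median(rk), 10)
  expect_error(differential_table(st$datasets$metabolite,
                                  matched_design("nope", "ctrl_01")),
               "absent|DEL")
})
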