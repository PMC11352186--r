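test_that("lipid line consolidation sums split lines and handles missing", {
  x <- matrix(c(100, 50, 7,
                NA,  50, 7,
                NA,  NA, 7,
                1,    2, 7,
                3,    4, 7,
                5,    6, 7,
                8,    9, 7,
                10,  11, 7,
                12,  13, 7), nrow = 3, ncol = 9)
  ds <- toy_dataset(nf = 3, np = 3, n_qc = 3, intensities = x,
                    layer = "lipid",
                    consolidation_key = c("L", "L", "single"))
  out <- consolidate_lipid_lines(ds)
  expect_equal(nrow(out$intensities), 2L)
  expect_equal(out$feature_meta$feature_id[1], "L")
  expect_equal(unname(out$intensities[1, 1:3]), c(150, 50, NA_real_))
  # single-line keys and other rows pass through unchanged
  expect_equal(unname(out$intensities[2, ]), unname(ds$intensities[3, ]))

  ds2 <- toy_dataset(nf = 2, np = 3, n_qc = 1, layer = "lipid",
                     intensities = matrix(1, 2, 7),
                     is_std = c(TRUE, FALSE),
                     consolidation_key = c("K", "K"))
  expect_error(consolidate_lipid_lines(ds2), "conflicting")
})

test_that("presence filter applies the either-group 50% rule", {
  np <- 18
  x <- matrix(1, 3, 2 * np + 3)
  ds <- toy_dataset(nf = 3, np = np, n_qc = 3, intensities = x)
  # feature 2: 9/18 DEL, 4/18 CNT -> kept via DEL; feature 3: all missing
  ds$intensities[2, 10:18] <- NA       # DEL cols are 1..18
  ds$intensities[2, 18 + 5:18] <- NA   # CNT cols are 19..36
  ds$intensities[3, ] <- NA
  res <- presence_filter(ds, toy_design(np))
  expect_setequal(res$dataset$feature_meta$feature_id, c("f01", "f02"))
  expect_equal(res$report$dropped$feature_id, "f03")
  # with rule = "both" the 9/18-vs-4/18 feature is dropped
  res2 <- presence_filter(ds, toy_design(np), rule = "both")
  expect_setequal(res2$dataset$feature_meta$feature_id, "f01")
})

test_that("QC-RFSC is identity on constant QC and flags sparse features", {
  set.seed(2)
  np <- 5; n_qc <- 4
  x <- matrix(rlnorm(6 * 14, 5, 0.3), 6, 14)
  x[, 11:14] <- 200                       # constant QC signal
  x[6, 11:13] <- NA                       # only 1 QC value left
  ds <- toy_dataset(nf = 6, np = np, n_qc = n_qc, intensities = x)
  out <- qc_rfsc_correct(ds, n_trees = 100, seed = 1)
  expect_equal(out$intensities[1:5, ], ds$intensities[1:5, ],
               tolerance = 1e-9)
  expect_equal(attr(out, "qc_rfsc_skipped"), "f06")
  expect_equal(out$intensities[6, ], ds$intensities[6, ])

  allna <- ds
  allna$intensities[, 11:14] <- NA
  expect_error(qc_rfsc_correct(allna, seed = 1), "mis-specified")
})

test_that("QC-RFSC removes planted multiplicative drift", {
  np <- 15; n_qc <- 8; ns <- 2 * np + n_qc
  set.seed(4)
  x <- matrix(rep(1000, 5 * ns), 5, ns)
  ds <- toy_dataset(nf = 5, np = np, n_qc = n_qc, intensities = x)
  ord <- ds$sample_meta$injection_order
  drift <- 1 + 0.3 * (ord / max(ord))
  ds$intensities <- sweep(ds$intensities, 2, drift, `*`) *
    matrix(rlnorm(5 * ns, 0, 0.01), 5, ns)
  pre <- qc_cv(ds)
  post <- qc_cv(qc_rfsc_correct(ds, seed = 9))
  expect_true(all(post < pre))
})

test_that("knn imputation matches hand-derived neighbour averages", {
  # k = 1: neighbour identical except at the missing sample
  x <- matrix(c(2, 4, 8, 16, 32, 64,
                2, 4, 8, 16, 32, 64), nrow = 2, byrow = TRUE)
  x <- rbind(x, matrix(1000, 2, 6))
  x[1, 5] <- NA
  ds <- toy_dataset(nf = 4, np = 3, n_qc = 0, intensities = x)
  out <- knn_impute(ds, k = 1)$dataset
  expect_equal(out$intensities[1, 5], 32)
  expect_equal(out$intensities[-1, ], ds$intensities[-1, ]) # observed untouched

  # k = 2 equidistant neighbours: log-scale midpoint of 10 and 20
  y <- rbind(a = c(15, 15, 15, 15, 15, NA),
             b = c(15 + 3, 15 - 3, 15, 15, 15, 10),
             c = c(15 - 3, 15 + 3, 15, 15, 15, 20))
  ds2 <- toy_dataset(nf = 3, np = 3, n_qc = 0, intensities = 2^y)
  out2 <- knn_impute(ds2, k = 2)$dataset
  expect_equal(log2(out2$intensities[1, 6]), 15)

  # no missing values: identity; all-missing features are dropped
  ds3 <- toy_dataset(intensities = matrix(rlnorm(4 * 9, 4), 4, 9))
  expect_equal(knn_impute(ds3)$dataset, ds3)
  ds4 <- ds3
  ds4$intensities[2, ] <- NA
  res <- knn_impute(ds4)
  expect_equal(res$report$dropped$feature_id, "f02")
  expect_equal(nrow(res$dataset$intensities), 3L)
  expect_error(knn_impute(ds3, k = 0), "k must be")
})

test_that("NOMIS algebra: constants pass through, IS copies are flattened", {
  set.seed(11)
  ns <- 9
  is_log <- matrix(rnorm(3 * ns, 6, 1), 3, ns)   # three distinct standards
  # constant standards: centering annihilates them -> identity
  ds_const <- toy_dataset(nf = 5, np = 3, n_qc = 3,
                          intensities = rbind(matrix(64, 3, ns),
                                              2^matrix(rnorm(2 * ns, 8), 2, ns)),
                          is_std = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- suppressWarnings(nomis_normalize(ds_const))
  expect_equal(out$intensities, ds_const$intensities[4:5, ], tolerance = 1e-9)

  # feature = IS1 + constant on log scale -> variance annihilated
  feat <- rbind(is_log[1, ] + 3, rnorm(ns, 10, 1))
  ds <- toy_dataset(nf = 5, np = 3, n_qc = 3,
                    intensities = 2^rbind(is_log, feat),
                    is_std = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- nomis_normalize(ds)
  expect_lte(var(log2(out$intensities[1, ])), 1e-18)

  # feature orthogonal to the centered standards -> unchanged
  S <- scale(t(is_log), center = TRUE, scale = FALSE)
  ortho <- qr.resid(qr(S), rnorm(ns))
  ds_o <- toy_dataset(nf = 4, np = 3, n_qc = 3,
                      intensities = 2^rbind(is_log, 10 + ortho),
                      is_std = c(TRUE, TRUE, TRUE, FALSE))
  out_o <- nomis_normalize(ds_o)
  expect_equal(log2(out_o$intensities[1, ]), 10 + ortho,
               ignore_attr = TRUE, tolerance = 1e-9)

  # duplicated standards trigger the ridge fallback warning
  ds_dup <- toy_dataset(nf = 4, np = 3, n_qc = 3,
                        intensities = 2^rbind(is_log[c(1, 1), ], is_log[2, ],
                                              matrix(rnorm(ns, 9), 1)),
                        is_std = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(nomis_normalize(ds_dup), "rank-deficient")
})

test_that("qc_cv matches hand arithmetic and flags undefined features", {
  x <- matrix(1, 3, 9)
  x[1, 7:9] <- c(100, 100, 100)
  x[2, 7:9] <- c(90, 100, 110)
  x[3, 7:9] <- c(50, NA, NA)
  ds <- toy_dataset(nf = 3, np = 3, n_qc = 3, intensities = x)
  cv <- qc_cv(ds)
  expect_equal(unname(cv), c(0, 10, NA))
})

test_that("full chain is the identity on clean data (minus standards)", {
  set.seed(6)
  ns <- 2 * 10 + 4
  x <- 2^rbind(matrix(5, 2, ns),                      # constant standards
               matrix(rnorm(6 * ns, 8, 1), 6, ns))
  x[, ns - 3:0] <- rowMeans(x)                        # drift-free QC replicates
  ds <- toy_dataset(nf = 8, np = 10, n_qc = 4, intensities = x,
                    is_std = c(TRUE, TRUE, rep(FALSE, 6)))
  res <- suppressWarnings(preprocess(ds, toy_design(10), seed = 1))
  expect_equal(res$dataset$feature_meta$feature_id, sprintf("f%02d", 3:8))
  expect_equal(res$dataset$intensities, ds$intensities[3:8, ],
               tolerance = 1e-6)
})

test_that("median QC CV is monotone over correction, imputation, normalization", {
  # Asserted on the across-seed median trajectory (seeds 31-35, fixed
  # before inspection and kept even though the in-sample random-forest
  # drift fit makes the normalization step non-monotone for a minority
  # of single seeds — analysis in the methods vignette). The 0.1-point
  # slack covers the bounded error of imputing a few MNAR QC cells.
  traj <- vapply(31:35, function(s) {
    st <- generate_study(simulation_config(
      n_pairs = 15, n_features = c(60, 0, 0), n_differential = c(5, 0, 0),
      n_internal_standards = c(4, 0, 0), network_edges = 0, seed = s))
    res <- preprocess(st$datasets$metabolite, st$design, seed = 2)
    vapply(res$report$qc_cv, median, na.rm = TRUE,
           numeric(1))[c("input", "drift", "knn_impute", "normalize")]
  }, numeric(4))
  med <- apply(traj, 1, median)
  expect_true(all(diff(med) <= 0.1))
  expect_lt(med["normalize"], 10)   # ends under the 10% quality bar
})
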