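test_that("AUC follows the Mann-Whitney concordance count", {
  expect_equal(compute_auc(c(0.9, 0.3), c(0.5, 0.1)), 0.75)
  expect_equal(compute_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(compute_auc(rep(1, 5), rep(1, 7)), 0.5)
  expect_error(compute_auc(numeric(), 1), "empty")

  for (seed in 1:10) {
    withr::with_seed(seed, {
      pos <- sample(seq(0, 1, by = 0.1), 8, replace = TRUE)
      neg <- sample(seq(0, 1, by = 0.1), 15, replace = TRUE)
    })
    expect_equal(compute_auc(pos, neg), auc_oracle(pos, neg))
  }
})

test_that("AUC matches an independent ROC implementation", {
  withr::with_seed(17, {
    pos <- rnorm(40, 1)
    neg <- rnorm(120)
  })
  ref <- suppressMessages(pROC::auc(
    c(rep(1, 40), rep(0, 120)), c(pos, neg), direction = "<"
  ))
  expect_equal(compute_auc(pos, neg), as.numeric(ref), tolerance = 1e-12)
})

test_that("AUPR is step-wise average precision", {
  # ranking +,-,+,- : AP = 1*(1/2) + (2/3)*(1/2) = 5/6
  expect_equal(compute_aupr(c(4, 2), c(3, 1)), 5 / 6, tolerance = 1e-12)
  expect_equal(compute_aupr(c(4, 3), c(2, 1)), 1)
  # both positives ranked last among 4: (1/3 + 2/4)/2 = 5/12
  expect_equal(compute_aupr(c(1, 0.5), c(3, 2)), 5 / 12, tolerance = 1e-12)
})

test_that("a random-scoring predictor sits at chance level", {
  withr::with_seed(2024, {
    pos <- runif(1000)
    neg <- runif(20000)
  })
  auc <- compute_auc(pos, neg)
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("global LOOCV masks each positive once and restores the data", {
  ds <- simulate_mda_dataset(p = 8, q = 6, seed = 13)
  Y_before <- ds$assoc$Y + 0L
  ks <- build_kernels(ds)
  cv <- run_global_loocv(ds, fusion = fusion_config(neighbors = 4),
                         kernels = ks, recompute = "hamming")
  expect_equal(nrow(cv$ranks), sum(Y_before))  # one fold per positive
  expect_identical(ds$assoc$Y, Y_before)       # input untouched
  expect_true(all(cv$ranks$auc >= 0 & cv$ranks$auc <= 1))
  expect_equal(cv$pooled_auc, mean(cv$ranks$auc))
})

test_that("global LOOCV recovers planted associations well above chance", {
  ds <- simulate_mda_dataset(p = 20, q = 14, seed = 7)
  ks <- build_kernels(ds)
  cv <- run_global_loocv(ds, fusion = fusion_config(neighbors = 8),
                         kernels = ks, recompute = "hamming")
  expect_gt(cv$pooled_auc, 0.75)
})

test_that("local LOOCV evaluates exactly the eligible diseases", {
  Y <- matrix(0L, 6, 4)
  Y[1:3, 1] <- 1L          # disease 1: 3 positives
  Y[, 2] <- 1L             # disease 2: all positive -> skipped
  Y[4, 3] <- 1L            # disease 3: 1 positive
  # disease 4: no positives -> excluded
  ds <- simulate_mda_dataset(p = 6, q = 4, seed = 9)
  ds$assoc <- assoc_from_matrix(Y, ds$assoc$mirna_ids, ds$assoc$disease_ids)
  ks <- build_kernels(ds)
  expect_warning(
    cv <- run_local_loocv(ds, fusion = fusion_config(neighbors = 3),
                          kernels = ks),
    "every miRNA"
  )
  expect_equal(nrow(cv$per_unit), 2L)  # diseases 1 and 3 only
  expect_equal(cv$pooled_auc, mean(cv$per_unit$auc))
})

test_that("local LOOCV scores a noiseless planted disease perfectly", {
  # one disease whose block contains all of its positives, no noise
  ds <- simulate_mda_dataset(p = 12, q = 8, n_blocks = 2, d_in = 1,
                             d_out = 0, mut_rate = 0, seed = 3)
  ks <- build_kernels(ds)
  # noiseless blocks make the fused kernel rank-deficient; the documented
  # ridge-jitter path fires and is expected
  cv <- suppressWarnings(
    run_local_loocv(ds, fusion = fusion_config(neighbors = 6),
                    laprls = laprls_config(2^-1), kernels = ks)
  )
  expect_equal(max(cv$per_unit$auc), 1)
  expect_gt(cv$pooled_auc, 0.95)
})

test_that("k-fold folds partition the positives and the run is seeded", {
  ds <- simulate_mda_dataset(p = 12, q = 8, seed = 4)
  ks <- build_kernels(ds)
  cfg <- fusion_config(neighbors = 5)
  cv1 <- run_kfold_cv(ds, folds = 4, seed = 11, fusion = cfg, kernels = ks)
  cv2 <- run_kfold_cv(ds, folds = 4, seed = 11, fusion = cfg, kernels = ks)
  cv3 <- run_kfold_cv(ds, folds = 4, seed = 12, fusion = cfg, kernels = ks)
  expect_identical(cv1$ranks, cv2$ranks)
  expect_equal(cv1$pooled_auc, cv2$pooled_auc)
  fold_map <- function(cv) {
    r <- dplyr::arrange(cv$ranks, .data$mirna, .data$disease)
    r$fold
  }
  expect_false(identical(fold_map(cv1), fold_map(cv3)))
  # disjoint folds covering every positive exactly once
  key <- paste(cv1$ranks$mirna, cv1$ranks$disease)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(length(key), sum(ds$assoc$Y))
  expect_equal(sort(unique(cv1$ranks$fold)), 1:4)
})

test_that("masked positives leave no trace in the rebuilt kernels", {
  # sentinel leak test: adding a pair and then masking it must reproduce
  # the kernels built without the pair, bit for bit
  ds <- simulate_mda_dataset(p = 10, q = 7, seed = 6)
  Y0 <- ds$assoc$Y
  stopifnot(Y0[2, 3] == 0L)
  Y1 <- Y0
  Y1[2, 3] <- 1L
  with_sentinel <- ds
  with_sentinel$assoc <- assoc_from_matrix(Y1, ds$assoc$mirna_ids,
                                           ds$assoc$disease_ids)
  ks_clean <- build_kernels(ds)
  ks_sent <- build_kernels(with_sentinel)
  masked <- mdaskf:::mask_assoc(with_sentinel$assoc, cbind(2L, 3L))
  ks_masked <- rebuild_y_kernels(ks_sent, masked)
  expect_identical(ks_masked$mirna$hamming$K, ks_clean$mirna$hamming$K)
  expect_identical(ks_masked$disease$hamming$K, ks_clean$disease$hamming$K)
  expect_identical(ks_masked$mirna$misim$K, ks_clean$mirna$misim$K)
  # without recomputation the sentinel does leak (sanity of the test)
  expect_false(identical(ks_sent$mirna$hamming$K, ks_clean$mirna$hamming$K))
})

test_that("top candidates rank unknown pairs only, ties by identifier", {
  scores <- matrix(c(0.9, 0.7, 0.4), 3, 1,
                   dimnames = list(c("m1", "m2", "m3"), "d1"))
  Y <- matrix(c(1L, 0L, 0L), 3, 1)
  a <- assoc_from_matrix(Y, c("m1", "m2", "m3"), "d1")
  got <- expect_warning(top_candidates(scores, "d1", n = 2, assoc = a),
                        NA)
  expect_equal(got$mirna, c("m2", "m3"))
  expect_equal(got$rank, 1:2)
  expect_null(dim(got$score))  # plain numeric column, not a matrix slice
  expect_equal(got$score, c(0.7, 0.4))
  # n = 1 returns the argmax unknown pair
  expect_equal(top_candidates(scores, "d1", n = 1, assoc = a)$mirna, "m2")
  # all pairs known: empty with a warning
  a_all <- assoc_from_matrix(matrix(1L, 3, 1), c("m1", "m2", "m3"), "d1")
  expect_warning(empty <- top_candidates(scores, "d1", assoc = a_all),
                 "already associated")
  expect_equal(nrow(empty), 0L)
  # truncation warning when fewer unknowns than requested
  expect_warning(top_candidates(scores, "d1", n = 50, assoc = a), "only 2")
  # exact ties ranked by identifier
  s2 <- matrix(c(0.5, 0.5, 0.5), 3, 1,
               dimnames = list(c("mC", "mA", "mB"), "d1"))
  a2 <- assoc_from_matrix(matrix(0L, 3, 1), c("mC", "mA", "mB"), "d1")
  expect_equal(top_candidates(s2, "d1", n = 3, assoc = a2)$mirna,
               c("mA", "mB", "mC"))
})

test_that("cv tidiers expose per-unit and pooled views", {
  ds <- simulate_mda_dataset(p = 10, q = 7, seed = 8)
  ks <- build_kernels(ds)
  cv <- run_kfold_cv(ds, folds = 3, seed = 2,
                     fusion = fusion_config(neighbors = 5), kernels = ks)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- glance(cv)
  expect_equal(gl$scheme, "kfold")
  expect_equal(gl$pooled_auc, cv$pooled_auc)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
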