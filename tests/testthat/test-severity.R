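test_that("CGI-S binarization follows the printed rule", {
  expect_equal(as.character(binarize_cgis(4)), "low")
  expect_equal(as.character(binarize_cgis(5)), "high")
  expect_equal(as.character(binarize_cgis(1)), "low")
  expect_equal(as.character(binarize_cgis(7)), "high")
  expect_error(binarize_cgis(0), "1..7")
  expect_error(binarize_cgis(8), "1..7")
})

test_that("the 15 family combinations are enumerated in order", {
  combos <- enumerate_combinations()
  expect_length(combos, 15)
  expect_equal(combos[[13]], c("HRV", "MSTE", "MSNR"))
  for (fam in c("HRV", "ACT", "MSTE", "MSNR")) {
    expect_equal(sum(vapply(combos, function(cb) fam %in% cb, TRUE)), 8)
  }
})

test_that("pooled AUC equals brute-force pair counting", {
  lab <- factor(c("high", "high", "low", "low"), levels = c("low", "high"))
  expect_equal(pooled_auc(c(0.9, 0.8, 0.1, 0.7), lab), 1.0)
  expect_equal(pooled_auc(c(0.9, 0.8, 0.1, 0.7), lab),
               brute_auc(c(0.9, 0.8, 0.1, 0.7), lab))

  # perfectly ordered and all-tied cases
  expect_equal(pooled_auc(c(1, 0.9, 0.2, 0.1), lab), 1)
  expect_equal(pooled_auc(rep(0.5, 4), lab), 0.5)
  expect_error(pooled_auc(c(0.5, 0.6), factor(c("low", "low"))), "classes")

  # random instances with ties
  for (s in 1:50) {
    set.seed(s)
    n <- sample(6:30, 1)
    l <- factor(sample(c("low", "high"), n, replace = TRUE),
                levels = c("low", "high"))
    if (length(unique(l)) < 2) next
    p <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(pooled_auc(p, l), brute_auc(p, l), tolerance = 1e-12)
  }

  # invariance under strictly monotone probability transforms
  set.seed(4)
  p <- runif(20)
  l <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  expect_equal(pooled_auc(plogis(5 * p - 2), l), pooled_auc(p, l))
})

test_that("LOOCV produces reps x patients models and pooled medians", {
  tab <- random_feature_table(20, n_feat = 8, seed = 2, effect = 3)
  r <- suppressWarnings(loocv_experiment(tab, n_reps = 5, base_seed = 1))
  expect_equal(r$n_models, 100)
  expect_length(r$pooled_probs, 20)
  expect_true(all(r$pooled_probs >= 0 & r$pooled_probs <= 1))
  expect_gte(r$pooled_auc, 0.8)
  expect_error(loocv_experiment(tab, "XYZ"), "families|XYZ")
})

test_that("the held-out patient's rows never influence its own fold", {
  tab <- random_feature_table(8, n_feat = 6, seed = 3, effect = 1)
  r1 <- suppressWarnings(loocv_experiment(tab, n_reps = 1, base_seed = 9))
  # corrupt P01's feature rows; its fold model must be unchanged
  tab2 <- tab
  tab2$X[tab$patient_id == "P01", ] <- 1e6
  r2 <- suppressWarnings(loocv_experiment(tab2, n_reps = 1, base_seed = 9))
  m1 <- r1$models[[which(vapply(r1$models, function(m) m$patient, "") == "P01")]]
  m2 <- r2$models[[which(vapply(r2$models, function(m) m$patient, "") == "P01")]]
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$coef, m2$coef)
})

test_that("feature popularity lies on the model-count grid", {
  tab <- random_feature_table(10, n_feat = 6, seed = 5, effect = 3)
  r <- suppressWarnings(loocv_experiment(tab, n_reps = 5, base_seed = 2))
  pop <- feature_popularity(r)
  expect_equal(nrow(pop), 6)
  expect_true(all(pop$rho >= 0 & pop$rho <= 1))
  expect_true(all(abs(pop$rho * r$n_models -
                        round(pop$rho * r$n_models)) < 1e-9))
  # sum of selection counts equals sum of per-model support sizes
  total_sel <- sum(pop$rho) * r$n_models
  support <- sum(vapply(r$models, function(m) sum(abs(m$coef) > 1e-10), 0))
  expect_equal(total_sel, support, tolerance = 1e-6)
  # the informative feature dominates
  expect_equal(pop$feature[1], "f1")
  # competition ranking: ties share a rank
  expect_equal(pop$rank[1], 1)
  expect_true(all(diff(pop$rank) >= 0))
})

test_that("permuted labels give chance-level pooled AUC", {
  tab <- random_feature_table(10, n_feat = 6, seed = 6, effect = 3,
                              visits = 2)
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    perm <- tab
    # permute patient-level labels, keeping visits of a patient together
    pats <- unique(tab$patient_id)
    newlab <- setNames(sample(
      vapply(pats, function(p) as.character(tab$label[tab$patient_id == p][1]),
             "")), pats)
    perm$label <- factor(newlab[tab$patient_id], levels = c("low", "high"))
    suppressWarnings(
      loocv_experiment(perm, n_reps = 3, base_seed = s)$pooled_auc)
  })
  # chance level on the whole: the centre of the permutation distribution
  # sits at 0.5 (individual permutations disperse widely at n = 10
  # patients because residual label-feature overlap survives permutation)
  expect_gte(median(aucs), 0.3)
  expect_lte(median(aucs), 0.7)
  expect_gte(mean(aucs), 0.25)
  expect_lte(mean(aucs), 0.75)
})

test_that("ROC coordinates integrate back to the pooled AUC", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:30, 1)
    l <- factor(sample(c("low", "high"), n, replace = TRUE),
                levels = c("low", "high"))
    if (length(unique(l)) < 2) next
    p <- round(runif(n), 1)
    rc <- roc_points(p, l)
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    # trapezoidal area under the ROC equals the rank-based AUC
    area <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(area, pooled_auc(p, l), tolerance = 1e-12)
  }
})

test_that("the full experiment runs all 15 combinations", {
  tab <- random_feature_table(8, n_feat = 8, seed = 7, effect = 2)
  res <- suppressWarnings(run_full_experiment(tab, n_reps = 2,
                                              base_seed = 3))
  expect_length(res$results, 15)
  expect_equal(nrow(res$summary), 15)
  expect_equal(res$summary$combination[13], "HRV+MSTE+MSNR")
  expect_true(all(res$summary$n_models == 2 * 8, na.rm = TRUE))
  # identical seed: identical report
  res2 <- suppressWarnings(run_full_experiment(tab, n_reps = 2,
                                               base_seed = 3))
  expect_identical(res$summary, res2$summary)
})
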