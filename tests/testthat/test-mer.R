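# MER stacked classifier: metrics, out-of-fold discipline, determinism.

test_that("confusion-derived metrics match the defining ratios", {
  truth <- c(rep("apnea", 100), rep("normal", 100))
  pred <- c(rep("apnea", 97), rep("normal", 3),
            rep("apnea", 34), rep("normal", 66))
  cm <- confusion(truth, pred)
  expect_equal(cm$TP, 97); expect_equal(cm$FN, 3)
  expect_equal(cm$TN, 66); expect_equal(cm$FP, 34)
  expect_equal(sensitivity(cm), 0.97)
  expect_equal(specificity(cm), 0.66)
  expect_equal(accuracy(cm), 0.815)
  # zero-denominator guard
  cm0 <- confusion(rep("normal", 5), rep("normal", 5))
  expect_warning(s <- sensitivity(cm0), "zero denominator")
  expect_equal(s, 0)
})

test_that("AUC equals the Mann-Whitney pairwise oracle and is monotone
           invariant", {
  set.seed(61)
  for (i in 1:10) {
    truth <- sample(c("apnea", "normal"), 40, replace = TRUE,
                    prob = c(0.5, 0.5))
    if (length(unique(truth)) < 2) next
    sc <- round(rnorm(40), 1)  # ties included
    expect_equal(auc_score(truth, sc), oracle_auc(truth, sc),
                 tolerance = 1e-12)
    expect_equal(auc_score(truth, exp(sc)), auc_score(truth, sc),
                 tolerance = 1e-12)
  }
  # perfectly separated scores
  truth <- c(rep("apnea", 5), rep("normal", 5))
  expect_equal(auc_score(truth, c(6:10, 1:5)), 1)
})

test_that("accuracy lies between sens and spec on balanced test sets", {
  set.seed(67)
  truth <- rep(c("apnea", "normal"), each = 50)
  pred <- sample(c("apnea", "normal"), 100, replace = TRUE)
  cm <- confusion(truth, pred)
  a <- accuracy(cm)
  expect_gte(a, min(sensitivity(cm), specificity(cm)) - 1e-12)
  expect_lte(a, max(sensitivity(cm), specificity(cm)) + 1e-12)
})

test_that("meta features are out-of-fold and the meta table has the
           declared shape", {
  tab <- simulate_feature_cohort(n_patients = 10, segments_per_class = 10,
                                 n_features = 6, informative = 1:3,
                                 effect_sd = 2, seed = 71)
  meta <- build_meta_features(tab, k = 5, seed = 3)
  expect_equal(nrow(meta), nrow(tab))
  expect_equal(ncol(meta), 5)  # 4 scores + label
  expect_true(all(vapply(meta[1:4], function(c) all(c >= 0 & c <= 1), TRUE)))
  expect_identical(meta$label, tab$label)
})

test_that("leakage detector: permuting the fold assignment changes the
           meta table", {
  tab <- simulate_feature_cohort(n_patients = 10, segments_per_class = 8,
                                 n_features = 5, informative = 1:2,
                                 effect_sd = 2, seed = 73)
  pats <- unique(tab$patient_id)
  pf <- setNames(rep_len(1:5, length(pats)), pats)
  fold1 <- unname(pf[tab$patient_id])
  set.seed(4)
  pf2 <- setNames(sample(pf), names(pf))
  while (all(pf2 == pf)) pf2 <- setNames(sample(pf), names(pf))
  fold2 <- unname(pf2[tab$patient_id])
  m1 <- build_meta_features(tab, k = 5, seed = 3, fold_assign = fold1)
  m2 <- build_meta_features(tab, k = 5, seed = 3, fold_assign = fold2)
  expect_false(isTRUE(all.equal(m1[1:4], m2[1:4], tolerance = 1e-12)))
})

test_that("an oracle base learner yields a near-perfect meta column", {
  tab <- simulate_feature_cohort(n_patients = 10, segments_per_class = 10,
                                 n_features = 4, informative = integer(0),
                                 seed = 79)
  tab$feat_01 <- ifelse(tab$label == "apnea", 1, 0)  # label encoded
  specs <- boosting_base_specs()[1:2]
  specs$oracle <- list(
    name = "oracle",
    fit = function(x, y, seed) NULL,
    score = function(model, x) x[["feat_01"]]
  )
  meta <- build_meta_features(tab, specs, k = 5, seed = 5)
  acc <- mean((meta$score_oracle >= 0.5) == (meta$label == "apnea"))
  expect_gte(acc, 0.99)
})

test_that("stacked model: 4-4-1 meta topology, determinism, prediction
           contract", {
  tab <- simulate_feature_cohort(n_patients = 12, segments_per_class = 10,
                                 n_features = 6, informative = 1:3,
                                 effect_sd = 2, seed = 83)
  sp <- split_by_patient(tab, 0.7, 5)
  m1 <- train_stacked(sp$train, k = 5, seed = 11)
  expect_equal(m1$meta$n, c(4, 4, 1))
  p1 <- predict(m1, sp$test)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_true(all(p1$label %in% c("apnea", "normal")))
  m2 <- train_stacked(sp$train, k = 5, seed = 11)
  p2 <- predict(m2, sp$test)
  expect_identical(p1, p2)
  # agreement case: strong signal, bases agree, stack follows
  ev <- evaluate_stacked(m1, sp$test)
  expect_gte(ev$stacked$accuracy, 0.8)
})

test_that("shuffling rows and unshuffling restores the meta table", {
  tab <- simulate_feature_cohort(n_patients = 8, segments_per_class = 8,
                                 n_features = 5, informative = 1:2,
                                 effect_sd = 2, seed = 89)
  # row-order-free learners (exact splits, no subsampling) isolate the
  # fold bookkeeping from stochastic tree construction
  det_spec <- function(depth) list(
    name = sprintf("exact%d", depth),
    fit = function(x, y, seed = 1L) {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L,
                      seed = 1L, eta = 0.3, max_depth = depth,
                      tree_method = "exact", subsample = 1,
                      colsample_bytree = 1),
        data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
        nrounds = 20, verbose = 0)
    },
    score = function(model, x) {
      as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
    })
  specs <- list(a = det_spec(2), b = det_spec(3))
  pats <- unique(tab$patient_id)
  pf <- setNames(rep_len(1:4, length(pats)), pats)
  set.seed(90)
  perm <- sample(nrow(tab))
  m_orig <- build_meta_features(tab, specs, k = 4, seed = 2,
                                fold_assign = unname(pf[tab$patient_id]))
  m_perm <- build_meta_features(tab[perm, ], specs, k = 4, seed = 2,
                                fold_assign = unname(pf[tab$patient_id[perm]]))
  undone <- m_perm[order(perm), ]
  rownames(undone) <- NULL
  expect_equal(undone, m_orig, tolerance = 1e-12)
})
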