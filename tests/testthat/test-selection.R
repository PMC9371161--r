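# Two-stage selection: lambda counting, threshold rule, class grouping,
# balancing, SVM grid, hill climbing.

test_that("null features stay near lambda zero, strong features saturate", {
  set.seed(51)
  n_pat <- 20
  tab <- simulate_feature_cohort(n_patients = n_pat, segments_per_class = 15,
                                 n_features = 6, informative = 1,
                                 effect_sd = 5, seed = 51)
  s <- stage1_lambda(tab)
  expect_equal(unname(s$lambda["feat_01"]), n_pat)  # 5 SD separation
  # pure-noise features: binomial false-positive bound
  expect_true(all(s$lambda[-1] <= 0.15 * n_pat))
  expect_true(all(s$lambda <= n_pat))
  expect_equal(s$n_patients_used, n_pat)
})

test_that("single-class patients are skipped and reported", {
  tab <- simulate_feature_cohort(n_patients = 3, segments_per_class = 5,
                                 n_features = 4, seed = 7)
  tab$label[tab$patient_id == "p001"] <- "apnea"
  s <- stage1_lambda(tab)
  expect_equal(s$skipped, "p001")
  expect_equal(s$n_patients_used, 2)
})

test_that("threshold selection is strict and monotone", {
  s <- structure(list(lambda = c(a = 787, b = 788, c = 0, d = 1574),
                      n_patients_used = 1574),
                 class = "significance_summary")
  sel <- threshold_select(s, 1574)
  expect_false("a" %in% sel)  # 787 is not strictly greater than 787
  expect_true(all(c("b", "d") %in% sel))
  expect_false("c" %in% sel)
  # monotone: raising lambda of a selected feature keeps it selected
  s$lambda["b"] <- 1000
  expect_true("b" %in% threshold_select(s, 1574))
  # empty on all-zero lambda
  s0 <- structure(list(lambda = c(a = 0, b = 0), n_patients_used = 10),
                  class = "significance_summary")
  expect_length(threshold_select(s0, 10), 0)
})

test_that("class grouping splits at the largest lambda gaps", {
  lam <- c(f1 = 1565, f2 = 1529, f3 = 1509, f4 = 1215, f5 = 997, f6 = 947,
           f7 = 831)
  g <- group_classes(lam, k = 4)
  # gaps: 36, 20, 294, 218, 50, 116 -> cut at 294, 218, 116
  expect_equal(g$classes$A, c("f1", "f2", "f3"))
  expect_equal(g$classes$B, "f4")
  expect_equal(g$classes$C, c("f5", "f6"))
  expect_equal(g$classes$D, "f7")
  expect_length(unlist(g$classes), 7)
  expect_equal(anyDuplicated(unlist(g$classes)), 0)
  g1 <- group_classes(lam, k = 1)
  expect_length(g1$classes, 1)
  expect_setequal(g1$classes[[1]], names(lam))
  # equal lambdas always share a class
  g2 <- group_classes(c(x = 10, y = 10, z = 2), k = 2)
  expect_setequal(g2$classes$A, c("x", "y"))
})

test_that("lambda is invariant under monotone transforms (rank-sum part)", {
  tab <- simulate_feature_cohort(n_patients = 6, segments_per_class = 10,
                                 n_features = 3, informative = 1,
                                 effect_sd = 2, seed = 13)
  s1 <- stage1_lambda(tab)
  tab2 <- tab
  tab2$feat_01 <- exp(tab2$feat_01)  # strictly monotone
  s2 <- stage1_lambda(tab2)
  r1 <- tapply(s1$per_patient$ranksum_reject[s1$per_patient$feature == "feat_01"],
               s1$per_patient$patient_id[s1$per_patient$feature == "feat_01"],
               identity)
  r2 <- tapply(s2$per_patient$ranksum_reject[s2$per_patient$feature == "feat_01"],
               s2$per_patient$patient_id[s2$per_patient$feature == "feat_01"],
               identity)
  expect_identical(r1, r2)
})

test_that("balancing equalizes classes and the z-rule drops outliers", {
  tab <- simulate_feature_cohort(n_patients = 5, segments_per_class = 10,
                                 n_features = 4, seed = 17)
  tab <- tab[-(1:12), ]  # unbalance
  tab$feat_02[5] <- tab$feat_02[5] + 10 * sd(tab$feat_02)
  out <- balance_and_clean(tab, seed = 3)
  expect_equal(sum(out$label == "apnea"), sum(out$label == "normal"))
  expect_false(any(abs(out$feat_02 - mean(tab$feat_02)) >
                     9 * sd(tab$feat_02)))
  out2 <- balance_and_clean(tab, seed = 3)
  expect_identical(out, out2)
})

test_that("the default SVM grid mirrors the 21 kernel/parameter configs", {
  g <- svm_grid()
  expect_equal(nrow(g), 21)
  expect_equal(sum(g$kernel == "rbf"), 9)
  expect_equal(sum(g$kernel == "polynomial"), 9)
  expect_equal(sum(g$kernel == "linear"), 3)
  expect_setequal(unique(g$R), c(0.2, 1, 10))
  expect_setequal(unique(g$sigma[g$kernel == "rbf"]), c(1, 5, 25))
  expect_setequal(unique(g$d[g$kernel == "polynomial"]), c(2, 3, 4))
})

test_that("a linearly separable table reaches perfect linear-SVM accuracy", {
  set.seed(19)
  n <- 120
  lab <- rep(c("apnea", "normal"), each = n / 2)
  x1 <- ifelse(lab == "apnea", 2, -2) + rnorm(n, sd = 0.2)
  x2 <- rnorm(n)
  tab <- data.frame(patient_id = rep(sprintf("p%02d", 1:12), each = 10),
                    label = lab, f1 = x1, f2 = x2,
                    stringsAsFactors = FALSE)
  sp <- split_by_patient(tab, 0.7, 1)
  met <- svm_grid_eval(sp$train, sp$test, c("f1", "f2"),
                       svm_grid()[svm_grid()$kernel == "linear", ][1, ,
                                                                   drop = FALSE])
  expect_equal(met$acc, 1)
  expect_true(all(met$sens >= 0 & met$sens <= 1))
  expect_true(all(met$auc >= 0 & met$auc <= 1))
})

test_that("class hill-climb evaluates cumulative unions and picks signal", {
  set.seed(23)
  tab <- simulate_feature_cohort(n_patients = 12, segments_per_class = 12,
                                 n_features = 8, informative = 1:3,
                                 effect_sd = 3, seed = 23)
  sp <- split_by_patient(tab, 0.7, 2)
  lam <- c(feat_01 = 12, feat_02 = 12, feat_03 = 11, feat_04 = 2,
           feat_05 = 2, feat_06 = 1, feat_07 = 1, feat_08 = 0)
  grouping <- group_classes(lam, k = 2)
  small_grid <- svm_grid()[c(2, 20), ]
  res <- hill_climb_classes(sp$train, sp$test, grouping, small_grid)
  expect_equal(nrow(res$trace), 3)  # A, AB, baseline
  expect_true(all(c("A", "AB", "all_features") %in% res$trace$candidate))
  # informative features live in class A; it should be chosen
  expect_true(all(res$chosen %in% unlist(grouping$classes)) ||
                identical(res$chosen, feature_columns(sp$train)))
  expect_true(all(attr(tab, "informative") %in%
                    c(res$chosen, "feat_04", "feat_05")) ||
                length(res$chosen) <= 3)
})

test_that("prefix hill-climb starts at the largest lambda and stops at the
           baseline", {
  tab <- simulate_feature_cohort(n_patients = 12, segments_per_class = 12,
                                 n_features = 8, informative = 1:2,
                                 effect_sd = 4, seed = 29)
  sp <- split_by_patient(tab, 0.7, 3)
  s <- stage1_lambda(sp$train)
  res <- hill_climb_features(sp$train, sp$test, s)
  ord <- names(sort(s$lambda, decreasing = TRUE))
  expect_equal(res$chosen[1], ord[1])
  base_acc <- res$trace$acc[res$trace$candidate == "all_features"]
  chosen_acc <- res$trace$acc[res$trace$candidate == res$chosen_candidate]
  expect_gte(chosen_acc, base_acc)
})

test_that("patient split never leaks a patient across sides", {
  tab <- simulate_feature_cohort(n_patients = 10, segments_per_class = 4,
                                 n_features = 3, seed = 31)
  sp <- split_by_patient(tab, 0.7, 9)
  expect_length(intersect(unique(sp$train$patient_id),
                          unique(sp$test$patient_id)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
})
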