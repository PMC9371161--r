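# Two-stage feature selection: per-patient significance counting
# (lambda) followed by SVM hill-climbing over lambda-ordered feature
# classes or prefixes.

feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

#' Stage 1: per-patient significance counting
#'
#' For every patient and feature, a one-way ANOVA (equal-variance F test)
#' and a Wilcoxon rank-sum test compare apnea against normal segments.
#' A (patient, feature) pair is positive when both tests reject at
#' `alpha`; `lambda[feature]` counts positive pairs across patients, so
#' its maximum is the number of processed patients. Patients with fewer
#' than two segments in either class are skipped and reported.
#'
#' @param table feature data.frame with `patient_id`, `label` and feature
#'   columns.
#' @param alpha significance level (default 0.05).
#' @return object of class `significance_summary`: `lambda` (named
#'   counts), `per_patient` (long data.frame of test outcomes),
#'   `skipped` patient ids, `n_patients_used`, `alpha`.
#' @export
stage1_lambda <- function(table, alpha = 0.05) {
  feats <- feature_columns(table)
  pats <- unique(table$patient_id)
  lambda <- stats::setNames(integer(length(feats)), feats)
  skipped <- character(0)
  rows <- vector("list", length(pats))
  used <- 0L
  for (pi in seq_along(pats)) {
    sub <- table[table$patient_id == pats[pi], , drop = FALSE]
    n_ap <- sum(sub$label == "apnea"); n_no <- sum(sub$label == "normal")
    if (n_ap < 2L || n_no < 2L) {
      skipped <- c(skipped, pats[pi])
      next
    }
    used <- used + 1L
    g <- factor(sub$label, levels = c("apnea", "normal"))
    p_a <- p_w <- rep(NA_real_, length(feats))
    for (j in seq_along(feats)) {
      x <- sub[[feats[j]]]
      p_a[j] <- tryCatch(
        stats::oneway.test(x ~ g, var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
      p_w[j] <- tryCatch(
        suppressWarnings(stats::wilcox.test(x[g == "apnea"], x[g == "normal"],
                                            exact = FALSE)$p.value),
        error = function(e) NA_real_)
    }
    pos <- !is.na(p_a) & p_a < alpha & !is.na(p_w) & p_w < alpha
    lambda <- lambda + pos
    rows[[pi]] <- data.frame(patient_id = pats[pi], feature = feats,
                             p_anova = p_a,
                             ranksum_reject = !is.na(p_w) & p_w < alpha,
                             positive = pos, stringsAsFactors = FALSE)
  }
  if (used == 0L) stopf("no patient has >= 2 segments per class")
  structure(list(lambda = lambda,
                 per_patient = do.call(rbind, Filter(Negate(is.null), rows)),
                 skipped = skipped, n_patients_used = used, alpha = alpha),
            class = "significance_summary")
}

#' @export
print.significance_summary <- function(x, ...) {
  cat(sprintf("<significance_summary> %d features, %d patients used (%d skipped)\n",
              length(x$lambda), x$n_patients_used, length(x$skipped)))
  cat("top lambda: ",
      paste(sprintf("%s=%d", names(sort(x$lambda, decreasing = TRUE))[1:5],
                    sort(x$lambda, decreasing = TRUE)[1:5]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stage 1 threshold selection
#'
#' Keeps a feature iff its lambda count strictly exceeds half the number
#' of processed patients.
#'
#' @param summary a `significance_summary`.
#' @param n_patients number of processed patients (defaults to the count
#'   used by the summary).
#' @return character vector of selected feature names.
#' @export
threshold_select <- function(summary, n_patients = summary$n_patients_used) {
  names(summary$lambda)[summary$lambda > n_patients / 2]
}

#' Group selected features into lambda classes
#'
#' Sorts selected features by lambda descending and splits at the `k - 1`
#' largest gaps between consecutive distinct lambda values; features with
#' equal lambda always share a class, ties in gap size break toward the
#' higher class.
#'
#' @param lambda named numeric vector of lambda values of the selected
#'   features.
#' @param k number of classes (default 4).
#' @return object of class `class_grouping`: `classes` (named list
#'   A, B, ... of feature names, descending lambda) and `ranges`.
#' @export
group_classes <- function(lambda, k = 4) {
  stopifnot(length(lambda) > 0L, k >= 1L)
  ord <- order(lambda, decreasing = TRUE)
  lam <- lambda[ord]
  uvals <- unique(as.numeric(lam))
  k <- min(k, length(uvals))
  cuts <- numeric(0)
  if (k > 1L) {
    gaps <- uvals[-length(uvals)] - uvals[-1L]  # positive, descending order
    cut_idx <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1L)])
    cuts <- (uvals[cut_idx] + uvals[cut_idx + 1L]) / 2  # class boundaries
  }
  cls <- findInterval(-as.numeric(lam), sort(-cuts)) + 1L
  classes <- split(names(lam), cls)
  names(classes) <- LETTERS[seq_along(classes)]
  ranges <- lapply(classes, function(f) range(lambda[f]))
  structure(list(classes = classes, ranges = ranges, lambda = lambda),
            class = "class_grouping")
}

#' @export
print.class_grouping <- function(x, ...) {
  for (nm in names(x$classes)) {
    cat(sprintf("Class %s [%g-%g]: %s\n", nm, x$ranges[[nm]][1],
                x$ranges[[nm]][2], paste(x$classes[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Balance classes and remove outliers
#'
#' Drops rows holding any feature more than `z_thresh` standard
#' deviations from that feature's mean, then randomly undersamples the
#' majority class to the minority count.
#'
#' @param table feature data.frame.
#' @param seed integer seed for the undersampling draw.
#' @param z_thresh outlier threshold in SD units (default 3).
#' @return balanced, cleaned data.frame.
#' @export
balance_and_clean <- function(table, seed = 1L, z_thresh = 3) {
  feats <- feature_columns(table)
  keep <- rep(TRUE, nrow(table))
  for (f in feats) {
    x <- table[[f]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) next
    keep <- keep & abs(x - mean(x)) <= z_thresh * s
  }
  tab <- table[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  idx_ap <- which(tab$label == "apnea")
  idx_no <- which(tab$label == "normal")
  m <- min(length(idx_ap), length(idx_no))
  if (m == 0L) stopf("one class is empty after outlier removal")
  sel <- c(sample(idx_ap, m), sample(idx_no, m))
  out <- tab[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default SVM configuration grid
#'
#' 21 configurations: linear, polynomial (degree 2, 3, 4) and RBF
#' (sigma 1, 5, 25) kernels, each at regularization weight R in
#' {0.2, 1, 10}.
#'
#' @return data.frame with columns `kernel`, `R`, `d`, `sigma`.
#' @export
svm_grid <- function() {
  rbind(
    expand.grid(kernel = "rbf", R = c(0.2, 1, 10), d = NA,
                sigma = c(1, 5, 25), stringsAsFactors = FALSE),
    expand.grid(kernel = "polynomial", R = c(0.2, 1, 10), d = c(2, 3, 4),
                sigma = NA, stringsAsFactors = FALSE),
    expand.grid(kernel = "linear", R = c(0.2, 1, 10), d = NA, sigma = NA,
                stringsAsFactors = FALSE)
  )
}

svm_fit <- function(train, subset, cfg) {
  x <- as.matrix(train[, subset, drop = FALSE])
  y <- factor(train$label, levels = c("apnea", "normal"))
  args <- list(x = x, y = y, cost = cfg$R, scale = TRUE)
  if (cfg$kernel == "linear") {
    args$kernel <- "linear"
  } else if (cfg$kernel == "polynomial") {
    args$kernel <- "polynomial"; args$degree <- cfg$d
    args$gamma <- 1; args$coef0 <- 1          # K = (x.y + 1)^d
  } else {
    args$kernel <- "radial"; args$gamma <- 1 / (2 * cfg$sigma^2)
  }
  do.call(e1071::svm, args)
}

svm_scores <- function(model, test, subset) {
  x <- as.matrix(test[, subset, drop = FALSE])
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv[, 1L])
  # orient the decision value so larger = more apnea-like
  if (!startsWith(colnames(dv)[1L], "apnea")) s <- -s
  list(pred = as.character(pr), score = s)
}

eval_config <- function(train, test, subset, cfg) {
  fit <- svm_fit(train, subset, cfg)
  out <- svm_scores(fit, test, subset)
  cm <- confusion(test$label, out$pred)
  data.frame(kernel = cfg$kernel, R = cfg$R, d = cfg$d, sigma = cfg$sigma,
             sens = sensitivity(cm), spec = specificity(cm),
             acc = accuracy(cm),
             auc = auc_score(test$label, out$score),
             stringsAsFactors = FALSE)
}

#' Evaluate a feature subset over an SVM configuration grid
#'
#' Trains one SVM per configuration on the training split and reports
#' sensitivity, specificity, accuracy and AUC on the held-out split.
#'
#' @param train,test feature data.frames (same schema).
#' @param subset character vector of feature names to use.
#' @param grid configuration data.frame (default [svm_grid()]).
#' @return data.frame of per-configuration metrics.
#' @export
svm_grid_eval <- function(train, test, subset, grid = svm_grid()) {
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    suppressWarnings(eval_config(train, test, subset, grid[i, ]))
  }))
}

#' Stage 2 hill climbing over lambda classes
#'
#' Evaluates the cumulative class unions (A, AB, ABC, ..., plus the
#' all-features baseline) over the SVM grid. The chosen candidate is the
#' one with the highest mean AUC among those whose best grid accuracy is
#' within `acc_tol` of the overall best accuracy (accuracy adjudicates
#' first, AUC breaks the near-ties).
#'
#' @param train,test feature data.frames.
#' @param grouping a `class_grouping`.
#' @param grid SVM configuration grid.
#' @param acc_tol accuracy tolerance in fractional points (default 0.01).
#' @return object of class `selection_result`: `chosen` feature names,
#'   `trace` (per-candidate metrics), `per_config` (full grid metrics).
#' @export
hill_climb_classes <- function(train, test, grouping, grid = svm_grid(),
                               acc_tol = 0.01) {
  cls <- grouping$classes
  cands <- list()
  for (i in seq_along(cls)) {
    cands[[paste(names(cls)[seq_len(i)], collapse = "")]] <-
      unlist(cls[seq_len(i)], use.names = FALSE)
  }
  cands[["all_features"]] <- feature_columns(train)
  per_config <- list()
  trace <- data.frame()
  for (nm in names(cands)) {
    met <- svm_grid_eval(train, test, cands[[nm]], grid)
    met$candidate <- nm
    per_config[[nm]] <- met
    trace <- rbind(trace, data.frame(candidate = nm,
                                     n_features = length(cands[[nm]]),
                                     best_acc = max(met$acc),
                                     mean_auc = mean(met$auc)))
  }
  best_acc <- max(trace$best_acc)
  ok <- trace$best_acc >= best_acc - acc_tol
  chosen_nm <- trace$candidate[ok][which.max(trace$mean_auc[ok])]
  structure(list(chosen = cands[[chosen_nm]], chosen_candidate = chosen_nm,
                 trace = trace, per_config = do.call(rbind, per_config)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> chosen %s (%d features)\n",
              x$chosen_candidate %||% "", length(x$chosen)))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Stage 2 hill climbing over lambda-ordered feature prefixes
#'
#' Features are ordered by lambda descending (the single best feature
#' first); prefixes of growing length are evaluated with one SVM
#' configuration against the all-features baseline, and the shortest
#' prefix whose accuracy reaches the baseline is chosen.
#'
#' @param train,test feature data.frames.
#' @param summary a `significance_summary` (source of the lambda order).
#' @param config single-row SVM configuration (default RBF sigma 25,
#'   R 0.2).
#' @param early_stop stop at the first prefix reaching the baseline
#'   (default TRUE).
#' @return a `selection_result`; `trace` holds one row per evaluated
#'   prefix plus the baseline.
#' @export
hill_climb_features <- function(train, test, summary,
                                config = data.frame(kernel = "rbf", R = 0.2,
                                                    d = NA, sigma = 25),
                                early_stop = TRUE) {
  feats <- feature_columns(train)
  lam <- summary$lambda[feats]
  ord <- names(sort(lam, decreasing = TRUE))
  base <- suppressWarnings(eval_config(train, test, feats, config[1, ]))
  trace <- data.frame(candidate = "all_features", n_features = length(feats),
                      acc = base$acc, sens = base$sens, spec = base$spec,
                      auc = base$auc)
  chosen <- feats
  chosen_nm <- "all_features"
  for (len in seq_along(ord)) {
    met <- suppressWarnings(eval_config(train, test, ord[seq_len(len)],
                                        config[1, ]))
    trace <- rbind(trace, data.frame(candidate = sprintf("prefix_%d", len),
                                     n_features = len, acc = met$acc,
                                     sens = met$sens, spec = met$spec,
                                     auc = met$auc))
    if (met$acc >= base$acc) {
      chosen <- ord[seq_len(len)]
      chosen_nm <- sprintf("prefix_%d", len)
      if (early_stop) break
    }
  }
  structure(list(chosen = chosen, chosen_candidate = chosen_nm,
                 trace = trace, per_config = NULL),
            class = "selection_result")
}

#' Patient-grouped train/test split
#'
#' Splits at the patient level (no patient contributes to both sides).
#'
#' @param table feature data.frame.
#' @param train_frac fraction of patients in the training split.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_by_patient <- function(table, train_frac = 0.7, seed = 1L) {
  pats <- unique(table$patient_id)
  set.seed(as.integer(seed))
  ntr <- max(1L, round(train_frac * length(pats)))
  tr <- sample(pats, ntr)
  list(train = table[table$patient_id %in% tr, , drop = FALSE],
       test = table[!table$patient_id %in% tr, , drop = FALSE])
}
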