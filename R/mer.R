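# Multi-error-reduction (MER) stacked classifier: four gradient-boosting
# base learners whose out-of-fold scores train a small neural-network
# meta-learner (input width 4, one hidden layer of 4 units, sigmoid
# output).

#' Default boosting base-learner specifications
#'
#' Four gradient-boosted tree variants with modest fixed defaults
#' (<= 300 trees, depth <= 6, learning rate 0.1): classic shallow-tree
#' gradient boosting, a depth-wise configuration, a leaf-wise (lossguide)
#' configuration, and a heavily regularised configuration. Any spec with
#' `fit(x, y, seed)` returning an object scored by `score(model, x)` can
#' stand in.
#'
#' @return named list of base-learner specs.
#' @export
boosting_base_specs <- function() {
  xgb_spec <- function(name, params, nrounds) {
    list(
      name = name,
      fit = function(x, y, seed = 1L) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        xgboost::xgb.train(
          params = c(params, list(objective = "binary:logistic",
                                  nthread = 1L, seed = as.integer(seed))),
          data = dtrain, nrounds = nrounds, verbose = 0)
      },
      score = function(model, x) {
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
      }
    )
  }
  list(
    gbm = xgb_spec("gbm", list(eta = 0.1, max_depth = 3, subsample = 1,
                               colsample_bytree = 1), 200),
    xgb = xgb_spec("xgb", list(eta = 0.1, max_depth = 6, subsample = 0.9,
                               colsample_bytree = 0.8), 300),
    leafwise = xgb_spec("leafwise",
                        list(eta = 0.1, max_depth = 0, max_leaves = 31,
                             grow_policy = "lossguide", tree_method = "hist"),
                        200),
    regularized = xgb_spec("regularized",
                           list(eta = 0.1, max_depth = 6, lambda = 3,
                                alpha = 0.5, subsample = 0.8), 300)
  )
}

label01 <- function(label) as.numeric(label == "apnea")

# Weight vector that makes a fresh 4-4-1 nnet approximate "copy input
# column j": hidden unit 1 sharpens x_j around 0.5, the output sharpens
# hidden unit 1; remaining weights start near zero.
copy_column_weights <- function(n_in, size, j, s = 6, t = 8) {
  w <- stats::rnorm((n_in + 1) * size + size + 1, sd = 0.05)
  w[1:(n_in + 1)] <- 0
  w[1] <- -s / 2          # bias of hidden unit 1
  w[1 + j] <- s           # weight from input j
  off <- (n_in + 1) * size
  w[(off + 1):(off + size + 1)] <- 0
  w[off + 1] <- -t / 2    # output bias
  w[off + 2] <- t         # weight from hidden unit 1
  w
}

# Meta-network training: backprop on cross-entropy in 25-epoch chunks up
# to 500 epochs, early-stopped on a 10% meta-validation slice (the
# weights with the best validation loss are kept). Restarts include
# random initialisations and, for each base learner, an informed warm
# start at the "copy that base" solution, so the fitted combiner starts
# no worse than its best single input.
fit_meta_ann <- function(x, y, size = 4, decay = 0.05, max_epochs = 500,
                         chunk = 25, random_restarts = 2) {
  n <- nrow(x)
  n_val <- max(1L, round(0.1 * n))
  val <- sample(n, n_val)
  tr <- setdiff(seq_len(n), val)
  eps <- 1e-12
  # selection score: validation error rate at the 0.5 deployment
  # threshold, cross-entropy as the tie-break
  val_loss <- function(ann) {
    p <- as.numeric(stats::predict(ann, x[val, , drop = FALSE]))
    err <- mean((p >= 0.5) != (y[val] == 1))
    ce <- -mean(y[val] * log(p + eps) + (1 - y[val]) * log(1 - p + eps))
    err + ce / 1e3
  }
  inits <- c(lapply(seq_len(ncol(x)), function(j) {
    copy_column_weights(ncol(x), size, j)
  }), vector("list", random_restarts))
  best <- NULL
  best_loss <- Inf
  for (w0 in inits) {
    ann <- if (is.null(w0)) {
      nnet::nnet(x[tr, , drop = FALSE], y[tr], size = size, entropy = TRUE,
                 decay = decay, maxit = chunk, trace = FALSE)
    } else {
      nnet::nnet(x[tr, , drop = FALSE], y[tr], size = size, entropy = TRUE,
                 decay = decay, maxit = chunk, trace = FALSE, Wts = w0)
    }
    for (step in seq_len(max_epochs %/% chunk)) {
      loss <- val_loss(ann)
      if (loss < best_loss - 1e-8) {
        best_loss <- loss
        best <- ann
      }
      if (step * chunk >= max_epochs) break
      ann <- nnet::nnet(x[tr, , drop = FALSE], y[tr], size = size,
                        entropy = TRUE, decay = decay, maxit = chunk,
                        trace = FALSE, Wts = ann$wts)
    }
  }
  best
}

# patient-grouped, class-checked fold assignment
make_folds <- function(table, k, seed, fold_assign = NULL) {
  n <- nrow(table)
  if (!is.null(fold_assign)) {
    folds <- fold_assign
  } else {
    set.seed(as.integer(seed))
    if ("patient_id" %in% names(table) &&
        length(unique(table$patient_id)) >= k) {
      pats <- unique(table$patient_id)
      pf <- stats::setNames(sample(rep_len(seq_len(k), length(pats))), pats)
      folds <- pf[table$patient_id]
    } else {
      # stratified by class
      folds <- integer(n)
      for (lab in unique(table$label)) {
        idx <- which(table$label == lab)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  }
  for (f in seq_len(k)) {
    labs <- table$label[folds == f]
    if (length(unique(labs)) < 2L) {
      stopf("fold %d lost a class; stratification failed", f)
    }
  }
  as.integer(folds)
}

#' Out-of-fold meta-features for the stacked classifier
#'
#' For each of `k` folds, the base learners are trained on the other
#' `k - 1` folds and score the held-out fold, so every row's meta-features
#' come from models that never saw that row. Folds are grouped by patient
#' when patient ids are available, stratified by class otherwise.
#'
#' @param table feature data.frame (`patient_id`, `label`, features).
#' @param specs base-learner specs (default [boosting_base_specs()]).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param fold_assign optional explicit integer fold assignment (used by
#'   the leakage-detection tests).
#' @return data.frame with one probability column per base learner
#'   (`score_<name>`) plus `label`, rows aligned with `table`.
#' @export
build_meta_features <- function(table, specs = boosting_base_specs(), k = 5,
                                seed = 1L, fold_assign = NULL) {
  stopifnot(k >= 2L)
  feats <- feature_columns(table)
  folds <- make_folds(table, k, seed, fold_assign)
  y <- label01(table$label)
  meta <- matrix(NA_real_, nrow(table), length(specs))
  colnames(meta) <- paste0("score_", names(specs))
  for (f in seq_len(k)) {
    tr <- folds != f
    for (j in seq_along(specs)) {
      m <- specs[[j]]$fit(table[tr, feats, drop = FALSE], y[tr],
                          seed = child_seed(seed, f * 10L + j))
      meta[!tr, j] <- specs[[j]]$score(m, table[!tr, feats, drop = FALSE])
    }
  }
  out <- as.data.frame(meta)
  out$label <- table$label
  out
}

#' Train the MER stacked classifier
#'
#' Builds out-of-fold meta-features, trains the meta-learner (a neural
#' network with one hidden layer of four units and a sigmoid output,
#' backprop on cross-entropy with strong weight decay, early-stopped on a
#' 10% meta-validation slice, at most 500 epochs, with informed restarts
#' at the copy-each-base solutions), and refits the base learners on the
#' full training table for deployment.
#'
#' @inheritParams build_meta_features
#' @return object of class `stacked_model`.
#' @export
train_stacked <- function(table, specs = boosting_base_specs(), k = 5,
                          seed = 1L) {
  feats <- feature_columns(table)
  meta <- build_meta_features(table, specs, k, seed)
  x_meta <- as.matrix(meta[, paste0("score_", names(specs)), drop = FALSE])
  y <- label01(meta$label)
  set.seed(child_seed(seed, 999L))
  ann <- fit_meta_ann(x_meta, y)
  y_full <- label01(table$label)
  bases <- lapply(seq_along(specs), function(j) {
    specs[[j]]$fit(table[, feats, drop = FALSE], y_full,
                   seed = child_seed(seed, 500L + j))
  })
  names(bases) <- names(specs)
  structure(list(bases = bases, specs = specs, meta = ann, k = k,
                 feature_names = feats, seed = seed),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> bases: %s; meta-ANN %d-%d-1; %d features\n",
              paste(names(x$bases), collapse = ", "),
              length(x$bases), 4L, length(x$feature_names)))
  invisible(x)
}

#' Predict with a fitted MER stacked classifier
#'
#' Base-learner probabilities are fed to the meta-network; the label is
#' `apnea` when the meta score reaches 0.5.
#'
#' @param object a `stacked_model`.
#' @param newdata feature data.frame containing the training schema
#'   columns.
#' @param ... unused.
#' @return data.frame with `score` in `[0, 1]` and `label`.
#' @export
predict.stacked_model <- function(object, newdata, ...) {
  x <- newdata[, object$feature_names, drop = FALSE]
  scores <- vapply(seq_along(object$bases), function(j) {
    object$specs[[j]]$score(object$bases[[j]], x)
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- paste0("score_", names(object$bases))
  s <- as.numeric(stats::predict(object$meta, scores))
  data.frame(score = s, label = ifelse(s >= 0.5, "apnea", "normal"),
             stringsAsFactors = FALSE)
}

#' Evaluate a stacked model and its base learners on held-out data
#'
#' @param model a `stacked_model`.
#' @param test feature data.frame with `label`.
#' @return list with `stacked` (a `metrics_report`) and `bases` (one per
#'   base learner).
#' @export
evaluate_stacked <- function(model, test) {
  pred <- predict(model, test)
  stacked <- metrics_report(test$label, pred$label, pred$score)
  x <- test[, model$feature_names, drop = FALSE]
  bases <- lapply(seq_along(model$bases), function(j) {
    s <- model$specs[[j]]$score(model$bases[[j]], x)
    metrics_report(test$label, ifelse(s >= 0.5, "apnea", "normal"), s)
  })
  names(bases) <- names(model$bases)
  list(stacked = stacked, bases = bases)
}

#' Bundle sensitivity, specificity, accuracy and AUC
#'
#' @param truth,pred character labels; `scores` numeric.
#' @return list of class `metrics_report` with the four metrics and the
#'   underlying `confusion_counts`.
#' @export
metrics_report <- function(truth, pred, scores) {
  cm <- confusion(truth, pred)
  structure(list(sensitivity = sensitivity(cm), specificity = specificity(cm),
                 accuracy = accuracy(cm),
                 auc = auc_score(truth, scores), confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("acc=%.4f sens=%.4f spec=%.4f auc=%.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
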