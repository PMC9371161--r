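# End-to-end convenience: features -> two-stage selection -> MER,
# with a patient-grouped train/test split.

#' Run the full apnea-detection pipeline on a cohort
#'
#' Extracts the 66-feature table, splits patients 70/30, balances and
#' cleans the training split, runs Stage 1 significance counting with
#' threshold selection, hill-climbs a lambda-ordered feature prefix with
#' an SVM on an inner patient split, trains the MER stacked classifier on
#' the selected features, and evaluates on the held-out patients.
#'
#' @param cohort list of `(record, annotations, truth)` elements, e.g.
#'   from [generate_cohort()], or an already-extracted feature table.
#' @param mode segmentation protocol: `"windows"` (default) or `"events"`.
#' @param window_s window length in seconds for `"windows"`.
#' @param seed integer seed driving the splits and learners.
#' @param k folds for the stacking meta-features (default 5).
#' @param train_frac training fraction of patients (default 0.7).
#' @return list: `metrics` (stacked `metrics_report`), `base_metrics`,
#'   `selected` feature names, `summary` (Stage 1), `selection`
#'   (hill-climb trace), `table` (the extracted feature table), `split`
#'   row counts.
#' @export
run_osa_pipeline <- function(cohort, mode = c("windows", "events"),
                             window_s = 60, seed = 1L, k = 5,
                             train_frac = 0.7) {
  mode <- match.arg(mode)
  table <- if (is.data.frame(cohort)) cohort else
    extract_cohort_features(cohort, mode = mode, window_s = window_s)
  split <- split_by_patient(table, train_frac, seed)
  train <- balance_and_clean(split$train, seed = child_seed(seed, 1L))

  summ <- stage1_lambda(train)
  sel1 <- threshold_select(summ)
  if (length(sel1) < 2L) sel1 <- feature_columns(train)
  keep_cols <- c("patient_id", "label", sel1)

  inner <- split_by_patient(train[, keep_cols, drop = FALSE], 0.7,
                            child_seed(seed, 2L))
  hc <- hill_climb_features(inner$train, inner$test, summ)
  chosen <- hc$chosen

  model <- train_stacked(train[, c("patient_id", "label", chosen),
                               drop = FALSE],
                         k = k, seed = child_seed(seed, 3L))
  ev <- evaluate_stacked(model, split$test)
  list(metrics = ev$stacked, base_metrics = ev$bases, selected = chosen,
       summary = summ, selection = hc, model = model, table = table,
       split = c(train = nrow(split$train), train_balanced = nrow(train),
                 test = nrow(split$test)))
}
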