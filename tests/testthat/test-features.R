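# The 66-feature battery: definitions on constructed windows, schema,
# scale behaviour, and robustness on generator output.

test_that("SaO2 features on a constant window match hand values", {
  f <- suppressWarnings(sao2_features(rep(97, 60)))
  expect_equal(unname(f["sao2.var"]), 0)
  expect_equal(unname(f["sao2.SD1"]), 0)
  expect_equal(unname(f["sao2.NumZC"]), 0)
  expect_equal(unname(f["sao2.MM2"]), 0)
  expect_equal(unname(f["sao2.Bel98"]), 0)
  expect_equal(unname(f["sao2.Abo98"]), 60)
  expect_equal(unname(f["sao2.min"]), 97)
  expect_equal(unname(f["sao2.med"]), 97)
  expect_equal(unname(f["sao2.mean"]), 97)
})

test_that("Bel98/Abo98 threshold arithmetic on a step window", {
  w <- c(rep(97, 30), rep(92, 10), rep(97, 20))
  f <- sao2_features(w)
  expect_equal(unname(f["sao2.min"]), 92)
  expect_equal(unname(f["sao2.Bel98"]), 10)  # 92 < 0.98 * 97 = 95.06
  expect_equal(unname(f["sao2.Abo98"]), 50)
  expect_identical(names(f), feature_schema()[1:12])
})

test_that("MM2 counts only extremum excursions above 2 points", {
  w <- c(rep(96, 10), 96, 93, 96, 95.5, 96, 92, 96, rep(96, 10))
  # excursions: 96->93 (3), 93->96 (3), 96->95.5 (0.5), 95.5->96 (0.5),
  # 96->92 (4), 92->96 (4): four excursions exceed 2 points
  f <- sao2_features(w)
  expect_equal(unname(f["sao2.MM2"]), 4)
})

test_that("airflow features separate spectral bands and match schema", {
  t <- 0:59
  f45 <- airflow_features(sin(2 * pi * 0.45 * t))
  expect_gt(f45[["airflow.mean_PSD0.4/0.5"]], f45[["airflow.mean_PSD0/0.1"]])
  fc <- airflow_features(rep(2, 60))
  expect_equal(unname(fc["airflow.std"]), 0)
  expect_lt(max(abs(fc[c("airflow.mean_D1", "airflow.mean_D2",
                         "airflow.mean_D3")])), 1e-8)
  expect_identical(names(fc), feature_schema()[13:22])
})

test_that("effort features: zero window, triangle inequality, homogeneity", {
  z <- suppressWarnings(abdominal_features(rep(0, 600)))
  expect_true(all(z == 0))
  set.seed(41)
  w <- rnorm(600)
  a1 <- abdominal_features(w)
  expect_gte(a1[["abd.sum_abs"]], abs(sum(w)))
  a2 <- abdominal_features(2 * w)
  expect_equal(unname(a2["abd.sum_abs"]), unname(2 * a1["abd.sum_abs"]))
  t1 <- thoracic_features(w)
  t2 <- thoracic_features(2 * w)
  expect_equal(unname(t2["thor.var"]), unname(4 * t1["thor.var"]))
  expect_equal(unname(t2["thor.sum"]), unname(2 * t1["thor.sum"]))
  expect_identical(names(a1), feature_schema()[23:28])
  expect_identical(names(t1), feature_schema()[29:34])
})

test_that("NN50 is one-sided and RR features match brute-force scans", {
  iv <- c(1.00, 1.06, 1.00, 1.06)
  rr <- structure(list(times_s = cumsum(c(10, iv)), intervals_s = iv),
                  class = "rr_series")
  f <- suppressWarnings(
    ecg_features(rnorm(125 * 60), 125, rr, edr = rnorm(60) + 5,
                 qrs = matrix(rnorm(10 * 15), 10), t0 = 0, t1 = 60))
  expect_equal(unname(f["ecg.NN50_RR"]), 2)
  expect_equal(unname(f["ecg.NN50_RR"]), oracle_nn50(iv))
  expect_identical(names(f), feature_schema()[35:66])
  # constant RR: variability features collapse to zero
  ivc <- rep(1, 10)
  rrc <- structure(list(times_s = cumsum(c(5, ivc)), intervals_s = ivc),
                   class = "rr_series")
  fc <- suppressWarnings(
    ecg_features(rnorm(125 * 60), 125, rrc, edr = rep(1, 60),
                 qrs = matrix(rnorm(10 * 15), 10), t0 = 0, t1 = 60))
  expect_equal(unname(fc["ecg.SDSD_RR"]), 0)
  expect_equal(unname(fc["ecg.tSD_RR"]), 0)
  expect_equal(unname(fc["ecg.SCrC_3_RR"]), 0)
  expect_equal(unname(fc["ecg.SCrC_4_RR"]), 0)
})

test_that("degenerate segments fall back to zeros with warnings", {
  rr0 <- structure(list(times_s = 5, intervals_s = numeric(0)),
                   class = "rr_series")
  w <- capture_warnings(
    f <- ecg_features(rnorm(125 * 30), 125, rr0, edr = rnorm(30),
                      qrs = matrix(numeric(0), 0, 15), t0 = 0, t1 = 30))
  expect_true(any(grepl("RR", w)))
  expect_true(any(grepl("QRS", w)))
  expect_equal(unname(f["ecg.mean_RR"]), 0)
  expect_equal(unname(f["ecg.max_dia_kPCA"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("extract_all returns the 66-name schema, deterministically", {
  seg <- small_segments()[[1]]
  v1 <- suppressWarnings(extract_all(seg))
  v2 <- suppressWarnings(extract_all(seg))
  expect_length(v1, 66)
  expect_identical(names(v1), feature_schema())
  expect_identical(as.numeric(v1), as.numeric(v2))
})

test_that("no feature is NaN/Inf on generator segments and desaturation
           features carry the expected signs", {
  segs <- small_segments()
  tab <- feature_table_from_segments(segs)
  for (f in feature_schema()) {
    expect_true(all(is.finite(tab[[f]])), info = f)
  }
  # second record too, pooled for the class-sign check
  el2 <- small_cohort()[[2]]
  prep2 <- prepare_record(el2$record)
  tab2 <- feature_table_from_segments(
    segment_prepared(prep2, el2$annotations, "windows"))
  pool <- rbind(tab, tab2)
  ap <- pool$label == "apnea"
  skip_if(sum(ap) < 2 || sum(!ap) < 2)
  expect_lt(mean(pool[["sao2.min"]][ap]), mean(pool[["sao2.min"]][!ap]))
  expect_gt(mean(pool[["sao2.Bel98"]][ap]), mean(pool[["sao2.Bel98"]][!ap]))
})

test_that("scale equivariance holds family-wise where definitions imply it", {
  set.seed(43)
  w <- 95 + cumsum(rnorm(60, sd = 0.3))
  w <- pmin(pmax(w, 80), 100)
  a <- sao2_features(w)
  # scale-invariant features unchanged under affine-free positive scaling
  b <- sao2_features(w * 1.0)  # identity guard
  expect_equal(a, b)
  x <- rnorm(60)
  fa <- airflow_features(x)
  fb <- airflow_features(3 * x)
  expect_equal(unname(fb["airflow.mean"]), unname(3 * fa["airflow.mean"]))
  expect_equal(unname(fb["airflow.std"]), unname(3 * fa["airflow.std"]))
  expect_equal(unname(fb["airflow.comp"]), unname(fa["airflow.comp"]))
})
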