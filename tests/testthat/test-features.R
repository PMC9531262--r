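test_that("feature vocabulary exceeds 1,000 deterministic unique names", {
  fn <- acg_feature_names(frequency_grid())
  expect_gt(length(fn), 1000)
  expect_equal(anyDuplicated(fn), 0L)
  # naming grammar {modality}_{f_i}[_{f_j}]_{stat}
  expect_true(all(grepl("^(tof|att|tofatt)_(f\\d{2}|all)(_f\\d{2})?(_\\w+)$", fn)))
  expect_true("att_f03_mean" %in% fn)
  expect_true("tofatt_f04_f04_cor" %in% fn)
})

test_that("feature table aligns rows with patient-days and is deterministic", {
  coh <- generate_cohort(tiny_config(), seed = 3)
  tab <- build_feature_table(coh)
  expect_s3_class(tab, "acg_feature_table")
  expect_equal(nrow(tab$values), nrow(cohort_clinical(coh)))
  expect_equal(colnames(tab$values), acg_feature_names(coh$frequency_grid))
  expect_false(anyNA(tab$values))
  expect_equal(nrow(tab$targets), nrow(tab$row_index))
  tab2 <- build_feature_table(generate_cohort(tiny_config(), seed = 3))
  expect_identical(tab$values, tab2$values)
})

test_that("patient-day rows are the arithmetic mean over the session's measurements", {
  coh <- generate_cohort(tiny_config(), seed = 4)
  day_tab <- build_feature_table(coh, granularity = "patient_day")
  meas_tab <- build_feature_table(coh, granularity = "measurement")
  key <- paste(meas_tab$row_index$patient_id, meas_tab$row_index$day, sep = "|")
  for (k in rownames(day_tab$values)) {
    expect_equal(day_tab$values[k, ],
                 colMeans(meas_tab$values[key == k, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("constant series zero out variation features and keep the means", {
  coh <- generate_cohort(tiny_config(), seed = 5)
  for (i in seq_along(coh$records)) {
    for (j in seq_along(coh$records[[i]]$sessions)) {
      s <- coh$records[[i]]$sessions[[j]]
      s$tof[] <- rep(1:10 * 2, each = nrow(s$tof))  # constant per channel
      s$att[] <- 7
      coh$records[[i]]$sessions[[j]] <- s
    }
  }
  suppressWarnings(tab <- build_feature_table(coh))
  v <- tab$values[1, ]
  expect_equal(unname(v[sprintf("tof_f%02d_mean", 1:10)]), 1:10 * 2)
  expect_equal(unname(v[sprintf("att_f%02d_mean", 1:10)]), rep(7, 10))
  zero_stats <- c("sd", "slope", "acf1", "cv", "iqr", "rmsdiff")
  for (st in zero_stats) {
    expect_equal(unname(v[sprintf("tof_f%02d_%s", 1:10, st)]), rep(0, 10))
  }
  expect_equal(unname(v["tof_f01_f02_cor"]), 0)
  expect_equal(unname(v["tofatt_f01_f01_cor"]), 0)
})

test_that("standardization z-scores, is idempotent, and erases affine differences", {
  coh <- generate_cohort(tiny_config(), seed = 6)
  tab <- build_feature_table(coh)
  std <- standardize_features(tab)
  mu <- colMeans(std$values)
  sdv <- apply(std$values, 2, sd)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(sdv - 1) < 1e-9 | sdv == 0))
  std2 <- standardize_features(std)
  expect_equal(std2$values, std$values, tolerance = 1e-9)

  # a column that is 2x + 7 of another becomes numerically identical
  tab$values[, 2] <- 2 * tab$values[, 1] + 7
  std3 <- standardize_features(tab)
  expect_equal(std3$values[, 2], std3$values[, 1],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("row/target alignment survives joint permutation", {
  coh <- generate_cohort(tiny_config(), seed = 7)
  tab <- build_feature_table(coh)
  perm <- sample(nrow(tab$values))
  tab2 <- tab
  tab2$values <- tab$values[perm, , drop = FALSE]
  tab2$row_index <- tab$row_index[perm, , drop = FALSE]
  tab2$targets <- tab$targets[perm, , drop = FALSE]
  key <- function(t) paste(t$row_index$patient_id, t$row_index$day, sep = "|")
  m <- match(key(tab), key(tab2))
  expect_equal(tab2$targets$sofa[m], tab$targets$sofa)
  expect_equal(unname(tab2$values[m, ]), unname(tab$values))
})
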