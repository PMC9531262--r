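make_clinical <- function(cg, sg, param = "lactate") {
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(length(cg) + length(sg))),
    group = rep(c("CG", "SG"), c(length(cg), length(sg))),
    day = 1,
    cam_icu = rep(c(FALSE, TRUE), c(length(cg), length(sg))))
  df[[param]] <- c(cg, sg)
  df
}

test_that("group comparison reports medians, quartiles and rank-test p-values", {
  # linear-interpolation quantiles of 1..5: median 3, q25 2, q75 4
  clin <- make_clinical(cg = 1:5, sg = 1:5 + 10)
  row <- group_compare(clin, parameters = "lactate", day = 1)
  expect_equal(row$cg_median, 3)
  expect_equal(row$cg_q25, 2)
  expect_equal(row$cg_q75, 4)
  expect_equal(row$sg_median, 13)
  expect_true(row$p_value < 0.05 && row$significant)
  expect_match(row$test, "mann-whitney")
  expect_true(row$cg_q25 <= row$cg_median && row$cg_median <= row$cg_q75)

  # identical groups: no significance
  same <- make_clinical(cg = c(1, 2, 3, 4, 5), sg = c(1, 2, 3, 4, 5))
  row2 <- suppressWarnings(group_compare(same, parameters = "lactate", day = 1))
  expect_gt(row2$p_value, 0.05)
  expect_false(row2$significant)

  # CAM-ICU rates compared by chi-squared on the 2x2 table
  clin$cam_icu <- rep(c(FALSE, TRUE), each = 5)
  row3 <- group_compare(clin, parameters = "cam_icu", day = 1)
  expect_equal(row3$test, "chi-squared")
  expect_equal(row3$p_value,
               suppressWarnings(chisq.test(table(clin$group, clin$cam_icu))$p.value))
  expect_warning(group_compare(clin, parameters = "nonexistent", day = 1), "absent")
})

test_that("rank-test p-values are invariant to monotone transforms", {
  set.seed(30)
  clin <- make_clinical(cg = rlnorm(8), sg = rlnorm(8, 0.8))
  p1 <- group_compare(clin, parameters = "lactate", day = 1)$p_value
  clin$lactate <- exp(clin$lactate)
  p2 <- group_compare(clin, parameters = "lactate", day = 1)$p_value
  expect_equal(p1, p2)
})

test_that("correlation table reports absolute Pearson correlations", {
  ds <- data.frame(patient_id = sprintf("P%02d", 1:3), day = 1,
                   dim_tof = c(1, 2, 3), dim_att = c(1, 2, 3),
                   dim_mean = c(1, 2, 3))
  clin <- data.frame(patient_id = sprintf("P%02d", 1:3), day = 1,
                     sofa = c(1, 2, 4), icdsc = c(3, 2, 1))
  ct <- correlation_table(ds, list(), clin, parameters = c("sofa", "icdsc"))
  # closed-form Pearson of (1,2,3) vs (1,2,4)
  expect_equal(ct$r_dim[1], 0.98198, tolerance = 1e-5)
  # perfect inverse correlation reports 1 in absolute value
  expect_equal(ct$r_dim[2], 1, tolerance = 1e-12)
  expect_true(all(ct$r_dim >= 0 & ct$r_dim <= 1))
  # a GA component equal to the parameter itself correlates perfectly
  ct2 <- correlation_table(ds, list(sofa = c(1, 2, 4)), clin,
                           parameters = c("sofa", "icdsc"))
  expect_equal(ct2$r_ga[1], 1, tolerance = 1e-12)
  expect_true(is.na(ct2$r_ga[2]))
  # zero-variance input reported as missing
  clin$icdsc <- c(2, 2, 2)
  ct3 <- correlation_table(ds, list(), clin, parameters = "icdsc")
  expect_true(is.na(ct3$r_dim))
})

test_that("SOFA attains the top GA correlation in most default cohorts", {
  wins <- 0
  n_seeds <- 5
  params <- c("sofa", "icdsc", "lactate", "pct", "creatinine", "bilirubin")
  for (seed in seq_len(n_seeds)) {
    coh <- generate_cohort(cohort_config(), seed = 400 + seed)
    std <- standardize_features(build_feature_table(coh))
    ga_scores <- list()
    for (i in seq_along(params)) {
      res <- ga_evolve(std, params[i],
                       ga_config(population_size = 80, generations = 20,
                                 seed = seed * 10 + i))
      ga_scores[[params[i]]] <- pc1_scores(res$best, std)
    }
    ct <- correlation_table(dimensionality_summary(coh), ga_scores,
                            cohort_clinical(coh), parameters = params)
    wins <- wins + (which.max(ct$r_ga) == 1)
  }
  expect_gte(wins, ceiling((n_seeds + 1) / 2))  # majority of seeds
})
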