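test_that("initial distribution spreads prevalence over the grade states", {
  dr <- draw_with()
  v <- initial_distribution("gt10", dr)
  expect_equal(v[["no_cancer"]], 0.330, tolerance = 1e-12)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_equal(v[["undx_high_nc"]], 0.670 * 0.139, tolerance = 1e-9)
  expect_equal(v[["undx_int_c"]], 0.670 * 0.332, tolerance = 1e-9)
  for (st in pca_strata())
    expect_equal(sum(initial_distribution(st, dr)), 1, tolerance = 1e-12)
  expect_error(initial_distribution("psa-99", dr), "unknown PSA stratum")
})

test_that("transition matrices encode the screening and disease rules", {
  dr <- draw_with()
  opts <- pca_options()
  M <- build_transition_matrix("standard", "gt10", dr, 0, opts)
  q <- 0.01647 # published all-cause death probability at age 65

  # the treatment year always resolves to post-treatment or death
  expect_equal(M["treat_year1", "post_treatment"] + M["treat_year1", "death"],
               1, tolerance = 1e-12)
  expect_equal(sum(M["treat_year1", c("post_treatment", "death")]),
               sum(M["treat_year1", ]), tolerance = 1e-12)
  # recurrence hazard is survival-scaled
  expect_equal(M["post_treatment", "recurrence"], (1 - q) * 0.066,
               tolerance = 1e-9)
  # standard-arm detection moves intermediate-grade men without
  # comorbidities straight to treatment
  expect_equal(M["undx_int_nc", "treat_year1"], (1 - q) * 0.76,
               tolerance = 1e-9)
  # comorbid low/intermediate detections defer instead of treating
  expect_equal(M["undx_int_c", "deferred_int"], (1 - q) * 0.76,
               tolerance = 1e-9)
  expect_equal(M["undx_int_c", "treat_year1"], 0)
  # death is absorbing
  expect_equal(M["death", ], c(rep(0, 12), death = 1),
               ignore_attr = TRUE)
})

test_that("transition rows are stochastic for random draws and cycles", {
  p <- test_table()
  opts <- pca_options()
  for (i in 1:25) {
    dr <- sample_draw(p, seed = 100, draw_id = i)
    sg <- if (i %% 2) "standard" else "mri"
    st <- pca_strata()[1 + (i %% 4)]
    M <- build_transition_matrix(sg, st, dr, i %% 10, opts)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    expect_true(all(M >= 0))
  }
})

test_that("age dependence enters only through mortality", {
  dr <- draw_with()
  opts <- opts_nodeath()
  M0 <- build_transition_matrix("mri", "2.5-4.0", dr, 0, opts)
  for (k in 1:9)
    expect_equal(build_transition_matrix("mri", "2.5-4.0", dr, k, opts), M0)
})

test_that("the cohort trace conserves mass and death is monotone", {
  dr <- draw_with()
  for (sg in c("standard", "mri")) for (st in c("lt2.5", "gt10")) {
    tr <- run_cohort(sg, st, dr)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
  }
})

test_that("disease-free cohorts reproduce the closed-form test costs", {
  # no disease, no deaths: every cycle costs exactly the screening round
  dr <- draw_with(p_cancer_psa_lt25 = 0)
  opts <- opts_nodeath()
  std <- evaluate_strategy("standard", "lt2.5", dr, opts = opts)
  ann <- sum((1.03)^-(0:9))
  expect_equal(std$expected_cost, (18 + 474) * ann, tolerance = 1e-9)
  mri <- evaluate_strategy("mri", "lt2.5", dr, opts = opts)
  expect_equal(mri$expected_cost, (18 + 560 + 0.12 * 723) * ann,
               tolerance = 1e-9)
})

test_that("discounted QALYs hit the geometric-series bound without disease", {
  dr <- draw_with(p_cancer_psa_lt25 = 0)
  dr[grepl("^disutility_", names(dr))] <- 0
  out <- evaluate_strategy("standard", "lt2.5", dr, opts = opts_nodeath())
  expect_equal(out$expected_qaly, 8.786109, tolerance = 1e-5)
  expect_equal(out$undiscounted_qaly, 10, tolerance = 1e-9)
})

test_that("higher test sensitivity weakly increases treated mass", {
  post_detection_mass <- function(sens) {
    dr <- draw_with(sens_standard_biopsy = sens)
    tr <- run_cohort("standard", "gt10", dr)
    sum(tr$occupancy[11, c("treat_year1", "post_treatment", "deferred_low",
                           "deferred_int", "recurrence")])
  }
  m <- vapply(c(0.2, 0.5, 0.76, 0.95), post_detection_mass, numeric(1))
  expect_true(all(diff(m) >= 0))
})
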