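test_that("discount factors follow the 3% annual convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(sum(discount_factor(0:9, 0.03)), 8.786109, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.03), "non-negative")
  expect_error(discount_factor(1, -0.5), "non-negative")
})

test_that("reward schedule carries the published state values", {
  dr <- draw_with()
  rew <- build_rewards("mri", dr)
  at <- function(m, i, st) unname(m[i, st])
  expect_equal(at(rew$utility, 1, "treat_year1"), 1 - 0.119)
  expect_equal(at(rew$utility, 5, "post_treatment"), 1 - 0.050)
  expect_equal(at(rew$utility, 3, "deferred_low"), 1 - 0.233)
  expect_equal(at(rew$utility, 3, "recurrence"), 1 - 0.320)
  expect_equal(at(rew$cost, 2, "deferred_int"), 706)
  expect_equal(at(rew$cost, 2, "recurrence"), 1353)
  # equal-thirds treatment mix
  expect_equal(at(rew$cost, 1, "treat_year1"), (16306 + 21860 + 19792) / 3,
               tolerance = 1e-9)
  expect_equal(at(rew$cost, 1, "death"), 0)
  expect_equal(at(rew$utility, 1, "death"), 0)

  # zeroing every decrement restores full utility in all living states
  dr0 <- dr
  dr0[grepl("^disutility_", names(dr0))] <- 0
  rew0 <- build_rewards("standard", dr0)
  expect_true(all(rew0$utility[, -13] == 1))
})

test_that("a constant cost on every living state cancels in the increment", {
  dr <- draw_with()
  opts <- pca_options()
  traces <- lapply(c(standard = "standard", mri = "mri"), run_cohort,
                   stratum = "4.1-10.0", draw = dr, opts = opts)
  rews <- lapply(c(standard = "standard", mri = "mri"), build_rewards,
                 draw = dr, opts = opts)
  base_inc <- diff(vapply(c("standard", "mri"), function(sg)
    accumulate(traces[[sg]], rews[[sg]], 0.03)$expected_cost, numeric(1)))
  shifted <- lapply(rews, function(r) {
    r$cost[, -13] <- r$cost[, -13] + 250
    r
  })
  shift_inc <- diff(vapply(c("standard", "mri"), function(sg)
    accumulate(traces[[sg]], shifted[[sg]], 0.03)$expected_cost, numeric(1)))
  expect_equal(base_inc, shift_inc, tolerance = 1e-8)
})

test_that("constant single-state occupancy integrates to the annuity value", {
  dr <- draw_with(p_cancer_psa_lt25 = 0, cost_psa = 100,
                  cost_standard_biopsy = 0)
  out <- evaluate_strategy("standard", "lt2.5", dr, opts = opts_nodeath())
  expect_equal(out$expected_cost, 878.6109, tolerance = 1e-4)
  # zero discount rate collapses to the undiscounted totals
  dr0 <- dr
  dr0["discount_rate"] <- 0
  out0 <- evaluate_strategy("standard", "lt2.5", dr0, opts = opts_nodeath())
  expect_equal(out0$expected_cost, out0$undiscounted_cost)
  expect_equal(out0$expected_qaly, out0$undiscounted_qaly)
})

test_that("QALYs strictly decrease as a decrement's magnitude grows", {
  q <- vapply(c(-0.15, -0.32, -0.55), function(v) {
    dr <- draw_with(disutility_recurrence = v)
    evaluate_strategy("standard", "gt10", dr)$expected_qaly
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("discounting never increases totals", {
  dr <- draw_with()
  for (sg in c("standard", "mri")) {
    out <- evaluate_strategy(sg, "2.5-4.0", dr)
    expect_lte(out$expected_cost, out$undiscounted_cost)
    expect_lte(out$expected_qaly, out$undiscounted_qaly)
    expect_true(out$expected_qaly >= 0 && out$expected_qaly <= 8.78612)
  }
})
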