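test_that("default configuration reproduces the published input tables", {
  p <- test_table()
  row <- function(nm) p[p$name == nm, ]
  r <- row("sens_mri")
  expect_equal(r$base, 0.760)
  expect_equal(c(r$low, r$high), c(0.528, 0.911))
  expect_equal(r$family, "beta")
  r <- row("cost_mri_guided_biopsy")
  expect_equal(r$base, 723)
  expect_equal(c(r$low, r$high), c(315, 1445))
  expect_equal(r$family, "gamma")
  expect_equal(row("p_cancer_psa_gt10")$base, 0.670)
  expect_equal(row("disutility_recurrence")$base, -0.320)
  expect_equal(row("discount_rate")$family, "fixed")
  # the six grade probabilities are printed summing to one
  expect_equal(sum(p$base[grepl("^p_grade_", p$name)]), 1.0)
})

test_that("missing or invalid parameters are reported by name", {
  cfg <- raw_config()
  keep <- vapply(cfg$parameters, function(r) r$name != "p_recurrence_psa_gt10",
                 logical(1))
  cfg$parameters <- cfg$parameters[keep]
  expect_error(load_parameter_table(cfg), "p_recurrence_psa_gt10")

  cfg <- raw_config()
  i <- which(vapply(cfg$parameters, function(r) r$name == "sens_mri",
                    logical(1)))
  cfg$parameters[[i]]$high <- 1.5
  expect_error(load_parameter_table(cfg), "sens_mri")

  cfg <- raw_config()
  cfg$parameters[[i]]$low <- 0.9 # above the base value
  expect_error(load_parameter_table(cfg), "low <= base <= high")
})

test_that("beta fit preserves the mean and reproduces the 95% interval", {
  # symmetric interval forces equal shapes
  f <- fit_beta_from_mean_interval(0.5, 0.2, 0.8)
  expect_equal(f$shape1, f$shape2, tolerance = 1e-4)

  cases <- list(c(0.76, 0.528, 0.911),  # MRI sensitivity
                c(0.90, 0.644, 0.997),  # MRI-guided biopsy sensitivity
                c(0.25, 0.094, 0.460))  # upgrading probability
  for (cs in cases) {
    f <- fit_beta_from_mean_interval(cs[1], cs[2], cs[3])
    # independent check: evaluate the fitted distribution's quantiles and mean
    expect_equal(f$shape1 / (f$shape1 + f$shape2), cs[1], tolerance = 1e-6)
    q <- stats::qbeta(c(0.025, 0.975), f$shape1, f$shape2)
    expect_lt(max(abs(q - cs[2:3])), 0.02)
  }
  expect_error(fit_beta_from_mean_interval(1, 0.906, 1), "degenerate")
  expect_error(fit_beta_from_mean_interval(0.5, 0.6, 0.9), "inside")
})

test_that("gamma fit preserves the mean and reproduces the 95% interval", {
  # mean preservation is exact; with one remaining degree of freedom the two
  # quantiles are matched in the least-squares sense, so fit quality is
  # judged on the interval-width scale
  f <- fit_gamma_from_mean_interval(723, 315, 1445)
  expect_equal(f$shape / f$rate, 723, tolerance = 1e-6)
  q <- stats::qgamma(c(0.025, 0.975), shape = f$shape, rate = f$rate)
  expect_lt(max(abs(q - c(315, 1445))) / (1445 - 315), 0.06)

  f <- fit_gamma_from_mean_interval(18, 7, 38)
  expect_equal(f$shape / f$rate, 18, tolerance = 18 * 1e-6)

  f <- fit_gamma_from_mean_interval(100, 100, 100)
  expect_equal(f$family, "fixed")
  expect_equal(f$point, 100)
})

test_that("fitted distributions sit close to every published interval", {
  fr <- fit_residuals(test_table())
  fr <- fr[fr$family != "fixed", ]
  width <- fr$q975_target - fr$q025_target
  expect_lt(max(abs(fr$resid_low) / width), 0.10)
  expect_lt(max(abs(fr$resid_high) / width), 0.10)
})

test_that("boundary-mean specificity is held at its point value", {
  fits <- attr(test_table(), "fits")
  f <- fits[["spec_mri_guided_biopsy"]]
  expect_equal(f$family, "fixed")
  expect_equal(f$point, 1.0)
})

test_that("base-case draw carries the printed values", {
  dr <- base_case_draw(test_table())
  expect_equal(dr[["spec_mri_guided_biopsy"]], 1.000)
  expect_equal(dr[["disutility_recurrence"]], -0.320)
  expect_equal(dr[["wtp_threshold"]], 1e5)
  expect_equal(sum(dr[grepl("^p_grade_", names(dr))]), 1, tolerance = 1e-12)
})

test_that("sampling is reproducible and independent across draw ids", {
  p <- test_table()
  d1 <- sample_draw(p, seed = 42, draw_id = 7)
  d2 <- sample_draw(p, seed = 42, draw_id = 7)
  expect_identical(as.numeric(d1), as.numeric(d2))
  d3 <- sample_draw(p, seed = 42, draw_id = 8)
  expect_false(all(as.numeric(d1) == as.numeric(d3)))
  # fixed-family settings never vary
  expect_equal(d1[["discount_rate"]], 0.03)
  expect_equal(d3[["horizon_years"]], 10)
})

test_that("every sampled draw satisfies the domain invariants", {
  p <- test_table()
  m <- sample_draws(p, 200, seed = 5)
  probs <- p$name[p$role %in% c("probability", "test_characteristic")]
  expect_true(all(m[, probs] >= 0 & m[, probs] <= 1))
  costs <- p$name[p$role == "cost_usd"]
  expect_true(all(m[, costs] >= 0))
  decs <- p$name[p$role == "utility_decrement"]
  expect_true(all(m[, decs] <= 0))
  gsum <- rowSums(m[, grepl("^p_grade_", colnames(m))])
  expect_lt(max(abs(gsum - 1)), 1e-12)
})

test_that("sample means converge to the printed base values", {
  p <- test_table()
  m <- sample_draws(p, 4000, seed = 9)
  for (nm in c("sens_mri", "cost_mri", "p_upgrade")) {
    se <- stats::sd(m[, nm]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, nm]) - p$base[p$name == nm]), 3 * se)
  }
})
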