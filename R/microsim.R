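# Individual-level microsimulation: an independent implementation of the
# same stochastic process as the cohort engine, used as a validation
# oracle. Events are sampled in the engine's order (reward accrual at cycle
# start, screening events, background mortality, detection, progression);
# any divergence between the two is a bug, not a modelling choice.

# Vectorised core over n patients. Returns per-patient discounted totals,
# per-cycle event counts and (optionally) the full trajectory log for
# patient 1.
.msim <- function(n, strategy, stratum, draw, opts, log = FALSE) {
  h <- as.integer(draw[["horizon_years"]])
  s <- .S()
  d <- function(nm) draw[[nm]]
  prof <- .screen_profile(strategy, draw, opts)
  f <- discount_factor(0:(h - 1), d("discount_rate"))
  r <- d(.stratum_params(stratum)$recurrence)
  up <- d("p_upgrade")
  treat_cost <- d("w_prostatectomy") * d("cost_prostatectomy") +
    d("w_radiotherapy") * d("cost_radiotherapy") +
    d("w_brachytherapy") * d("cost_brachytherapy")

  # deterministic per-state rewards, screening components handled separately
  u_base <- d("utility_healthy")
  c0 <- stats::setNames(numeric(13), pca_states())
  u0 <- stats::setNames(rep(u_base, 13), pca_states())
  u0[c("undx_low_nc", "undx_int_nc", "undx_low_c", "undx_int_c")] <-
    u_base + d("disutility_low_int_grade")
  u0[c("undx_high_nc", "undx_high_c")] <- u_base + d("disutility_high_grade")
  c0["treat_year1"] <- treat_cost
  u0["treat_year1"] <- u_base + d("disutility_treatment_year1")
  c0["post_treatment"] <- d("cost_post_treatment")
  u0["post_treatment"] <- u_base + d("disutility_treatment_later")
  c0[c("deferred_low", "deferred_int")] <- d("cost_untreated_comorbid")
  u0[c("deferred_low", "deferred_int")] <- u_base + d("disutility_comorbid_pca")
  c0["recurrence"] <- d("cost_post_treatment")
  u0["recurrence"] <- u_base + d("disutility_recurrence")
  u0["death"] <- 0
  u0 <- pmax(u0, 0)

  # screening-round components by disease status
  det_cost_h <- if (strategy == "standard")
    d("cost_psa") + d("cost_standard_biopsy") else d("cost_psa") + d("cost_mri")
  det_cost_d <- det_cost_h
  bx_extra_cost <- if (strategy == "mri") d("cost_mri_guided_biopsy") else 0
  p_adverse <- if (strategy == "standard") d("p_adverse_standard")
    else d("p_adverse_mri_guided")
  dis_ae <- if (strategy == "standard") d("disutility_ae_standard_biopsy")
    else d("disutility_ae_mri_guided_biopsy")
  p_detect_given_bx <- if (strategy == "standard") d("sens_standard_biopsy")
    else if (opts$composition == "serial") d("sens_mri_guided_biopsy") else 1
  p_bx_h <- prof$p_b_h
  p_bx_d <- prof$p_b_d
  fp_rate_given_bx <- if (strategy == "standard")
    1 - d("spec_standard_biopsy") else 1 - d("spec_mri_guided_biopsy")

  init <- initial_distribution(stratum, draw)
  state <- sample.int(13, n, replace = TRUE, prob = init)
  cost <- numeric(n)
  util <- numeric(n)
  events <- matrix(0L, h, 6,
                   dimnames = list(NULL, c("biopsied", "adverse_event",
                                           "detected", "upgraded",
                                           "recurred", "died")))
  traj <- if (log) vector("list", h) else NULL

  undx_idx <- s[c("undx_low_nc", "undx_int_nc", "undx_high_nc",
                  "undx_low_c", "undx_int_c", "undx_high_c")]
  first_screen <- 1L

  for (t in seq_len(h)) {
    screening <- ((t - 1L) %% opts$screen_interval) == 0
    alive <- state != s["death"]
    screenable <- state %in% c(s["no_cancer"], undx_idx)
    diseased <- state %in% undx_idx

    # (1) cycle-start reward accrual (deterministic components)
    cost <- cost + f[t] * c0[state]
    util <- util + f[t] * u0[state]
    if (screening) {
      cost <- cost + f[t] * ifelse(screenable,
                                   ifelse(diseased, det_cost_d, det_cost_h), 0)
      util <- util + f[t] * ifelse(screenable, d("disutility_psa"), 0)
    }

    # (2) screening events: biopsy exposure and adverse events
    u_bx <- stats::runif(n)
    u_ae <- stats::runif(n)
    biopsied <- screening & screenable &
      u_bx < ifelse(diseased, p_bx_d, p_bx_h)
    cost <- cost + f[t] * biopsied * bx_extra_cost
    ae <- biopsied & u_ae < p_adverse
    charge_ae <- opts$ae_timing == "per_round" || t == first_screen
    if (charge_ae) util <- util + f[t] * ae * dis_ae

    # (3) background mortality
    q <- .mortality_q(draw, t - 1L, opts)
    u_death <- stats::runif(n)
    dies <- alive & u_death < q

    # (4) detection among surviving biopsied diseased men
    u_det <- stats::runif(n)
    u_fp <- stats::runif(n)
    detected <- !dies & diseased & biopsied & u_det < p_detect_given_bx
    fp_treated <- opts$fp_treated & !dies & biopsied &
      state == s["no_cancer"] & u_fp < fp_rate_given_bx

    # (5) progression among surviving undetected disease and deferred men
    u_up <- stats::runif(n)
    upgrade <- !dies & !detected & u_up < up &
      state %in% c(s["undx_low_nc"], s["undx_int_nc"], s["undx_low_c"],
                   s["undx_int_c"], s["deferred_low"], s["deferred_int"])

    # (6) treatment-year / post-treatment / recurrence moves
    u_rec <- stats::runif(n)
    recur <- !dies & state == s["post_treatment"] & u_rec < r
    if (opts$salvage_cost) cost <- cost + f[t] * recur * treat_cost

    nxt <- state
    # detection routing by grade and comorbidity
    nxt[detected & state %in% s[c("undx_low_nc", "undx_int_nc",
                                  "undx_high_nc", "undx_high_c")]] <-
      s["treat_year1"]
    nxt[detected & state == s["undx_low_c"]] <- s["deferred_low"]
    nxt[detected & state == s["undx_int_c"]] <- s["deferred_int"]
    nxt[fp_treated] <- s["treat_year1"]
    # upgrading
    nxt[upgrade & state == s["undx_low_nc"]] <- s["undx_int_nc"]
    nxt[upgrade & state == s["undx_int_nc"]] <- s["undx_high_nc"]
    nxt[upgrade & state == s["undx_low_c"]] <- s["undx_int_c"]
    nxt[upgrade & state == s["undx_int_c"]] <- s["undx_high_c"]
    nxt[upgrade & state == s["deferred_low"]] <- s["deferred_int"]
    nxt[upgrade & state == s["deferred_int"]] <- s["treat_year1"]
    # treatment pathway
    nxt[!dies & state == s["treat_year1"]] <- s["post_treatment"]
    nxt[recur] <- s["recurrence"]
    nxt[dies] <- s["death"]

    events[t, ] <- c(sum(biopsied), sum(ae), sum(detected), sum(upgrade),
                     sum(recur), sum(dies))
    if (log)
      traj[[t]] <- data.frame(cycle = t - 1L, state = pca_states()[state[1]],
                              biopsied = biopsied[1], adverse_event = ae[1],
                              detected = detected[1], upgraded = upgrade[1],
                              recurred = recur[1], died = dies[1],
                              cost_accrued = NA_real_,
                              utility_accrued = NA_real_,
                              stringsAsFactors = FALSE)
    state <- nxt
  }
  list(cost = unname(cost), util = unname(util), events = events,
       trajectory = if (log) do.call(rbind, traj) else NULL)
}

#' Simulate one patient trajectory
#'
#' Samples one individual history under the identical rules, event ordering
#' and reward schedule as the cohort engine.
#'
#' @param strategy \code{"standard"} or \code{"mri"}.
#' @param stratum One of \code{pca_strata()}.
#' @param draw Parameter draw.
#' @param seed Integer seed; the trajectory is fully determined by it.
#' @param opts Model options.
#' @return Object of class \code{patient_trajectory}: data frame of
#'   per-cycle states and events, with the discounted totals in attributes
#'   \code{"cost"} and \code{"qaly"}.
#' @export
simulate_patient <- function(strategy, stratum, draw, seed = 1L,
                             opts = pca_options()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- .msim(1L, strategy, stratum, draw, opts, log = TRUE)
  tr <- res$trajectory
  tr$cost_accrued <- NULL
  tr$utility_accrued <- NULL
  structure(tr, class = c("patient_trajectory", "data.frame"),
            cost = res$cost, qaly = res$util,
            strategy = strategy, stratum = stratum)
}

#' Simulate a cohort of independent patients
#'
#' Runs \code{n} independent patient trajectories and summarises mean
#' discounted cost and QALYs with Monte Carlo standard errors, plus
#' per-cycle event counts. Used to validate the cohort engine: the two are
#' implementations of one stochastic process and must agree within Monte
#' Carlo error.
#'
#' @param n Number of patients.
#' @param strategy \code{"standard"} or \code{"mri"}.
#' @param stratum One of \code{pca_strata()}.
#' @param draw Parameter draw.
#' @param seed Integer seed.
#' @param opts Model options.
#' @return Object of class \code{microsim_outcome}: list with \code{n},
#'   \code{mean_cost}, \code{mean_qaly}, \code{se_cost}, \code{se_qaly},
#'   and the per-cycle \code{events} matrix.
#' @export
simulate_cohort <- function(n, strategy, stratum, draw, seed = 1L,
                            opts = pca_options()) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- .msim(as.integer(n), strategy, stratum, draw, opts)
  sd_or_zero <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(n = as.integer(n),
                 mean_cost = mean(res$cost), mean_qaly = mean(res$util),
                 se_cost = sd_or_zero(res$cost) / sqrt(n),
                 se_qaly = sd_or_zero(res$util) / sqrt(n),
                 events = res$events,
                 strategy = strategy, stratum = stratum, seed = seed),
            class = "microsim_outcome")
}

#' @export
print.microsim_outcome <- function(x, ...) {
  cat(sprintf("Microsimulation (%d patients, %s strategy, PSA %s):\n",
              x$n, x$strategy, x$stratum))
  cat(sprintf("  cost  $%9.2f (SE %.2f)\n  QALYs %9.4f (SE %.4f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Validate the cohort engine against the microsimulation
#'
#' Compares expected discounted cost and QALYs from the deterministic cohort
#' engine with the empirical microsimulation means for every
#' strategy-by-stratum cell, reporting the z-score of each difference in
#' Monte Carlo standard errors.
#'
#' @param params A \code{pca_parameter_table}.
#' @param n Patients per cell.
#' @param seed Integer seed.
#' @param draw Parameter draw (base case by default).
#' @param strata Strata to validate.
#' @param opts Model options.
#' @return Data frame with one row per cell and the agreement z-scores.
#' @export
validate_engine <- function(params, n = 50000, seed = 1L,
                            draw = base_case_draw(params),
                            strata = pca_strata(), opts = pca_options()) {
  rows <- list()
  for (st in strata) for (sg in c("standard", "mri")) {
    eng <- evaluate_strategy(sg, st, draw, opts = opts)
    ms <- simulate_cohort(n, sg, st, draw,
                          seed = .draw_seed(seed, match(st, strata) * 2L +
                                              (sg == "mri")),
                          opts = opts)
    rows[[paste(st, sg)]] <- data.frame(
      stratum = st, strategy = sg,
      cost_engine = eng$expected_cost, cost_microsim = ms$mean_cost,
      se_cost = ms$se_cost,
      z_cost = (ms$mean_cost - eng$expected_cost) / ms$se_cost,
      qaly_engine = eng$expected_qaly, qaly_microsim = ms$mean_qaly,
      se_qaly = ms$se_qaly,
      z_qaly = (ms$mean_qaly - eng$expected_qaly) / ms$se_qaly,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
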