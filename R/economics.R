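# Per-state, per-cycle reward schedules and discounted aggregation.

#' Build the per-cycle reward schedule for a strategy
#'
#' Screening states (cancer-free and undiagnosed) accrue the strategy's
#' expected testing cost and disutility conditional on disease status, plus
#' the grade decrement for undiagnosed cancer. The treatment year costs the
#' treatment-mix average of prostatectomy, radiotherapy and brachytherapy
#' and carries the first-year treatment decrement; post-treatment years the
#' management cost and the later-year decrement; deferred treatment the
#' untreated-comorbid cost and the cancer-plus-comorbidity decrement;
#' recurrence the management cost and the recurrence decrement.
#'
#' @param strategy \code{"standard"} or \code{"mri"}.
#' @param draw Parameter draw.
#' @param horizon Number of annual cycles.
#' @param opts Model options; \code{ae_timing} decides whether the biopsy
#'   adverse-event disutility is charged at every screening round or only at
#'   the first.
#' @return Object of class \code{reward_schedule}: list with \code{cost} and
#'   \code{utility}, each a \code{horizon x 13} matrix over
#'   \code{pca_states()}.
#' @export
build_rewards <- function(strategy, draw,
                          horizon = draw[["horizon_years"]],
                          opts = pca_options()) {
  horizon <- as.integer(horizon)
  d <- function(nm) draw[[nm]]
  prof <- .screen_profile(strategy, draw, opts)
  states <- pca_states()
  u_base <- d("utility_healthy")

  treat_cost <- d("w_prostatectomy") * d("cost_prostatectomy") +
    d("w_radiotherapy") * d("cost_radiotherapy") +
    d("w_brachytherapy") * d("cost_brachytherapy")

  undx_states <- c("undx_low_nc", "undx_int_nc", "undx_high_nc",
                   "undx_low_c", "undx_int_c", "undx_high_c")
  grade_dec <- c(undx_low_nc = d("disutility_low_int_grade"),
                 undx_int_nc = d("disutility_low_int_grade"),
                 undx_high_nc = d("disutility_high_grade"),
                 undx_low_c = d("disutility_low_int_grade"),
                 undx_int_c = d("disutility_low_int_grade"),
                 undx_high_c = d("disutility_high_grade"))

  cost <- matrix(0, horizon, 13, dimnames = list(NULL, states))
  util <- matrix(0, horizon, 13, dimnames = list(NULL, states))

  screening_cycle <- ((seq_len(horizon) - 1L) %% opts$screen_interval) == 0
  first_screen <- which(screening_cycle)[1]

  for (t in seq_len(horizon)) {
    ct <- stats::setNames(numeric(13), states)
    ut <- stats::setNames(rep(u_base, 13), states)
    if (screening_cycle[t]) {
      ct["no_cancer"] <- prof$cost_h
      ct[undx_states] <- prof$cost_d
      ut["no_cancer"] <- ut["no_cancer"] + prof$psa_dis
      ut[undx_states] <- ut[undx_states] + prof$psa_dis
      if (opts$ae_timing == "per_round" || t == first_screen) {
        ut["no_cancer"] <- ut["no_cancer"] + prof$ae_h
        ut[undx_states] <- ut[undx_states] + prof$ae_d
      }
    }
    ut[undx_states] <- ut[undx_states] + grade_dec[undx_states]
    ct["treat_year1"] <- treat_cost
    ut["treat_year1"] <- u_base + d("disutility_treatment_year1")
    ct["post_treatment"] <- d("cost_post_treatment")
    ut["post_treatment"] <- u_base + d("disutility_treatment_later")
    ct[c("deferred_low", "deferred_int")] <- d("cost_untreated_comorbid")
    ut[c("deferred_low", "deferred_int")] <- u_base + d("disutility_comorbid_pca")
    ct["recurrence"] <- d("cost_post_treatment")
    ut["recurrence"] <- u_base + d("disutility_recurrence")
    ct["death"] <- 0
    ut["death"] <- 0
    cost[t, ] <- ct
    util[t, ] <- pmax(ut, 0) # guard against stacked sampled decrements
  }
  structure(list(cost = cost, utility = util, strategy = strategy,
                 horizon = horizon),
            class = "reward_schedule")
}

#' Discount factor for an annual cycle
#'
#' @param cycle_index Zero-based cycle index; cycle 0 is undiscounted.
#' @param rate Annual discount rate.
#' @return \code{(1 + rate)^(-cycle_index)}.
#' @export
discount_factor <- function(cycle_index, rate) {
  if (any(cycle_index < 0)) stop("cycle index must be non-negative")
  if (rate < 0) stop("discount rate must be non-negative")
  (1 + rate)^(-cycle_index)
}

#' Aggregate a cohort trace into discounted cost and QALYs
#'
#' Values each cycle's rewards on the cycle-start occupancy (or on the
#' average of cycle-start and cycle-end occupancy when the half-cycle
#' correction is enabled) and sums with annual discounting.
#'
#' @param trace A \code{cohort_trace}.
#' @param rewards A \code{reward_schedule} for the same strategy/horizon.
#' @param rate Annual discount rate.
#' @param opts Model options.
#' @return Object of class \code{strategy_outcome}: discounted and
#'   undiscounted expected cost and QALYs plus the per-cycle breakdown.
#' @export
accumulate <- function(trace, rewards, rate, opts = pca_options()) {
  h <- trace$horizon
  if (rewards$horizon != h) stop("trace and rewards horizons differ")
  occ <- if (opts$half_cycle)
    0.5 * (trace$occupancy[1:h, , drop = FALSE] +
             trace$occupancy[2:(h + 1), , drop = FALSE])
  else trace$occupancy[1:h, , drop = FALSE]
  f <- discount_factor(0:(h - 1), rate)
  cyc_cost <- rowSums(occ * rewards$cost)
  cyc_util <- rowSums(occ * rewards$utility)
  structure(list(expected_cost = sum(f * cyc_cost),
                 expected_qaly = sum(f * cyc_util),
                 undiscounted_cost = sum(cyc_cost),
                 undiscounted_qaly = sum(cyc_util),
                 per_cycle = data.frame(cycle = 0:(h - 1), factor = f,
                                        cost = cyc_cost, utility = cyc_util),
                 strategy = trace$strategy, stratum = trace$stratum),
            class = "strategy_outcome")
}

#' Evaluate one strategy for one stratum and draw
#'
#' Convenience wrapper running the cohort trace, building rewards and
#' aggregating with the draw's discount rate.
#'
#' @inheritParams run_cohort
#' @return A \code{strategy_outcome}.
#' @export
evaluate_strategy <- function(strategy, stratum, draw,
                              horizon = draw[["horizon_years"]],
                              opts = pca_options()) {
  trace <- run_cohort(strategy, stratum, draw, horizon, opts)
  rew <- build_rewards(strategy, draw, horizon, opts)
  out <- accumulate(trace, rew, draw[["discount_rate"]], opts)
  if (opts$salvage_cost) {
    # one-time average treatment cost on each entry into recurrence
    d <- function(nm) draw[[nm]]
    treat_cost <- d("w_prostatectomy") * d("cost_prostatectomy") +
      d("w_radiotherapy") * d("cost_radiotherapy") +
      d("w_brachytherapy") * d("cost_brachytherapy")
    h <- trace$horizon
    r <- draw[[.stratum_params(stratum)$recurrence]]
    q <- vapply(0:(h - 1), function(t) .mortality_q(draw, t, opts), numeric(1))
    entries <- (1 - q) * trace$occupancy[1:h, "post_treatment"] * r
    f <- discount_factor(0:(h - 1), draw[["discount_rate"]])
    extra <- sum(f * entries * treat_cost)
    out$expected_cost <- out$expected_cost + extra
    out$undiscounted_cost <- out$undiscounted_cost + sum(entries) * treat_cost
  }
  out
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("%s strategy, PSA stratum %s: cost $%.2f, QALYs %.4f (discounted)\n",
              x$strategy, x$stratum, x$expected_cost, x$expected_qaly))
  invisible(x)
}
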