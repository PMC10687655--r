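# Markov cohort engine: 13 health states, annual cycles, one matrix per
# cycle (age-dependent mortality composed with a strategy-specific
# screening/progression kernel).

#' Health states of the cohort model
#'
#' Thirteen states: cancer-free; undiagnosed cancer by grade
#' (low/intermediate/high) and comorbidity status; the treatment year;
#' post-treatment; deferred treatment (diagnosed low/intermediate-grade
#' disease with comorbidities); recurrence; death.
#'
#' @return Character vector of state names in canonical order.
#' @export
pca_states <- function() {
  c("no_cancer",
    "undx_low_nc", "undx_int_nc", "undx_high_nc",
    "undx_low_c",  "undx_int_c",  "undx_high_c",
    "treat_year1", "post_treatment",
    "deferred_low", "deferred_int",
    "recurrence", "death")
}

.S <- function() stats::setNames(seq_along(pca_states()), pca_states())

#' Initial state distribution for a PSA stratum
#'
#' Cancer-free mass is one minus the stratum's prevalence; prevalent cancers
#' are spread over the six undiagnosed grade-by-comorbidity states in the
#' proportions of the (renormalised) joint grade distribution.
#'
#' @param stratum One of \code{pca_strata()}.
#' @param draw Parameter draw.
#' @return Named numeric vector over \code{pca_states()} summing to one.
#' @export
initial_distribution <- function(stratum, draw) {
  sp <- .stratum_params(stratum)
  p <- draw[[sp$prevalence]]
  g <- draw[.pca_grade_names]
  g <- g / sum(g)
  v <- stats::setNames(numeric(13), pca_states())
  v["no_cancer"]    <- 1 - p
  v["undx_high_nc"] <- p * g[["p_grade_high_nc"]]
  v["undx_high_c"]  <- p * g[["p_grade_high_c"]]
  v["undx_int_nc"]  <- p * g[["p_grade_int_nc"]]
  v["undx_int_c"]   <- p * g[["p_grade_int_c"]]
  v["undx_low_nc"]  <- p * g[["p_grade_low_nc"]]
  v["undx_low_c"]   <- p * g[["p_grade_low_c"]]
  v
}

# Survival-conditional transition kernel (no mortality). Rows encode, in
# order of application within a cycle: the screening round (detection,
# transient or treated false positives), then grade progression among
# undetected and deferred disease, then the treatment-year/post-treatment/
# recurrence moves.
.cohort_kernel <- function(strategy, stratum, draw, opts, screening = TRUE) {
  s <- .S()
  K <- matrix(0, 13, 13, dimnames = list(pca_states(), pca_states()))
  prof <- .screen_profile(strategy, draw, opts)
  s_det <- if (screening) prof$s_det else 0
  fp <- if (screening) prof$fp else 0
  up <- draw[["p_upgrade"]]
  r <- draw[[.stratum_params(stratum)$recurrence]]

  # cancer-free: false positives are transient by default
  if (opts$fp_treated) {
    K["no_cancer", "treat_year1"] <- fp
    K["no_cancer", "no_cancer"] <- 1 - fp
  } else {
    K["no_cancer", "no_cancer"] <- 1
  }

  # undiagnosed disease: detection routes by grade and comorbidity, the
  # undetected remainder may upgrade one grade
  undx <- function(state, detect_to, stay, upgrade_to = NULL) {
    K[state, detect_to] <<- K[state, detect_to] + s_det
    if (is.null(upgrade_to)) {
      K[state, stay] <<- K[state, stay] + (1 - s_det)
    } else {
      K[state, upgrade_to] <<- K[state, upgrade_to] + (1 - s_det) * up
      K[state, stay] <<- K[state, stay] + (1 - s_det) * (1 - up)
    }
  }
  undx("undx_low_nc",  "treat_year1",  "undx_low_nc",  "undx_int_nc")
  undx("undx_int_nc",  "treat_year1",  "undx_int_nc",  "undx_high_nc")
  undx("undx_high_nc", "treat_year1",  "undx_high_nc")
  undx("undx_low_c",   "deferred_low", "undx_low_c",   "undx_int_c")
  undx("undx_int_c",   "deferred_int", "undx_int_c",   "undx_high_c")
  undx("undx_high_c",  "treat_year1",  "undx_high_c")

  # deferred disease upgrades regardless of screening; reaching high grade
  # triggers treatment
  K["deferred_low", "deferred_int"] <- up
  K["deferred_low", "deferred_low"] <- 1 - up
  K["deferred_int", "treat_year1"] <- up
  K["deferred_int", "deferred_int"] <- 1 - up

  K["treat_year1", "post_treatment"] <- 1
  K["post_treatment", "recurrence"] <- r
  K["post_treatment", "post_treatment"] <- 1 - r
  K["recurrence", "recurrence"] <- 1
  K["death", "death"] <- 1
  K
}

#' Per-cycle transition matrix
#'
#' Composes age-dependent background mortality with the survival-conditional
#' screening/progression kernel: every living state moves to death with the
#' cycle's all-cause death probability and follows the kernel otherwise.
#'
#' @param strategy \code{"standard"} or \code{"mri"}.
#' @param stratum One of \code{pca_strata()}.
#' @param draw Parameter draw.
#' @param cycle_index Zero-based cycle index; sets the attained age for
#'   mortality and whether the cycle is a screening round.
#' @param opts Model options.
#' @return A 13 x 13 row-stochastic matrix.
#' @export
build_transition_matrix <- function(strategy, stratum, draw, cycle_index,
                                    opts = pca_options()) {
  stopifnot(cycle_index >= 0)
  screening <- (cycle_index %% opts$screen_interval) == 0
  K <- .cohort_kernel(strategy, stratum, draw, opts, screening = screening)
  q <- .mortality_q(draw, cycle_index, opts)
  M <- (1 - q) * K
  M[, "death"] <- M[, "death"] + q
  M["death", ] <- 0
  M["death", "death"] <- 1
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12) || any(M < -1e-15))
    stop("internal consistency error: transition rows must sum to 1 ",
         "(max deviation ", format(max(abs(rs - 1))), ")")
  M
}

#' Run the cohort trace
#'
#' Evolves the initial state distribution through \code{horizon} annual
#' cycles. Occupancy is recorded at every cycle start (plus the final
#' end-of-horizon distribution); rewards are valued by
#' \code{\link{accumulate}}.
#'
#' @param strategy \code{"standard"} or \code{"mri"}.
#' @param stratum One of \code{pca_strata()}.
#' @param draw Parameter draw.
#' @param horizon Number of annual cycles; defaults to the draw's
#'   \code{horizon_years} setting.
#' @param opts Model options.
#' @return Object of class \code{cohort_trace}: list with \code{occupancy}
#'   (a \code{(horizon + 1) x 13} matrix whose first \code{horizon} rows are
#'   the cycle-start distributions), \code{strategy}, \code{stratum},
#'   \code{horizon}.
#' @export
run_cohort <- function(strategy, stratum, draw,
                       horizon = draw[["horizon_years"]],
                       opts = pca_options()) {
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1)
  occ <- matrix(0, horizon + 1, 13,
                dimnames = list(NULL, pca_states()))
  occ[1, ] <- initial_distribution(stratum, draw)

  # mortality enters only as a per-cycle scalar, so the survival-conditional
  # kernel is built once per distinct screening pattern and rescaled
  K_screen <- .cohort_kernel(strategy, stratum, draw, opts, screening = TRUE)
  K_skip <- if (opts$screen_interval > 1)
    .cohort_kernel(strategy, stratum, draw, opts, screening = FALSE)
  else K_screen

  for (t in seq_len(horizon)) {
    K <- if (((t - 1L) %% opts$screen_interval) == 0) K_screen else K_skip
    q <- .mortality_q(draw, t - 1L, opts)
    live <- occ[t, -13]
    nxt <- (1 - q) * as.numeric(live %*% K[-13, , drop = FALSE])
    nxt[13] <- nxt[13] + q * sum(live) + occ[t, 13]
    occ[t + 1, ] <- nxt
  }
  if (any(abs(rowSums(occ) - 1) > 1e-10))
    stop("occupancy conservation violated")
  structure(list(occupancy = occ, strategy = strategy, stratum = stratum,
                 horizon = horizon),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, digits = 4, ...) {
  cat("Cohort trace:", x$strategy, "strategy, PSA stratum", x$stratum,
      "-", x$horizon, "annual cycles\n")
  print(round(x$occupancy, digits))
  invisible(x)
}
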