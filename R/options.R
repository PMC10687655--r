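#' Structural model options
#'
#' Collects the structural conventions of the cohort model that are not
#' pinned down by the published inputs. Each has a default chosen and
#' justified in the methods vignette; all are switchable so the consequences
#' of the reconstruction choices can be audited.
#'
#' @param ae_timing When the biopsy adverse-event disutility is charged:
#'   \code{"first_round"} (default) charges the expected event decrement
#'   once, at the first screening round; \code{"per_round"} charges it at
#'   every screening round. The default is the convention consistent with
#'   the published incremental results in the near-disease-free stratum;
#'   see the methods vignette.
#' @param fp_treated If \code{TRUE}, a false-positive screening result sends
#'   a cancer-free man to treatment (overtreatment variant). Default
#'   \code{FALSE}: false positives are transient, incurring that round's
#'   testing cost and adverse-event disutility only.
#' @param salvage_cost If \code{TRUE}, entering the recurrence state incurs a
#'   one-time salvage-treatment cost equal to the average treatment cost.
#'   Default \code{FALSE}: recurrence accrues only annual management cost.
#' @param half_cycle If \code{TRUE}, rewards are valued on the average of
#'   cycle-start and cycle-end occupancy (half-cycle correction). Default
#'   \code{FALSE}: rewards on cycle-start occupancy.
#' @param composition How MRI and MRI-guided biopsy sensitivities combine
#'   into the MRI pathway's detection probability: \code{"serial"}
#'   (independent errors, product of sensitivities) or \code{"mri_only"}
#'   (detection gated by the MRI alone, the guided biopsy confirming).
#' @param screen_interval Years between screening rounds (1 = annual).
#' @param mortality Background-mortality table (data frame with columns
#'   \code{age}, \code{annual_death_probability}); \code{NULL} loads the
#'   bundled US-male table for ages 65-74.
#' @return A list of class \code{pca_options}.
#' @export
pca_options <- function(ae_timing = c("first_round", "per_round"),
                        fp_treated = FALSE,
                        salvage_cost = FALSE,
                        half_cycle = FALSE,
                        composition = c("serial", "mri_only"),
                        screen_interval = 1L,
                        mortality = NULL) {
  ae_timing <- match.arg(ae_timing)
  composition <- match.arg(composition)
  stopifnot(is.logical(fp_treated), is.logical(salvage_cost),
            is.logical(half_cycle), screen_interval >= 1)
  if (is.null(mortality)) mortality <- load_mortality()
  structure(list(ae_timing = ae_timing, fp_treated = fp_treated,
                 salvage_cost = salvage_cost, half_cycle = half_cycle,
                 composition = composition,
                 screen_interval = as.integer(screen_interval),
                 mortality = mortality),
            class = "pca_options")
}

#' PSA strata recognised by the model
#'
#' @return Character vector of the four serum PSA stratum identifiers.
#' @export
pca_strata <- function() c("lt2.5", "2.5-4.0", "4.1-10.0", "gt10")

# Map a stratum id to its prevalence and recurrence parameter names.
.stratum_params <- function(stratum) {
  suffix <- switch(stratum,
                   "lt2.5"    = "psa_lt25",
                   "2.5-4.0"  = "psa_25_40",
                   "4.1-10.0" = "psa_41_100",
                   "gt10"     = "psa_gt10",
                   stop("unknown PSA stratum '", stratum, "'; expected one of ",
                        paste(pca_strata(), collapse = ", ")))
  list(prevalence = paste0("p_cancer_", suffix),
       recurrence = paste0("p_recurrence_", suffix))
}

# Annual death probability at a given cycle for the entry age in the draw.
.mortality_q <- function(draw, cycle_index, opts) {
  age <- draw[["entry_age"]] + cycle_index
  m <- opts$mortality
  i <- match(age, m$age)
  if (is.na(i)) {
    # beyond the table: hold the last available probability
    i <- if (age > max(m$age)) nrow(m) else 1L
  }
  m$annual_death_probability[i]
}
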