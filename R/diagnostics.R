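# Expected outcomes of one annual screening round, conditional on disease
# status and marginally over a given prevalence.

# Strategy-specific screening profile conditional on disease status.
# Returns detection probability for diseased men, biopsy exposure for
# healthy/diseased men, the healthy false-positive probability, and the
# expected testing cost and disutility for each status.  The adverse-event
# disutility component is returned separately so the reward builder can
# apply the configured charging convention.
.screen_profile <- function(strategy, draw, opts) {
  d <- function(nm) draw[[nm]]
  if (strategy == "standard") {
    s_det <- d("sens_standard_biopsy")
    p_b_h <- 1
    p_b_d <- 1
    fp    <- 1 - d("spec_standard_biopsy")
    cost_h <- cost_d <- d("cost_psa") + d("cost_standard_biopsy")
    ae_h <- ae_d <- d("p_adverse_standard") * d("disutility_ae_standard_biopsy")
  } else if (strategy == "mri") {
    p_b_h <- 1 - d("spec_mri")
    p_b_d <- d("sens_mri")
    s_det <- if (opts$composition == "serial")
      d("sens_mri") * d("sens_mri_guided_biopsy") else d("sens_mri")
    fp <- (1 - d("spec_mri")) * (1 - d("spec_mri_guided_biopsy"))
    cost_h <- d("cost_psa") + d("cost_mri") + p_b_h * d("cost_mri_guided_biopsy")
    cost_d <- d("cost_psa") + d("cost_mri") + p_b_d * d("cost_mri_guided_biopsy")
    ae_h <- p_b_h * d("p_adverse_mri_guided") * d("disutility_ae_mri_guided_biopsy")
    ae_d <- p_b_d * d("p_adverse_mri_guided") * d("disutility_ae_mri_guided_biopsy")
  } else stop("unknown strategy '", strategy, "'")
  list(s_det = s_det, p_b_h = p_b_h, p_b_d = p_b_d, fp = fp,
       cost_h = cost_h, cost_d = cost_d,
       ae_h = ae_h, ae_d = ae_d, psa_dis = draw[["disutility_psa"]])
}

.screening_outcome <- function(p_tp, p_fn, p_fp, p_tn, p_biopsied,
                               cost, disutility) {
  structure(list(p_true_positive = p_tp, p_false_negative = p_fn,
                 p_false_positive = p_fp, p_true_negative = p_tn,
                 p_biopsied = p_biopsied,
                 expected_test_cost = cost,
                 expected_test_disutility = disutility),
            class = "screening_outcome")
}

.check_prob <- function(...) {
  v <- c(...)
  if (any(!is.finite(v) | v < 0 | v > 1))
    stop("probabilities must lie in [0, 1]")
}

#' Expected outcomes of one standard-biopsy screening round
#'
#' Every screened man receives a PSA test and a standard (TRUS-guided)
#' biopsy; classification follows the biopsy's sensitivity and specificity.
#'
#' @param prevalence Disease prevalence among the screened.
#' @param sens_bx,spec_bx Standard-biopsy sensitivity and specificity.
#' @param draw Parameter draw supplying costs, adverse-event probability and
#'   disutilities.
#' @param opts Model options (see \code{\link{pca_options}}).
#' @return A \code{screening_outcome}: the four classification
#'   probabilities, the biopsied fraction, and the expected testing cost and
#'   disutility per screened man.
#' @export
standard_pathway <- function(prevalence,
                             sens_bx = draw[["sens_standard_biopsy"]],
                             spec_bx = draw[["spec_standard_biopsy"]],
                             draw, opts = pca_options()) {
  .check_prob(prevalence, sens_bx, spec_bx)
  p_tp <- prevalence * sens_bx
  p_fn <- prevalence * (1 - sens_bx)
  p_fp <- (1 - prevalence) * (1 - spec_bx)
  p_tn <- (1 - prevalence) * spec_bx
  cost <- draw[["cost_psa"]] + draw[["cost_standard_biopsy"]]
  dis <- draw[["disutility_psa"]] +
    draw[["p_adverse_standard"]] * draw[["disutility_ae_standard_biopsy"]]
  .screening_outcome(p_tp, p_fn, p_fp, p_tn, 1, cost, dis)
}

#' Expected outcomes of one MRI-first screening round
#'
#' Every screened man receives a PSA test and an MRI; only men with a
#' positive MRI receive an MRI-guided biopsy, so the biopsied fraction is
#' below one whenever the MRI has non-zero specificity. Detection requires a
#' positive MRI followed by a positive MRI-guided biopsy (independent serial
#' errors by default).
#'
#' @param prevalence Disease prevalence among the screened.
#' @param sens_mri,spec_mri MRI sensitivity and specificity.
#' @param sens_bx,spec_bx MRI-guided-biopsy sensitivity and specificity.
#' @param draw Parameter draw supplying costs, adverse-event probability and
#'   disutilities.
#' @param opts Model options.
#' @return A \code{screening_outcome}.
#' @export
mri_pathway <- function(prevalence,
                        sens_mri = draw[["sens_mri"]],
                        spec_mri = draw[["spec_mri"]],
                        sens_bx = draw[["sens_mri_guided_biopsy"]],
                        spec_bx = draw[["spec_mri_guided_biopsy"]],
                        draw, opts = pca_options()) {
  .check_prob(prevalence, sens_mri, spec_mri, sens_bx, spec_bx)
  s_path <- if (opts$composition == "serial") sens_mri * sens_bx else sens_mri
  p_tp <- prevalence * s_path
  p_fn <- prevalence * (1 - s_path)
  p_fp <- (1 - prevalence) * (1 - spec_mri) * (1 - spec_bx)
  p_tn <- (1 - prevalence) * (1 - (1 - spec_mri) * (1 - spec_bx))
  p_biopsied <- prevalence * sens_mri + (1 - prevalence) * (1 - spec_mri)
  cost <- draw[["cost_psa"]] + draw[["cost_mri"]] +
    p_biopsied * draw[["cost_mri_guided_biopsy"]]
  dis <- draw[["disutility_psa"]] +
    p_biopsied * draw[["p_adverse_mri_guided"]] *
      draw[["disutility_ae_mri_guided_biopsy"]]
  .screening_outcome(p_tp, p_fn, p_fp, p_tn, p_biopsied, cost, dis)
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat("One screening round (expected, per screened man):\n")
  cat(sprintf("  TP %.4f  FN %.4f  FP %.4f  TN %.4f\n",
              x$p_true_positive, x$p_false_negative,
              x$p_false_positive, x$p_true_negative))
  cat(sprintf("  biopsied fraction %.4f; test cost $%.2f; test disutility %.5f\n",
              x$p_biopsied, x$expected_test_cost, x$expected_test_disutility))
  invisible(x)
}
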