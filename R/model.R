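# User-facing front end: one call evaluating the base case for all strata,
# returning a classed object with print/summary/plot/simulate methods.

#' Fit the base-case cost-effectiveness model
#'
#' Evaluates the 10-year Markov cohort model for both screening strategies
#' (annual standard biopsy; annual MRI with potential MRI-guided biopsy) in
#' each requested PSA stratum at the base-case parameter values, and forms
#' the incremental comparison per stratum.
#'
#' @param params A \code{pca_parameter_table}; defaults to the bundled
#'   configuration.
#' @param strata PSA strata to evaluate (default all four).
#' @param opts Model options, see \code{\link{pca_options}}.
#' @param draw Optional parameter draw to evaluate instead of the base case.
#' @return Object of class \code{pca_cea}: list with \code{outcomes} (one
#'   row per strategy and stratum with discounted cost and QALYs),
#'   \code{comparisons} (one row per stratum with incremental cost and
#'   QALYs and the ICER), the \code{params}, \code{opts} and \code{draw}
#'   used.
#' @examples
#' fit <- pca_cea()
#' print(fit)
#' @export
pca_cea <- function(params = load_parameter_table(),
                    strata = pca_strata(),
                    opts = pca_options(),
                    draw = base_case_draw(params)) {
  strata <- match.arg(strata, pca_strata(), several.ok = TRUE)
  outcomes <- list()
  comparisons <- list()
  for (st in strata) {
    std <- evaluate_strategy("standard", st, draw, opts = opts)
    mri <- evaluate_strategy("mri", st, draw, opts = opts)
    cmp <- icer(std, mri)
    outcomes[[paste(st, "standard")]] <-
      data.frame(stratum = st, strategy = "standard",
                 cost = std$expected_cost, qaly = std$expected_qaly,
                 undiscounted_cost = std$undiscounted_cost,
                 undiscounted_qaly = std$undiscounted_qaly,
                 stringsAsFactors = FALSE)
    outcomes[[paste(st, "mri")]] <-
      data.frame(stratum = st, strategy = "mri",
                 cost = mri$expected_cost, qaly = mri$expected_qaly,
                 undiscounted_cost = mri$undiscounted_cost,
                 undiscounted_qaly = mri$undiscounted_qaly,
                 stringsAsFactors = FALSE)
    comparisons[[st]] <-
      data.frame(stratum = st,
                 incremental_cost = cmp$incremental_cost,
                 incremental_qaly = cmp$incremental_qaly,
                 icer = cmp$icer, label = cmp$label,
                 stringsAsFactors = FALSE)
  }
  structure(list(outcomes = do.call(rbind, c(outcomes, make.row.names = FALSE)),
                 comparisons = do.call(rbind, c(comparisons,
                                                make.row.names = FALSE)),
                 params = params, opts = opts, draw = draw,
                 wtp = draw[["wtp_threshold"]]),
            class = "pca_cea")
}

#' @export
print.pca_cea <- function(x, ...) {
  cat("Cost-effectiveness of annual MRI + potential MRI-guided biopsy",
      "versus annual standard biopsy\n")
  cat(sprintf("(10-year Markov cohort, entry age %d, %.0f%% discount rate)\n\n",
              as.integer(x$draw[["entry_age"]]),
              100 * x$draw[["discount_rate"]]))
  for (st in unique(x$outcomes$stratum)) {
    o <- x$outcomes[x$outcomes$stratum == st, ]
    cmp <- x$comparisons[x$comparisons$stratum == st, ]
    cat("PSA stratum ", st, " (ng/mL)\n", sep = "")
    for (i in seq_len(nrow(o)))
      cat(sprintf("  %-9s cost $%8.0f   QALYs %6.3f\n",
                  o$strategy[i], o$cost[i], o$qaly[i]))
    lab <- if (cmp$label == "icer")
      sprintf("ICER $%.0f/QALY", cmp$icer) else cmp$label
    cat(sprintf("  increment cost $%8.0f   QALYs %6.3f   %s\n\n",
                cmp$incremental_cost, cmp$incremental_qaly, lab))
  }
  invisible(x)
}

#' @export
summary.pca_cea <- function(object, ...) {
  wtp <- object$wtp
  ce <- with(object$comparisons,
             label == "dominant" |
               (label == "icer" & incremental_qaly > 0 & icer < wtp))
  s <- object$comparisons
  s$cost_effective_at_wtp <- ce
  structure(list(comparisons = s, wtp = wtp,
                 outcomes = object$outcomes), class = "summary.pca_cea")
}

#' @export
print.summary.pca_cea <- function(x, ...) {
  cat("Incremental results (MRI strategy vs standard), WTP $",
      format(x$wtp, big.mark = ","), "/QALY\n", sep = "")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness plane for a fitted base case
#'
#' Plots each stratum's incremental QALYs against incremental cost with the
#' willingness-to-pay threshold as a reference line.
#'
#' @param x A \code{pca_cea}.
#' @param ... Further graphical arguments.
#' @export
plot.pca_cea <- function(x, ...) {
  cmp <- x$comparisons
  graphics::plot(cmp$incremental_qaly, cmp$incremental_cost,
                 pch = 19, col = seq_len(nrow(cmp)),
                 xlab = "Incremental QALYs",
                 ylab = "Incremental cost ($)", ...)
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::legend("topleft", legend = paste("PSA", cmp$stratum),
                   col = seq_len(nrow(cmp)), pch = 19, bty = "n")
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' \code{simulate} on a fitted base case runs the Monte Carlo probabilistic
#' sensitivity analysis: \code{nsim} parameter draws propagated through the
#' cohort engine for both strategies and all fitted strata.
#'
#' @param object A \code{pca_cea}.
#' @param nsim Number of parameter draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A \code{pca_psa} result set (see \code{\link{run_psa}}).
#' @export
simulate.pca_cea <- function(object, nsim = 10000, seed = 1L, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed,
          strata = unique(object$outcomes$stratum), opts = object$opts)
}
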