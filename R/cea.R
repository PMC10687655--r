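# Incremental cost-effectiveness statistics.

#' Incremental cost-effectiveness ratio
#'
#' Increments are alternative minus reference. The ICER is reported only
#' when the incremental QALY is non-zero; an alternative that is cheaper and
#' more effective is labelled \code{"dominant"}, one that is costlier and
#' less effective \code{"dominated"}.
#'
#' @param reference,alternative \code{strategy_outcome}s computed on the
#'   same stratum and draw, or lists with \code{expected_cost} and
#'   \code{expected_qaly}.
#' @return Object of class \code{cea_comparison} with
#'   \code{incremental_cost}, \code{incremental_qaly}, \code{icer} (numeric
#'   or \code{NA}) and \code{label}.
#' @export
icer <- function(reference, alternative) {
  dc <- alternative$expected_cost - reference$expected_cost
  dq <- alternative$expected_qaly - reference$expected_qaly
  if (dq == 0) {
    label <- if (dc == 0) "equivalent" else "undefined"
    ratio <- NA_real_
  } else if (dc < 0 && dq > 0) {
    label <- "dominant"
    ratio <- dc / dq
  } else if (dc > 0 && dq < 0) {
    label <- "dominated"
    ratio <- dc / dq
  } else {
    label <- "icer"
    ratio <- dc / dq
  }
  structure(list(incremental_cost = dc, incremental_qaly = dq,
                 icer = ratio, label = label,
                 reference_name = reference$strategy,
                 alternative_name = alternative$strategy),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: incremental cost $%.2f, incremental QALY %.5f; ",
              if (is.null(x$alternative_name)) "alternative" else x$alternative_name,
              if (is.null(x$reference_name)) "reference" else x$reference_name,
              x$incremental_cost, x$incremental_qaly))
  if (x$label == "icer") cat(sprintf("ICER $%.0f/QALY\n", x$icer))
  else cat(x$label, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' @param outcome A \code{strategy_outcome} (or list with
#'   \code{expected_cost} and \code{expected_qaly}).
#' @param wtp Willingness-to-pay threshold in dollars per QALY.
#' @return \code{wtp * expected_qaly - expected_cost}.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be non-negative")
  wtp * outcome$expected_qaly - outcome$expected_cost
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value and PSA stratum, the fraction of
#' probabilistic draws in which the MRI strategy's net monetary benefit
#' strictly exceeds the standard strategy's (ties count as not
#' cost-effective).
#'
#' @param psa_result A \code{pca_psa} result set from \code{\link{run_psa}}.
#' @param wtp_grid Willingness-to-pay grid in dollars per QALY.
#' @return Object of class \code{pca_ceac}: data frame with columns
#'   \code{wtp}, \code{stratum}, \code{probability_cost_effective},
#'   \code{n_draws}.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa_result, "pca_psa"))
  n <- psa_result$n_draws
  if (n < 1) stop("empty probabilistic result set")
  strata <- dimnames(psa_result$cost)[[3]]
  rows <- lapply(strata, function(st) {
    dc <- psa_result$cost[, "mri", st] - psa_result$cost[, "standard", st]
    dq <- psa_result$qaly[, "mri", st] - psa_result$qaly[, "standard", st]
    p <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
    data.frame(wtp = wtp_grid, stratum = st,
               probability_cost_effective = p, n_draws = n,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("pca_ceac", "data.frame"))
}

#' Plot cost-effectiveness acceptability curves
#'
#' One line per PSA stratum: probability that the MRI strategy is
#' cost-effective against willingness-to-pay.
#'
#' @param x A \code{pca_ceac}.
#' @param ... Further arguments passed to \code{matplot}.
#' @export
plot.pca_ceac <- function(x, ...) {
  strata <- unique(x$stratum)
  wtp <- sort(unique(x$wtp))
  m <- sapply(strata, function(st)
    x$probability_cost_effective[x$stratum == st][order(x$wtp[x$stratum == st])])
  if (length(wtp) == 1) {
    graphics::plot(rep(wtp, length(strata)), as.numeric(m), pch = 19,
                   xlab = "Willingness to pay ($/QALY)",
                   ylab = "P(MRI strategy cost-effective)", ylim = c(0, 1), ...)
  } else {
    graphics::matplot(wtp, m, type = "l", lty = 1, lwd = 2,
                      col = seq_along(strata),
                      xlab = "Willingness to pay ($/QALY)",
                      ylab = "P(MRI strategy cost-effective)", ylim = c(0, 1),
                      ...)
  }
  graphics::legend("bottomright", legend = paste("PSA", strata),
                   col = seq_along(strata), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
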