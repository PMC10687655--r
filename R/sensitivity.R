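# Probabilistic sensitivity analysis, one-way sweeps and tornado diagrams.

#' Run the probabilistic sensitivity analysis
#'
#' Samples \code{n_draws} complete parameter draws from the fitted
#' distributions and evaluates both strategies for every requested stratum
#' on each draw (common random parameters across strategies). Fully
#' reproducible from \code{seed}.
#'
#' @param params A \code{pca_parameter_table}.
#' @param n_draws Number of Monte Carlo draws (the full published analysis
#'   uses 10,000).
#' @param seed Integer seed.
#' @param strata Strata to evaluate.
#' @param opts Model options.
#' @return Object of class \code{pca_psa}: arrays \code{cost} and
#'   \code{qaly} with dimensions (draw, strategy, stratum), the draw matrix
#'   \code{draws}, \code{n_draws} and \code{seed}.
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1L,
                    strata = pca_strata(), opts = pca_options()) {
  stopifnot(n_draws >= 1)
  strategies <- c("standard", "mri")
  cost <- array(NA_real_, c(n_draws, 2, length(strata)),
                dimnames = list(NULL, strategies, strata))
  qaly <- cost
  draws <- matrix(NA_real_, n_draws, nrow(params),
                  dimnames = list(NULL, params$name))
  for (i in seq_len(n_draws)) {
    dr <- sample_draw(params, seed, i)
    draws[i, ] <- as.numeric(dr)
    for (st in strata) {
      for (sg in strategies) {
        out <- tryCatch(evaluate_strategy(sg, st, dr, opts = opts),
                        error = function(e)
                          stop("draw ", i, " (", sg, ", ", st, "): ",
                               conditionMessage(e)))
        cost[i, sg, st] <- out$expected_cost
        qaly[i, sg, st] <- out$expected_qaly
      }
    }
  }
  structure(list(cost = cost, qaly = qaly, draws = draws,
                 n_draws = n_draws, seed = seed, strata = strata),
            class = "pca_psa")
}

#' @export
print.pca_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      x$seed, ")\n")
  wtp <- 100000
  for (st in x$strata) {
    dc <- x$cost[, "mri", st] - x$cost[, "standard", st]
    dq <- x$qaly[, "mri", st] - x$qaly[, "standard", st]
    p <- mean(wtp * dq - dc > 0)
    cat(sprintf("  PSA %-8s mean inc. cost $%7.0f, mean inc. QALY %7.4f, P(CE at $100k) %.3f\n",
                st, mean(dc), mean(dq), p))
  }
  invisible(x)
}

#' Draw-wise percentile summary of a probabilistic analysis
#'
#' @param object A \code{pca_psa}.
#' @param probs Quantile probabilities.
#' @param ... Unused.
#' @return Data frame of percentile intervals for incremental cost and
#'   QALYs per stratum.
#' @export
summary.pca_psa <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  do.call(rbind, lapply(object$strata, function(st) {
    dc <- object$cost[, "mri", st] - object$cost[, "standard", st]
    dq <- object$qaly[, "mri", st] - object$qaly[, "standard", st]
    data.frame(stratum = st,
               stat = c(paste0("inc_cost_q", probs), paste0("inc_qaly_q", probs)),
               value = c(stats::quantile(dc, probs), stats::quantile(dq, probs)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' One-way deterministic sensitivity sweep
#'
#' Re-evaluates the base case with a single parameter varied over a grid,
#' all other parameters held at their base values, reporting incremental
#' cost, incremental QALYs and the ICER per stratum at every grid point.
#'
#' @param params A \code{pca_parameter_table}.
#' @param parameter Name of the parameter to sweep.
#' @param grid Numeric grid of values; defaults to 50 equally spaced points
#'   across the parameter's published interval.
#' @param strata Strata to evaluate.
#' @param opts Model options.
#' @return Object of class \code{pca_sweep}: data frame with one row per
#'   (grid value, stratum).
#' @export
one_way_sweep <- function(params, parameter, grid = NULL,
                          strata = pca_strata(), opts = pca_options()) {
  i <- match(parameter, params$name)
  if (is.na(i)) stop("unknown parameter '", parameter, "'")
  if (is.null(grid))
    grid <- seq(params$low[i], params$high[i], length.out = 50)
  if (any(grid < params$low[i] - 1e-12) || any(grid > params$high[i] + 1e-12))
    stop("grid values outside the parameter's admissible interval")
  base <- base_case_draw(params)
  rows <- list()
  for (v in grid) {
    dr <- base
    dr[parameter] <- v
    if (parameter %in% .pca_grade_names) {
      g <- dr[.pca_grade_names]
      dr[.pca_grade_names] <- g / sum(g)
    }
    for (st in strata) {
      std <- evaluate_strategy("standard", st, dr, opts = opts)
      mri <- evaluate_strategy("mri", st, dr, opts = opts)
      cmp <- icer(std, mri)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = parameter, value = v, stratum = st,
                   cost_standard = std$expected_cost,
                   cost_mri = mri$expected_cost,
                   qaly_standard = std$expected_qaly,
                   qaly_mri = mri$expected_qaly,
                   incremental_cost = cmp$incremental_cost,
                   incremental_qaly = cmp$incremental_qaly,
                   icer = cmp$icer, label = cmp$label,
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("pca_sweep", "data.frame"))
}

#' Plot a one-way sweep
#'
#' @param x A \code{pca_sweep}.
#' @param outcome Which column to plot against the swept value.
#' @param ... Further graphical arguments.
#' @export
plot.pca_sweep <- function(x, outcome = "icer", ...) {
  strata <- unique(x$stratum)
  v <- sort(unique(x$value))
  m <- sapply(strata, function(st)
    x[[outcome]][x$stratum == st][order(x$value[x$stratum == st])])
  graphics::matplot(v, m, type = "l", lty = 1, lwd = 2,
                    col = seq_along(strata),
                    xlab = unique(x$parameter), ylab = outcome, ...)
  graphics::legend("topright", legend = paste("PSA", strata),
                   col = seq_along(strata), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Tornado analysis
#'
#' Evaluates a chosen incremental outcome at each parameter's published
#' interval endpoints with all other parameters at base values, and ranks
#' parameters by the magnitude of the outcome span.
#'
#' @param params A \code{pca_parameter_table}.
#' @param parameters Parameter names to include; defaults to every
#'   non-degenerate (sampled) parameter.
#' @param stratum Single PSA stratum.
#' @param outcome One of \code{"icer"}, \code{"incremental_cost"},
#'   \code{"incremental_qaly"}.
#' @param opts Model options.
#' @return Object of class \code{pca_tornado}: data frame with the outcome
#'   at the low and high endpoint, the base-case outcome, and the span,
#'   ordered by decreasing absolute span.
#' @export
tornado <- function(params, parameters = NULL, stratum = "2.5-4.0",
                    outcome = c("icer", "incremental_cost",
                                "incremental_qaly"),
                    opts = pca_options()) {
  outcome <- match.arg(outcome)
  if (is.null(parameters))
    parameters <- params$name[params$family != "fixed" &
                                params$low < params$high]
  stratum <- match.arg(stratum, pca_strata())
  base <- base_case_draw(params)
  eval_outcome <- function(dr) {
    std <- evaluate_strategy("standard", stratum, dr, opts = opts)
    mri <- evaluate_strategy("mri", stratum, dr, opts = opts)
    cmp <- icer(std, mri)
    switch(outcome, icer = cmp$icer,
           incremental_cost = cmp$incremental_cost,
           incremental_qaly = cmp$incremental_qaly)
  }
  base_out <- eval_outcome(base)
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, params$name)
    if (is.na(i)) stop("unknown parameter '", nm, "'")
    at <- function(v) {
      dr <- base
      dr[nm] <- v
      if (nm %in% .pca_grade_names) {
        g <- dr[.pca_grade_names]
        dr[.pca_grade_names] <- g / sum(g)
      }
      eval_outcome(dr)
    }
    lo <- at(params$low[i])
    hi <- at(params$high[i])
    data.frame(parameter = nm, low_value = params$low[i],
               high_value = params$high[i],
               outcome_at_low = lo, outcome_at_high = hi,
               outcome_base = base_out,
               span = hi - lo, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$span)), ]
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "stratum") <- stratum
  structure(out, class = c("pca_tornado", "data.frame"))
}

#' Plot a tornado diagram
#'
#' @param x A \code{pca_tornado}.
#' @param n_top Number of highest-span parameters to show.
#' @param ... Further graphical arguments.
#' @export
plot.pca_tornado <- function(x, n_top = 10, ...) {
  d <- utils::head(as.data.frame(x), n_top)
  d <- d[nrow(d):1, ]
  lo <- pmin(d$outcome_at_low, d$outcome_at_high)
  hi <- pmax(d$outcome_at_low, d$outcome_at_high)
  graphics::par(mar = c(5, 12, 2, 2))
  graphics::plot(NULL, xlim = range(c(lo, hi, d$outcome_base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = attr(x, "outcome"), ylab = "", ...)
  graphics::rect(lo, seq_len(nrow(d)) - 0.3, hi, seq_len(nrow(d)) + 0.3,
                 col = "steelblue")
  graphics::abline(v = d$outcome_base[1], lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
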