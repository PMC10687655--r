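#' @keywords internal
"_PACKAGE"

# Roles a parameter may take and the distribution families allowed for each.
.pca_roles <- c("probability", "test_characteristic", "cost_usd",
                "utility_decrement", "setting")

.pca_role_families <- list(
  probability         = c("beta", "fixed"),
  test_characteristic = c("beta", "fixed"),
  cost_usd            = c("gamma", "fixed"),
  utility_decrement   = c("beta", "fixed"),
  setting             = "fixed"
)

# The six joint grade x comorbidity probabilities; renormalised to sum to one
# in every realised draw.
.pca_grade_names <- c("p_grade_high_nc", "p_grade_high_c",
                      "p_grade_int_nc", "p_grade_int_c",
                      "p_grade_low_nc", "p_grade_low_c")

#' Names of all required model parameters
#'
#' The canonical list of model inputs: disease prevalence and annual
#' recurrence probability per PSA stratum, the joint grade-by-comorbidity
#' distribution of prevalent cancers, test characteristics of MRI and both
#' biopsies, adverse-event probabilities, unit costs, utility decrements and
#' fixed analysis settings.
#'
#' @return Character vector of parameter names.
#' @export
pca_parameter_names <- function() {
  c("p_cancer_psa_lt25", "p_cancer_psa_25_40", "p_cancer_psa_41_100",
    "p_cancer_psa_gt10",
    "p_recurrence_psa_lt25", "p_recurrence_psa_25_40",
    "p_recurrence_psa_41_100", "p_recurrence_psa_gt10",
    "p_adverse_mri_guided", "p_adverse_standard",
    .pca_grade_names,
    "p_upgrade",
    "sens_mri", "spec_mri",
    "sens_mri_guided_biopsy", "spec_mri_guided_biopsy",
    "sens_standard_biopsy", "spec_standard_biopsy",
    "cost_psa", "cost_standard_biopsy", "cost_mri", "cost_mri_guided_biopsy",
    "cost_prostatectomy", "cost_radiotherapy", "cost_brachytherapy",
    "cost_untreated_comorbid", "cost_post_treatment",
    "disutility_high_grade", "disutility_low_int_grade",
    "disutility_comorbid_pca", "disutility_recurrence",
    "disutility_psa",
    "disutility_ae_standard_biopsy", "disutility_ae_mri_guided_biopsy",
    "disutility_prostatectomy", "disutility_radiotherapy",
    "disutility_brachytherapy",
    "disutility_treatment_year1", "disutility_treatment_later",
    "utility_healthy", "discount_rate", "wtp_threshold", "horizon_years",
    "entry_age", "w_prostatectomy", "w_radiotherapy", "w_brachytherapy")
}

#' Path to the bundled default parameter configuration
#'
#' @return Path to the YAML file shipped with the package.
#' @export
pca_default_config <- function() {
  system.file("extdata", "parameters.yaml", package = "mriscreen",
              mustWork = TRUE)
}

#' Path to the bundled background-mortality table
#'
#' Annual all-cause death probabilities for US males aged 65 to 74,
#' transcribed from a published period life table.
#'
#' @return Path to the CSV file shipped with the package.
#' @export
pca_default_mortality <- function() {
  system.file("extdata", "us_male_mortality_65_74.csv",
              package = "mriscreen", mustWork = TRUE)
}

#' Load a background-mortality table
#'
#' @param path CSV file with columns \code{age} and
#'   \code{annual_death_probability}. Defaults to the bundled US-male table
#'   for ages 65 to 74.
#' @return Data frame with columns \code{age} and
#'   \code{annual_death_probability}.
#' @export
load_mortality <- function(path = pca_default_mortality()) {
  m <- utils::read.csv(path)
  need <- c("age", "annual_death_probability")
  if (!all(need %in% names(m)))
    stop("mortality table must have columns: ", paste(need, collapse = ", "))
  q <- m$annual_death_probability
  if (any(q < 0 | q > 1)) stop("death probabilities must lie in [0, 1]")
  m[order(m$age), need]
}

.validate_parameter_row <- function(name, role, family, base, low, high) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, paste0(name, ": ", msg))
  if (!role %in% .pca_roles)
    add(paste0("unknown role '", role, "'"))
  else if (!family %in% .pca_role_families[[role]])
    add(paste0("family '", family, "' not allowed for role '", role, "'"))
  if (!(low <= base && base <= high))
    add("interval must satisfy low <= base <= high")
  if (role %in% c("probability", "test_characteristic") &&
      (low < 0 || high > 1))
    add("probability interval must lie in [0, 1]")
  if (role == "cost_usd" && low < 0)
    add("costs must be non-negative")
  if (role == "utility_decrement" && high > 0)
    add("utility decrements must be stored as non-positive values")
  if (family == "fixed" && !(low == base && high == base))
    add("family 'fixed' requires low = high = base")
  errs
}

#' Load and validate the model parameter table
#'
#' Reads a structured configuration (one record per parameter with fields
#' \code{name}, \code{role}, \code{family}, \code{base}, \code{low},
#' \code{high}, \code{note}), validates every record against its role's
#' admissible range, checks that all required parameters are present, and
#' fits a sampling distribution to each record's mean and 95% interval.
#'
#' @param config Path to a YAML or JSON configuration file, or a list with a
#'   \code{parameters} element as produced by reading such a file. Defaults
#'   to the bundled configuration reproducing the published input tables.
#' @return An object of class \code{pca_parameter_table}: a data frame with
#'   columns \code{name}, \code{role}, \code{family}, \code{base},
#'   \code{low}, \code{high}, \code{note}, carrying the fitted distributions
#'   in attribute \code{"fits"}.
#' @export
load_parameter_table <- function(config = pca_default_config()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$parameters))
    stop("config must contain a 'parameters' list")
  recs <- config$parameters
  tab <- do.call(rbind, lapply(recs, function(r) {
    need <- c("name", "role", "family", "base", "low", "high")
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("parameter record missing fields: ", paste(miss, collapse = ", "))
    data.frame(name = r$name, role = r$role, family = r$family,
               base = as.numeric(r$base), low = as.numeric(r$low),
               high = as.numeric(r$high),
               note = if (is.null(r$note)) "" else r$note,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(tab$name))
    stop("duplicated parameter names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))

  required <- pca_parameter_names()
  missing <- setdiff(required, tab$name)
  if (length(missing))
    stop("missing required parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(tab$name, required)
  if (length(extra))
    message("ignoring extra parameters: ", paste(extra, collapse = ", "))

  errs <- unlist(Map(.validate_parameter_row, tab$name, tab$role, tab$family,
                     tab$base, tab$low, tab$high))
  if (length(errs))
    stop("invalid parameter values:\n  ", paste(errs, collapse = "\n  "))

  tab <- tab[match(required, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  fits <- lapply(seq_len(nrow(tab)), function(i)
    fit_parameter_distribution(tab$role[i], tab$family[i], tab$base[i],
                               tab$low[i], tab$high[i]))
  names(fits) <- tab$name
  attr(tab, "fits") <- fits
  class(tab) <- c("pca_parameter_table", class(tab))
  tab
}

#' @export
print.pca_parameter_table <- function(x, ...) {
  cat("Model parameter table:", nrow(x), "parameters\n")
  cat(sprintf("  %d probabilities/test characteristics (beta), %d costs (gamma), %d utility decrements, %d fixed settings\n",
              sum(x$role %in% c("probability", "test_characteristic")),
              sum(x$role == "cost_usd"),
              sum(x$role == "utility_decrement"),
              sum(x$role == "setting")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' Fit a beta distribution to a mean and 95% interval
#'
#' Finds the beta distribution whose mean equals \code{mean} exactly and
#' whose 2.5% and 97.5% quantiles best reproduce \code{(low, high)} in the
#' least-squares sense, by a one-dimensional search over the first shape
#' parameter (the second is determined by the mean constraint).
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param low,high Target 2.5% and 97.5% quantiles.
#' @return List with elements \code{family = "beta"}, \code{shape1},
#'   \code{shape2}, fitted quantiles \code{q_fit} and targets
#'   \code{q_target}.
#' @export
fit_beta_from_mean_interval <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1)
    stop("degenerate beta: mean must be strictly inside (0, 1); ",
         "use a fixed (point) distribution instead")
  if (!(low < high)) stop("interval must satisfy low < high")
  if (!(low <= mean && mean <= high))
    stop("mean must lie inside [low, high]")
  obj <- function(la) {
    a <- exp(la)
    b <- a * (1 - mean) / mean
    (stats::qbeta(0.025, a, b) - low)^2 +
      (stats::qbeta(0.975, a, b) - high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-4), log(1e7)))
  a <- exp(opt$minimum)
  b <- a * (1 - mean) / mean
  if (!is.finite(a) || !is.finite(b))
    stop("beta fit failed: non-finite shape parameters (objective ",
         format(opt$objective), ")")
  list(family = "beta", shape1 = a, shape2 = b,
       q_fit = stats::qbeta(c(0.025, 0.975), a, b),
       q_target = c(low, high))
}

#' Fit a gamma distribution to a mean and 95% interval
#'
#' Finds the gamma distribution whose mean (shape/rate) equals \code{mean}
#' exactly and whose 2.5% and 97.5% quantiles best reproduce
#' \code{(low, high)}, by a one-dimensional search over the shape parameter.
#' A degenerate interval (\code{low == high == mean}) yields a point
#' distribution.
#'
#' @param mean Target mean, positive.
#' @param low,high Target 2.5% and 97.5% quantiles.
#' @return List with \code{family = "gamma"}, \code{shape}, \code{rate},
#'   fitted quantiles \code{q_fit} and targets \code{q_target}; or
#'   \code{family = "fixed"} with \code{point = mean} for a degenerate
#'   interval.
#' @export
fit_gamma_from_mean_interval <- function(mean, low, high) {
  if (mean <= 0) stop("gamma mean must be positive")
  if (low == high) {
    if (low != mean) stop("degenerate interval must equal the mean")
    return(list(family = "fixed", point = mean,
                q_fit = c(mean, mean), q_target = c(low, high)))
  }
  if (!(low <= mean && mean <= high))
    stop("mean must lie inside [low, high]")
  obj <- function(ls) {
    s <- exp(ls)
    r <- s / mean
    (stats::qgamma(0.025, shape = s, rate = r) - low)^2 +
      (stats::qgamma(0.975, shape = s, rate = r) - high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-4), log(1e7)))
  s <- exp(opt$minimum)
  r <- s / mean
  if (!is.finite(s) || !is.finite(r))
    stop("gamma fit failed: non-finite parameters (objective ",
         format(opt$objective), ")")
  list(family = "gamma", shape = s, rate = r,
       q_fit = stats::qgamma(c(0.025, 0.975), shape = s, rate = r),
       q_target = c(low, high))
}

# Dispatch the appropriate fit for one parameter record.  Utility decrements
# are fitted on the magnitude scale (a beta on [0, 1] for the absolute
# decrement) and negated at sampling time.  Probabilities whose printed mean
# sits on the boundary of (0, 1) cannot carry a mean-preserving beta and are
# treated as point values.
fit_parameter_distribution <- function(role, family, base, low, high) {
  if (family == "fixed" || low == high)
    return(list(family = "fixed", point = base,
                q_fit = c(base, base), q_target = c(low, high)))
  if (role %in% c("probability", "test_characteristic")) {
    if (base <= 0 || base >= 1)
      return(list(family = "fixed", point = base, boundary = TRUE,
                  q_fit = c(base, base), q_target = c(low, high)))
    return(fit_beta_from_mean_interval(base, low, high))
  }
  if (role == "cost_usd")
    return(fit_gamma_from_mean_interval(base, low, high))
  if (role == "utility_decrement") {
    # magnitude scale: mean -base with interval (-high, -low)
    m <- -base
    if (m <= 0)
      return(list(family = "fixed", point = base,
                  q_fit = c(base, base), q_target = c(low, high)))
    f <- fit_beta_from_mean_interval(m, -high, -low)
    f$negate <- TRUE
    f$q_fit <- -rev(f$q_fit)
    f$q_target <- c(low, high)
    return(f)
  }
  stop("no distribution rule for role '", role, "'")
}

# Draw one realisation from a fitted distribution; n-vectorised.
.sample_fit <- function(fit, n = 1L) {
  v <- switch(fit$family,
              fixed = rep(fit$point, n),
              beta  = stats::rbeta(n, fit$shape1, fit$shape2),
              gamma = stats::rgamma(n, shape = fit$shape, rate = fit$rate),
              stop("unknown family '", fit$family, "'"))
  if (isTRUE(fit$negate)) -v else v
}

# Renormalise the six joint grade x comorbidity probabilities so that each
# realised draw is a valid categorical distribution.
.finalize_draw <- function(v, draw_id = NA_integer_, seed_info = "base case") {
  g <- v[.pca_grade_names]
  v[.pca_grade_names] <- g / sum(g)
  structure(v, class = "pca_draw", draw_id = draw_id, seed_info = seed_info)
}

#' Base-case parameter draw
#'
#' @param table A \code{pca_parameter_table}.
#' @return A named numeric vector of class \code{pca_draw} assigning every
#'   parameter its base value (with the joint grade probabilities
#'   renormalised to sum to one).
#' @export
base_case_draw <- function(table) {
  stopifnot(inherits(table, "pca_parameter_table"))
  v <- stats::setNames(table$base, table$name)
  .finalize_draw(v)
}

# Derived per-draw seed, kept below 2^31 so it is a valid R integer.
.draw_seed <- function(seed, draw_id) {
  as.integer(((as.double(seed) %% 2147483647) * 69621 +
                as.double(draw_id) * 7919) %% 2147483647)
}

#' Sample one Monte Carlo parameter draw
#'
#' Draws every parameter independently from its fitted distribution. The
#' result is fully determined by \code{(seed, draw_id)}, and distinct
#' \code{draw_id}s give independent draws, so a probabilistic analysis can be
#' reproduced or resumed draw by draw.
#'
#' @param table A \code{pca_parameter_table}.
#' @param seed Integer seed of the analysis.
#' @param draw_id Integer index of the draw within the analysis.
#' @return A named numeric vector of class \code{pca_draw}.
#' @export
sample_draw <- function(table, seed, draw_id = 1L) {
  stopifnot(inherits(table, "pca_parameter_table"))
  fits <- attr(table, "fits")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.draw_seed(seed, draw_id))
  v <- vapply(fits, .sample_fit, numeric(1))
  names(v) <- table$name
  .finalize_draw(v, draw_id = as.integer(draw_id),
                 seed_info = paste0("seed=", seed, ", draw=", draw_id))
}

#' Sample a matrix of Monte Carlo parameter draws
#'
#' @param table A \code{pca_parameter_table}.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric matrix with one row per draw and one column per
#'   parameter; row \code{i} equals \code{sample_draw(table, seed, i)}.
#' @export
sample_draws <- function(table, n, seed) {
  m <- t(vapply(seq_len(n), function(i) as.numeric(sample_draw(table, seed, i)),
                numeric(nrow(table))))
  colnames(m) <- table$name
  m
}

#' @export
print.pca_draw <- function(x, ...) {
  cat("Parameter draw (", attr(x, "seed_info"), "), ",
      length(x), " parameters\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Report distribution-fit residuals
#'
#' For every non-degenerate parameter, compares the 2.5% and 97.5% quantiles
#' of the fitted distribution with the published interval endpoints.
#'
#' @param table A \code{pca_parameter_table}.
#' @return Data frame with the fitted and target quantiles and their
#'   differences.
#' @export
fit_residuals <- function(table) {
  stopifnot(inherits(table, "pca_parameter_table"))
  fits <- attr(table, "fits")
  do.call(rbind, lapply(table$name, function(nm) {
    f <- fits[[nm]]
    data.frame(name = nm, family = f$family,
               q025_fit = f$q_fit[1], q975_fit = f$q_fit[2],
               q025_target = f$q_target[1], q975_target = f$q_target[2],
               resid_low = f$q_fit[1] - f$q_target[1],
               resid_high = f$q_fit[2] - f$q_target[2],
               stringsAsFactors = FALSE)
  }))
}
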