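# Shared fixtures, built in code.

# The default parameter table, loaded once per test run.
test_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parameter_table()
    cache
  }
})

# A mortality table with no deaths, for closed-form checks.
zero_mortality <- function() {
  data.frame(age = 60:90, annual_death_probability = 0)
}

opts_nodeath <- function(...) pca_options(mortality = zero_mortality(), ...)

# Base-case draw with selective overrides (grade probabilities renormalised
# by the constructors downstream, so overrides here are raw).
draw_with <- function(...) {
  dr <- base_case_draw(test_table())
  ov <- list(...)
  for (nm in names(ov)) {
    stopifnot(nm %in% names(dr))
    dr[nm] <- ov[[nm]]
  }
  dr
}

# Read the default YAML config as a plain list so tests can perturb records.
raw_config <- function() yaml::read_yaml(pca_default_config())
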