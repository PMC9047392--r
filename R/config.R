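#' Assemble a C-search configuration
#'
#' Collects every tunable hyperparameter of the discovery pipeline into a
#' single validated list, so that a whole run is reproducible from the
#' configuration snapshot attached to its result.
#'
#' @param k_tau Bandwidth (temperature) of the Boltzmann similarity kernel,
#'   i.e. the product of the kernel constant and the temperature. `"auto"`
#'   (default) uses the empirical standard deviation of the counterpart
#'   pool's basal projections, recomputed separately for the clinical and
#'   the genetic block; otherwise a positive number applied to both blocks.
#' @param renormalize_combined Logical. The product of the two
#'   individually-normalized weight vectors (clinical x genetic) does not
#'   itself sum to one; when `TRUE` (default) it is renormalized so each
#'   treated individual contributes exactly one pseudo-observation to its
#'   Beta posterior. `FALSE` reproduces the verbatim product reading.
#' @param prior_alpha,prior_beta Beta prior pseudo-counts for every win
#'   probability. Default `Beta(1, 1)` (uniform).
#' @param incomparable How to treat pairs whose survival ordering is
#'   undecidable under censoring: `"drop"` (default; weight renormalized
#'   over comparable pairs) or `"half"` (score 0.5).
#' @param basal_ridge Ridge penalty for the basal proportional-hazards risk
#'   score; the genetic block is wide, binary and sparse, so a small
#'   penalty (default 0.1) stabilizes the fit.
#' @param basal_fit_pool `"all"` (default; treatment entered as an
#'   unpenalized adjustment covariate) or `"untreated"`.
#' @param use_ipw Logical; reweight per-gene posterior accumulation by
#'   inverse propensities of treatment given clinical and genetic
#'   covariates. Default `FALSE`: see `ipw_gene_posterior` for the verbatim
#'   and stabilized variants.
#' @param stabilized_ipw Logical; rescale IPW pseudo-counts so their total
#'   equals the number of contributing carriers (only used with `use_ipw`).
#' @param propensity_clip Two probabilities; fitted propensities are clipped
#'   into this interval before weighting. Default `c(0.05, 0.95)`.
#' @param propensity_ridge Ridge penalty for the genetic-block propensity
#'   model (default 0.1).
#' @param match_caliper_sd Caliper for 1:1 propensity matching, as a
#'   multiple of the standard deviation of the logit propensity
#'   (default 0.2).
#' @param credible_level Credible level of the equal-tailed posterior
#'   intervals used by the decision rule (default 0.95).
#' @param k Number of genes to suggest (default 10).
#' @param direction Which arm is scored against which: the default
#'   `"treated_vs_untreated"` estimates, for every treated individual, the
#'   probability of outliving an untreated counterpart.
#'
#' @return A named list of class `"csearch_config"`.
#' @export
csearch_config <- function(k_tau = "auto",
                           renormalize_combined = TRUE,
                           prior_alpha = 1,
                           prior_beta = 1,
                           incomparable = c("drop", "half"),
                           basal_ridge = 0.1,
                           basal_fit_pool = c("all", "untreated"),
                           use_ipw = FALSE,
                           stabilized_ipw = FALSE,
                           propensity_clip = c(0.05, 0.95),
                           propensity_ridge = 0.1,
                           match_caliper_sd = 0.2,
                           credible_level = 0.95,
                           k = 10,
                           direction = c("treated_vs_untreated",
                                         "untreated_vs_treated")) {
  incomparable <- match.arg(incomparable)
  basal_fit_pool <- match.arg(basal_fit_pool)
  direction <- match.arg(direction)
  if (!identical(k_tau, "auto")) {
    stopifnot(is.numeric(k_tau), length(k_tau) == 1L, k_tau > 0)
  }
  stopifnot(
    prior_alpha > 0, prior_beta > 0,
    basal_ridge >= 0, propensity_ridge >= 0,
    length(propensity_clip) == 2L,
    propensity_clip[1] > 0, propensity_clip[2] < 1,
    propensity_clip[1] < propensity_clip[2],
    match_caliper_sd > 0,
    credible_level > 0, credible_level < 1,
    k >= 1
  )
  structure(
    list(
      k_tau = k_tau,
      renormalize_combined = isTRUE(renormalize_combined),
      prior_alpha = prior_alpha,
      prior_beta = prior_beta,
      incomparable = incomparable,
      basal_ridge = basal_ridge,
      basal_fit_pool = basal_fit_pool,
      use_ipw = isTRUE(use_ipw),
      stabilized_ipw = isTRUE(stabilized_ipw),
      propensity_clip = propensity_clip,
      propensity_ridge = propensity_ridge,
      match_caliper_sd = match_caliper_sd,
      credible_level = credible_level,
      k = as.integer(k),
      direction = direction
    ),
    class = "csearch_config"
  )
}

#' @export
print.csearch_config <- function(x, ...) {
  cat("C-search configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Serialize a config (or any flat list) as key=value lines; used for the
# provenance snapshot written next to every output artifact.
config_snapshot_lines <- function(config) {
  vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]]), collapse = ","))
  }, character(1))
}
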