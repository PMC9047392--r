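#' Per-gene carrier and non-carrier win posteriors
#'
#' Aggregates individual win probabilities into the two Beta posteriors
#' compared by the decision rule: treating each carrier's `Pw_i` as a
#' fractional Bernoulli outcome, the carrier posterior is
#' `Beta(alpha0 + sum Pw_i, beta0 + N_k - sum Pw_i)` over the `N_k` treated
#' carriers of the gene, and the non-carrier posterior is accumulated
#' identically over the complement. With IPW inputs the accumulation is
#' delegated to [ipw_gene_posterior()].
#'
#' @param pw Numeric vector of win probabilities for all evidence-bearing
#'   treated individuals.
#' @param carrier_mask Logical/binary vector aligned with `pw` (1 = the
#'   individual carries the gene).
#' @param prior A `"beta_posterior"` (default uniform).
#' @param ipw Optional list with elements `e_v`, `e_g` (clipped
#'   propensities aligned with `pw`) and optionally `stabilized`.
#' @return List with `carrier` and `noncarrier` (`"beta_posterior"`),
#'   `n_carriers`, and `flag_no_carriers` / `flag_no_noncarriers` (the
#'   corresponding side returned as the bare prior).
#' @export
gene_posterior <- function(pw, carrier_mask, prior = beta_posterior(1, 1),
                           ipw = NULL) {
  stopifnot(length(carrier_mask) == length(pw))
  carrier_mask <- as.logical(carrier_mask)
  side <- function(idx) {
    if (!length(idx)) return(prior)
    if (is.null(ipw)) {
      s <- sum(pw[idx])
      beta_posterior(prior$alpha + s, prior$beta + length(idx) - s)
    } else {
      ipw_gene_posterior(pw[idx], ipw$e_v[idx], ipw$e_g[idx], prior,
                         stabilized = isTRUE(ipw$stabilized))
    }
  }
  list(carrier = side(which(carrier_mask)),
       noncarrier = side(which(!carrier_mask)),
       n_carriers = sum(carrier_mask),
       flag_no_carriers = !any(carrier_mask),
       flag_no_noncarriers = all(carrier_mask))
}

#' Credible-interval separation decision
#'
#' A gene is decided causal when the lower bound of the carrier
#' posterior's equal-tailed 95% credible interval exceeds the upper bound
#' of the non-carrier posterior's interval; the separation margin
#' (`lower_carrier - upper_noncarrier`) is positive exactly in that case
#' and serves as the ranking key.
#'
#' @param carrier,noncarrier `"beta_posterior"` objects.
#' @param level Credible level (default 0.95).
#' @return List: `decided` (logical), `separation`, `ci_carrier`,
#'   `ci_noncarrier`.
#' @export
decide_causal <- function(carrier, noncarrier, level = 0.95) {
  ci_c <- credible_interval(carrier, level)
  ci_n <- credible_interval(noncarrier, level)
  separation <- ci_c[1] - ci_n[2]
  list(decided = separation > 0, separation = separation,
       ci_carrier = ci_c, ci_noncarrier = ci_n)
}

#' Rank genes and return the top-k suggestions
#'
#' Genes decided causal always rank above undecided ones; within each
#' group the ranking key is the separation margin (descending), with ties
#' broken by carrier count (descending) and then gene name.
#'
#' @param per_gene Data frame with columns `gene`, `decided`, `separation`,
#'   `n_carriers` (as produced by [run_csearch()]).
#' @param k Number of genes to suggest.
#' @return Character vector of the top-k gene names.
#' @export
suggest_genes <- function(per_gene, k) {
  stopifnot(k >= 1)
  if (k > nrow(per_gene)) {
    warning("k exceeds the number of genes; returning all ", nrow(per_gene))
    k <- nrow(per_gene)
  }
  ord <- order(-per_gene$decided, -per_gene$separation,
               -per_gene$n_carriers, per_gene$gene)
  per_gene$gene[ord][seq_len(k)]
}

#' Run the C-search discovery pipeline
#'
#' Full orchestration: fits the clinical and genetic basal models, computes
#' every treated individual's win posterior against the untreated pool via
#' similarity-weighted censored pairwise comparisons, aggregates carrier /
#' non-carrier posteriors for every gene (optionally inverse-propensity
#' weighted), applies the credible-interval separation rule, and ranks the
#' genes. Fully deterministic given the cohort and configuration.
#'
#' @param cohort A `"csearch_cohort"` with both arms and a gene matrix.
#' @param config A [csearch_config()].
#' @return Object of class `"csearch_result"`: list with `per_gene` (data
#'   frame over all genes: pseudo-counts, posterior means, credible bounds,
#'   `separation`, `decided`, `n_carriers`), `suggested` (top-k gene
#'   names), `win` (the individual win posteriors), `config` (snapshot)
#'   and fit objects `basal_clinical`, `basal_genetic`.
#' @export
run_csearch <- function(cohort, config = csearch_config()) {
  stopifnot(inherits(cohort, "csearch_cohort"))
  stop_if_single_arm(cohort)
  if (is.null(cohort$G) || length(cohort$gene_names) == 0) {
    stop("run_csearch needs a cohort with a gene matrix")
  }
  prior <- beta_posterior(config$prior_alpha, config$prior_beta)

  basal_clinical <- with_stage("basal clinical fit",
    fit_basal(cohort, "clinical", ridge = config$basal_ridge,
              fit_pool = config$basal_fit_pool))
  basal_genetic <- with_stage("basal genetic fit",
    fit_basal(cohort, "genetic", ridge = config$basal_ridge,
              fit_pool = config$basal_fit_pool))

  win <- with_stage("win posteriors",
    all_win_posteriors(cohort, basal_clinical, basal_genetic,
                       prior = prior, direction = config$direction,
                       k_tau = config$k_tau,
                       renormalize_combined = config$renormalize_combined,
                       incomparable = config$incomparable))

  use <- !win$no_evidence
  ids <- win$id[use]
  pw <- win$pw[use]
  Gt <- cohort$G[match(ids, cohort$clinical$id), , drop = FALSE]
  storage.mode(Gt) <- "double"

  ipw <- NULL
  if (config$use_ipw) {
    pv <- with_stage("clinical propensity fit",
      fit_propensity(cohort, "clinical", ridge = config$propensity_ridge,
                     clip = config$propensity_clip))
    pg <- with_stage("genetic propensity fit",
      fit_propensity(cohort, "genetic", ridge = config$propensity_ridge,
                     clip = config$propensity_clip))
    ipw <- list(e_v = predict_propensity(pv)[ids],
                e_g = predict_propensity(pg)[ids],
                stabilized = config$stabilized_ipw)
  }

  a0 <- prior$alpha; b0 <- prior$beta
  n_carriers <- as.integer(colSums(Gt))
  n_use <- length(pw)
  if (is.null(ipw)) {
    # closed-form vectorized accumulation over carriers / non-carriers
    swin <- drop(crossprod(Gt, pw))
    ac <- a0 + swin;                 bc <- b0 + n_carriers - swin
    an <- a0 + sum(pw) - swin;       bn <- b0 + (n_use - n_carriers) - (sum(pw) - swin)
  } else {
    wa <- pw / (ipw$e_v * ipw$e_g)
    wb <- (1 - pw) / ((1 - ipw$e_v) * (1 - ipw$e_g))
    ac_inc <- drop(crossprod(Gt, wa)); bc_inc <- drop(crossprod(Gt, wb))
    an_inc <- sum(wa) - ac_inc;        bn_inc <- sum(wb) - bc_inc
    if (config$stabilized_ipw) {
      sc <- ifelse(n_carriers > 0, n_carriers / (ac_inc + bc_inc), 0)
      sn <- ifelse(n_use - n_carriers > 0,
                   (n_use - n_carriers) / (an_inc + bn_inc), 0)
      ac_inc <- ac_inc * sc; bc_inc <- bc_inc * sc
      an_inc <- an_inc * sn; bn_inc <- bn_inc * sn
    }
    ac <- a0 + ac_inc; bc <- b0 + bc_inc
    an <- a0 + an_inc; bn <- b0 + bn_inc
  }
  # zero-carrier (or all-carrier) genes fall back to the bare prior
  none <- n_carriers == 0
  if (any(none)) {
    message(sum(none), " gene(s) with zero carriers among evidence-bearing ",
            "treated individuals; prior returned")
    ac[none] <- a0; bc[none] <- b0
  }
  all_carr <- n_carriers == n_use
  an[all_carr] <- a0; bn[all_carr] <- b0

  lev <- config$credible_level
  ql <- (1 - lev) / 2
  per_gene <- data.frame(
    gene = cohort$gene_names,
    alpha_carrier = ac, beta_carrier = bc,
    alpha_noncarrier = an, beta_noncarrier = bn,
    mean_carrier = ac / (ac + bc),
    mean_noncarrier = an / (an + bn),
    lower_carrier = stats::qbeta(ql, ac, bc),
    upper_carrier = stats::qbeta(1 - ql, ac, bc),
    lower_noncarrier = stats::qbeta(ql, an, bn),
    upper_noncarrier = stats::qbeta(1 - ql, an, bn),
    n_carriers = n_carriers,
    stringsAsFactors = FALSE
  )
  per_gene$separation <- per_gene$lower_carrier - per_gene$upper_noncarrier
  per_gene$decided <- per_gene$separation > 0

  suggested <- suggest_genes(per_gene, config$k)
  structure(
    list(per_gene = per_gene, suggested = suggested, win = win,
         config = config, basal_clinical = basal_clinical,
         basal_genetic = basal_genetic,
         n = n_individuals(cohort), n_treated_used = n_use),
    class = "csearch_result"
  )
}

#' @export
print.csearch_result <- function(x, ...) {
  cat(sprintf("C-search result: %d genes over %d individuals (%d treated used)\n",
              nrow(x$per_gene), x$n, x$n_treated_used))
  cat(sprintf("  decided causal: %d; suggested top-%d:\n",
              sum(x$per_gene$decided), length(x$suggested)))
  cat("  ", paste(x$suggested, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a discovery result as TSV
#' @param result A `"csearch_result"`.
#' @param path Output path.
#' @return Invisibly, the per-gene table.
#' @export
write_csearch_result <- function(result, path) {
  utils::write.table(result$per_gene, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(result$per_gene)
}

# Re-raise errors with the pipeline stage named, so a failure deep in a
# submodule still says where it happened.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}
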