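#' Beta pseudo-count accumulator
#'
#' The universal container for win evidence: a `Beta(alpha, beta)`
#' distribution whose pseudo-counts are updated by (possibly fractional,
#' similarity-weighted) win/loss observations.
#'
#' @param alpha,beta Positive pseudo-counts.
#' @return Object of class `"beta_posterior"`.
#' @export
beta_posterior <- function(alpha = 1, beta = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L,
            is.finite(alpha), is.finite(beta), alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  ci <- credible_interval(x)
  cat(sprintf("Beta(%.4g, %.4g): mean %.4f, 95%% CrI [%.4f, %.4f]\n",
              x$alpha, x$beta, posterior_mean(x), ci[1], ci[2]))
  invisible(x)
}

#' Posterior mean of a Beta accumulator
#' @param x A `"beta_posterior"`.
#' @return `alpha / (alpha + beta)`.
#' @export
posterior_mean <- function(x) x$alpha / (x$alpha + x$beta)

#' Equal-tailed credible interval of a Beta accumulator
#' @param x A `"beta_posterior"`.
#' @param level Credible level (default 0.95).
#' @return Numeric `(lower, upper)`.
#' @export
credible_interval <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::qbeta(c(a, 1 - a), x$alpha, x$beta)
}

#' Score one censored survival comparison
#'
#' Pairwise Wilcoxon-Mann-Whitney comparability for right-censored pairs,
#' scoring whether individual `i` outlives counterpart `j`:
#' \itemize{
#'   \item both events: 1 if `t_i > t_j`, 0 if `t_i < t_j`, 0.5 on ties;
#'   \item `i` censored at `t_i >= t_j` with `j` dead at `t_j`: 1
#'     (`i` is known to outlive `j`); the mirror case scores 0;
#'   \item otherwise (the smaller observed time is censored, or both are
#'     censored): the ordering is unknowable and the pair is incomparable,
#'     returned as `NA`.
#' }
#'
#' @param time_i,event_i,time_j,event_j Times (non-negative) and event
#'   indicators (1 = event observed, 0 = censored); vectors are recycled
#'   elementwise.
#' @return Numeric vector of scores in `{0, 0.5, 1}` with `NA` for
#'   incomparable pairs.
#' @export
compare_pair <- function(time_i, event_i, time_j, event_j) {
  if (any(c(time_i, time_j) < 0, na.rm = TRUE)) stop("negative survival time")
  stopifnot(all(event_i %in% c(0, 1)), all(event_j %in% c(0, 1)))
  n <- max(length(time_i), length(time_j))
  ti <- rep_len(time_i, n); ei <- rep_len(event_i, n)
  tj <- rep_len(time_j, n); ej <- rep_len(event_j, n)
  s <- rep(NA_real_, n)
  both <- ei == 1 & ej == 1
  s[both] <- 0.5 * (sign(ti[both] - tj[both]) + 1)
  s[ei == 0 & ej == 1 & ti >= tj] <- 1
  s[ei == 1 & ej == 0 & tj >= ti] <- 0
  s
}

# Pairwise score matrix: rows = index-side individuals, cols = pool.
score_matrix <- function(time_i, event_i, time_j, event_j) {
  ni <- length(time_i); nj <- length(time_j)
  TI <- matrix(time_i, ni, nj)
  TJ <- matrix(time_j, ni, nj, byrow = TRUE)
  EI <- matrix(event_i == 1, ni, nj)
  EJ <- matrix(event_j == 1, ni, nj, byrow = TRUE)
  S <- matrix(NA_real_, ni, nj)
  both <- EI & EJ
  S[both] <- 0.5 * (sign(TI[both] - TJ[both]) + 1)
  S[!EI & EJ & TI >= TJ] <- 1
  S[EI & !EJ & TJ >= TI] <- 0
  S
}

#' Win posterior of one treated individual
#'
#' Accumulates the similarity-weighted pairwise scores of individual `i`
#' against its untreated counterpart pool into a Beta posterior: the
#' combined clinical x genetic weight of each comparable pair adds `s_j w_j`
#' wins and `(1 - s_j) w_j` losses to the prior pseudo-counts. Incomparable
#' pairs carry no evidence; under the default policy their weight is
#' redistributed by renormalizing over the comparable pairs, so each
#' individual contributes a constant total of one pseudo-observation.
#'
#' @param scores Numeric vector of pairwise scores aligned to the pool
#'   (`NA` = incomparable), from [compare_pair()].
#' @param w_clinical,w_genetic `"similarity_weights"` aligned to the pool.
#' @param prior A `"beta_posterior"` prior (default uniform `Beta(1, 1)`).
#' @param renormalize_combined Passed to [combine_weights()].
#' @param incomparable `"drop"` (default) or `"half"` (incomparable pairs
#'   score 0.5 instead of being dropped).
#' @param id Optional individual id carried through.
#' @return Object of class `"win_posterior"`: list with `id`, `posterior`
#'   (a `"beta_posterior"`), `pw` (its mean), `n_effective` (total applied
#'   weight) and `no_evidence` (TRUE when every pair was incomparable, in
#'   which case the posterior equals the prior).
#' @export
individual_win_posterior <- function(scores, w_clinical, w_genetic,
                                     prior = beta_posterior(1, 1),
                                     renormalize_combined = TRUE,
                                     incomparable = c("drop", "half"),
                                     id = NA_character_) {
  incomparable <- match.arg(incomparable)
  wc <- combine_weights(w_clinical, w_genetic, renormalize = renormalize_combined)
  stopifnot(length(scores) == length(wc$weights))
  if (incomparable == "half") scores[is.na(scores)] <- 0.5
  comp <- !is.na(scores)
  if (!any(comp)) {
    return(structure(list(id = id, posterior = prior,
                          pw = posterior_mean(prior),
                          n_effective = 0, no_evidence = TRUE),
                     class = "win_posterior"))
  }
  w <- wc$weights[comp]
  if (renormalize_combined) w <- w / sum(w)
  a <- prior$alpha + sum(scores[comp] * w)
  b <- prior$beta + sum((1 - scores[comp]) * w)
  structure(list(id = id, posterior = beta_posterior(a, b),
                 pw = a / (a + b), n_effective = sum(w),
                 no_evidence = FALSE),
            class = "win_posterior")
}

#' Win posteriors for every index-side individual of a cohort
#'
#' The pipeline's pairwise stage. Each individual on the index side
#' (treated, by default) is compared against the whole counterpart pool
#' (untreated): clinical and genetic basal projections give two Boltzmann
#' weight matrices, their (renormalized) product weights the pairwise
#' censored win/loss scores, and the weighted evidence is accumulated into
#' one Beta posterior per individual. Deterministic given its inputs, and
#' computed with dense matrices in O(N_treated x N_untreated).
#'
#' @param cohort A `"csearch_cohort"` with both arms.
#' @param basal_clinical,basal_genetic Fitted [fit_basal()] models for the
#'   two blocks.
#' @param prior A `"beta_posterior"` prior (default uniform).
#' @param direction `"treated_vs_untreated"` (default) scores treated
#'   individuals against the untreated pool; `"untreated_vs_treated"`
#'   swaps the roles.
#' @param k_tau `"auto"` (per-block pool SD) or a positive bandwidth.
#' @param renormalize_combined,incomparable See
#'   [individual_win_posterior()].
#' @return A data frame of class `"win_posteriors"` with one row per
#'   index-side individual: `id`, `alpha`, `beta`, `pw` (posterior mean),
#'   `n_effective`, `no_evidence`; attributes `direction` and `prior`.
#' @export
all_win_posteriors <- function(cohort, basal_clinical, basal_genetic,
                               prior = beta_posterior(1, 1),
                               direction = c("treated_vs_untreated",
                                             "untreated_vs_treated"),
                               k_tau = "auto",
                               renormalize_combined = TRUE,
                               incomparable = c("drop", "half")) {
  direction <- match.arg(direction)
  incomparable <- match.arg(incomparable)
  stop_if_single_arm(cohort)
  cl <- cohort$clinical
  i_arm <- if (direction == "treated_vs_untreated") 1 else 0
  i_side <- which(cl$treatment == i_arm)
  pool <- which(cl$treatment != i_arm)

  pv <- project(basal_clinical, cohort)
  pg <- project(basal_genetic, cohort)
  ktau_v <- resolve_k_tau(k_tau, pv[pool])
  ktau_g <- resolve_k_tau(k_tau, pg[pool])

  WV <- weight_matrix(pv[i_side], pv[pool], ktau_v)
  WG <- weight_matrix(pg[i_side], pg[pool], ktau_g)
  P <- WV * WG
  if (renormalize_combined) P <- P / rowSums(P)

  S <- score_matrix(cl$time[i_side], cl$event[i_side],
                    cl$time[pool], cl$event[pool])
  if (incomparable == "half") S[is.na(S)] <- 0.5
  comp <- !is.na(S)
  Pc <- P * comp
  rs <- rowSums(Pc)
  no_evidence <- rs == 0
  if (renormalize_combined) {
    Pn <- Pc / ifelse(rs > 0, rs, 1)
  } else {
    Pn <- Pc
  }
  S0 <- S
  S0[!comp] <- 0
  wins <- rowSums(S0 * Pn)
  total <- rowSums(Pn)
  alpha <- prior$alpha + wins
  beta <- prior$beta + (total - wins)
  alpha[no_evidence] <- prior$alpha
  beta[no_evidence] <- prior$beta

  out <- data.frame(
    id = cl$id[i_side],
    alpha = alpha, beta = beta,
    pw = alpha / (alpha + beta),
    n_effective = total, no_evidence = no_evidence,
    stringsAsFactors = FALSE
  )
  if (any(no_evidence)) {
    message(sum(no_evidence), " individual(s) had no comparable counterpart; ",
            "posterior left at the prior")
  }
  attr(out, "direction") <- direction
  attr(out, "prior") <- prior
  class(out) <- c("win_posteriors", "data.frame")
  out
}
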