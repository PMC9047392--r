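#' Fit a treatment-propensity model for one covariate block
#'
#' Logistic-link regression of the treatment indicator on the clinical or
#' genetic covariate block, giving the assignment probabilities `e(V)` or
#' `e(G)` used for inverse-propensity weighting and for propensity-score
#' matching. The genetic block (wide, binary) is ridge-penalized; constant
#' columns are dropped with a warning, and fitted probabilities are clipped
#' away from 0 and 1.
#'
#' @param cohort A `"csearch_cohort"` with both arms.
#' @param block `"clinical"` or `"genetic"`.
#' @param ridge Ridge penalty for the genetic block (per-observation
#'   `glmnet` lambda `ridge / n`; default 0.1).
#' @param clip Clipping bounds for fitted probabilities (default
#'   `c(0.05, 0.95)`).
#' @return Object of class `"propensity_model"`: coefficients, intercept,
#'   clip bounds, and the clipped fitted probabilities named by id.
#' @export
fit_propensity <- function(cohort, block = c("clinical", "genetic"),
                           ridge = 0.1, clip = c(0.05, 0.95)) {
  block <- match.arg(block)
  stop_if_single_arm(cohort)
  stopifnot(length(clip) == 2L, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
  X <- block_matrix(cohort, block)
  tr <- cohort$clinical$treatment
  n <- nrow(X)

  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant column(s) dropped from ", block,
            " propensity fit")
  }
  Xk <- X[, keep, drop = FALSE]

  if (ncol(Xk) == 0) {
    intercept <- stats::qlogis(mean(tr))
    coefs <- numeric(0)
    raw <- rep(stats::plogis(intercept), n)
  } else if (block == "genetic" && ncol(Xk) >= 2) {
    b <- glmnet_ridge_path(Xk, tr, "binomial", ridge / n)
    intercept <- b[1]
    coefs <- b[-1]
    raw <- drop(stats::plogis(intercept + Xk %*% coefs))
  } else {
    dat <- data.frame(tr = tr, Xk)
    f <- suppressWarnings(stats::glm(tr ~ ., data = dat,
                                     family = stats::binomial()))
    b <- stats::coef(f)
    b[is.na(b)] <- 0
    intercept <- unname(b[1])
    coefs <- unname(b[-1])
    raw <- drop(stats::plogis(intercept + Xk %*% coefs))
  }
  if (all(raw > 0.999 | raw < 0.001)) {
    stop("propensity fit degenerate (perfect separation) for block ", block)
  }
  n_clipped <- sum(raw < clip[1] | raw > clip[2])
  if (n_clipped > 0) {
    message(n_clipped, " propensity value(s) clipped to [",
            clip[1], ", ", clip[2], "]")
  }
  fitted <- pmin(pmax(raw, clip[1]), clip[2])
  names(fitted) <- cohort$clinical$id

  full_coefs <- stats::setNames(rep(0, ncol(X)), colnames(X))
  full_coefs[colnames(Xk)] <- coefs
  structure(
    list(block = block, coefficients = full_coefs, intercept = intercept,
         clip = clip, fitted = fitted, n_clipped = n_clipped),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Propensity %s model: %d covariates, clip [%.2f, %.2f], %d clipped\n",
              x$block, length(x$coefficients), x$clip[1], x$clip[2], x$n_clipped))
  invisible(x)
}

#' Predict clipped propensities
#' @param model A `"propensity_model"`.
#' @param cohort A `"csearch_cohort"` (default: use the fitted values).
#' @return Named vector of clipped probabilities.
#' @export
predict_propensity <- function(model, cohort = NULL) {
  if (is.null(cohort)) return(model$fitted)
  X <- block_matrix(cohort, model$block)
  raw <- drop(stats::plogis(model$intercept + X %*% model$coefficients))
  out <- pmin(pmax(raw, model$clip[1]), model$clip[2])
  names(out) <- cohort$clinical$id
  out
}

#' Inverse-propensity-weighted per-gene Beta posterior
#'
#' Aggregates the win probabilities of a gene's carriers into a Beta
#' posterior with inverse-propensity weights: each carrier contributes
#' `Pw_i / (e(V_i) e(G_i))` wins and `(1 - Pw_i) / ((1 - e(V_i))(1 - e(G_i)))`
#' losses. Verbatim, these pseudo-count totals can far exceed the number of
#' carriers, making the credible intervals overconfident; `stabilized`
#' rescales both increments so their total equals the number of
#' contributing carriers (the posterior mean is unchanged).
#'
#' @param pw Numeric vector of carrier win probabilities (posterior means).
#' @param e_v,e_g Clipped propensities aligned with `pw`.
#' @param prior A `"beta_posterior"` (default uniform).
#' @param stabilized Logical, default `FALSE` (verbatim weighting).
#' @return A `"beta_posterior"`; the prior itself when `pw` is empty.
#' @export
ipw_gene_posterior <- function(pw, e_v, e_g,
                               prior = beta_posterior(1, 1),
                               stabilized = FALSE) {
  if (length(pw) == 0) return(prior)
  stopifnot(length(e_v) == length(pw), length(e_g) == length(pw),
            all(e_v > 0 & e_v < 1), all(e_g > 0 & e_g < 1),
            all(pw >= 0 & pw <= 1))
  a_inc <- sum(pw / (e_v * e_g))
  b_inc <- sum((1 - pw) / ((1 - e_v) * (1 - e_g)))
  if (stabilized) {
    scale <- length(pw) / (a_inc + b_inc)
    a_inc <- a_inc * scale
    b_inc <- b_inc * scale
  }
  beta_posterior(prior$alpha + a_inc, prior$beta + b_inc)
}

#' 1:1 propensity-score matching
#'
#' Greedy nearest-neighbor matching without replacement on the logit
#' propensity, with a caliper expressed as a multiple of the standard
#' deviation of the logit. Treated individuals are processed in ascending
#' id order and distance ties go to the smaller untreated id, so the
#' matching is deterministic.
#'
#' @param cohort A `"csearch_cohort"` with both arms.
#' @param model A fitted `"propensity_model"` (default: clinical-block
#'   model fit on `cohort`).
#' @param caliper_sd Caliper width in logit SD units (default 0.2); `Inf`
#'   disables the caliper.
#' @return The matched subset of the cohort (a `"csearch_cohort"`), with
#'   attributes `"pairs"` (data frame `treated_id`, `untreated_id`,
#'   `distance`) and `"unmatched_treated"` (ids excluded by the caliper or
#'   pool exhaustion).
#' @export
propensity_match <- function(cohort, model = NULL, caliper_sd = 0.2) {
  stop_if_single_arm(cohort)
  if (is.null(model)) model <- fit_propensity(cohort, "clinical")
  e <- predict_propensity(model, cohort)
  lp <- stats::qlogis(e)
  cl <- cohort$clinical
  s <- stats::sd(lp)
  caliper <- if (!is.finite(s) || s < 1e-12) Inf else caliper_sd * s

  t_idx <- which(cl$treatment == 1)
  u_idx <- which(cl$treatment == 0)
  t_idx <- t_idx[order(cl$id[t_idx])]
  u_idx <- u_idx[order(cl$id[u_idx])]
  u_free <- rep(TRUE, length(u_idx))
  pairs_t <- integer(0); pairs_u <- integer(0); dist <- numeric(0)
  unmatched <- character(0)
  for (ti in t_idx) {
    if (!any(u_free)) { unmatched <- c(unmatched, cl$id[ti]); next }
    cand <- which(u_free)
    d <- abs(lp[ti] - lp[u_idx[cand]])
    j <- cand[which.min(d)]  # which.min takes the first minimum: smallest id
    if (min(d) > caliper) { unmatched <- c(unmatched, cl$id[ti]); next }
    u_free[j] <- FALSE
    pairs_t <- c(pairs_t, ti); pairs_u <- c(pairs_u, u_idx[j])
    dist <- c(dist, min(d))
  }
  if (length(pairs_t) == 0) stop("no propensity matches within the caliper")
  if (length(unmatched)) {
    message(length(unmatched), " treated individual(s) left unmatched")
  }
  keep <- sort(c(pairs_t, pairs_u))
  out <- subset_cohort(cohort, keep)
  attr(out, "pairs") <- data.frame(treated_id = cl$id[pairs_t],
                                   untreated_id = cl$id[pairs_u],
                                   distance = dist,
                                   stringsAsFactors = FALSE)
  attr(out, "unmatched_treated") <- unmatched
  out
}
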