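#' Fit a basal risk model for one covariate block
#'
#' The basal function is a scalar regression projection approximating each
#' individual's survival state; projection differences drive the Boltzmann
#' similarity weights. It is fit separately for the clinical covariates
#' (`block = "clinical"`) and the gene matrix (`block = "genetic"`) as a
#' linear proportional-hazards risk score maximizing a ridge-penalized Cox
#' partial likelihood. The genetic block is wide, binary and sparse, hence
#' the default small ridge penalty.
#'
#' By default the model is fit on the full cohort with treatment included
#' as an unpenalized adjustment covariate, so the projection reflects
#' baseline risk rather than treatment; `fit_pool = "untreated"` restricts
#' the fitting pool instead. If the partial-likelihood fit fails (e.g.
#' complete separation), the fit falls back to a logistic regression of
#' event-by-median-follow-up, with a loud message.
#'
#' @param cohort A `"csearch_cohort"`.
#' @param block `"clinical"` or `"genetic"`.
#' @param ridge Ridge penalty (default 0.1; the per-observation `glmnet`
#'   lambda is `ridge / n`).
#' @param fit_pool `"all"` (default) or `"untreated"`.
#' @return Object of class `"basal_model"`: coefficients over the block's
#'   covariates (zeros for columns dropped as constant), the covariate
#'   names, and fit metadata (`family`, `fit_pool`, `n`, `n_events`).
#' @export
fit_basal <- function(cohort, block = c("clinical", "genetic"),
                      ridge = 0.1, fit_pool = c("all", "untreated")) {
  block <- match.arg(block)
  fit_pool <- match.arg(fit_pool)
  X_all <- block_matrix(cohort, block)
  cl <- cohort$clinical
  rows <- if (fit_pool == "untreated") which(cl$treatment == 0) else seq_len(nrow(cl))
  X <- X_all[rows, , drop = FALSE]
  time <- cl$time[rows]
  event <- cl$event[rows]
  if (sum(event) < 2) stop("basal fit needs at least 2 events in the fitting pool")

  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant column(s) dropped from ", block,
            " basal fit")
  }
  Xk <- X[, keep, drop = FALSE]
  adjust <- fit_pool == "all"
  fit <- tryCatch(
    fit_cox_ridge(Xk, time, event,
                  adjust = if (adjust) cl$treatment[rows] else NULL,
                  ridge = ridge),
    error = function(e) e
  )
  family <- "cox_ridge"
  if (inherits(fit, "error") || any(!is.finite(fit$coef))) {
    message("basal ", block, " fit: partial-likelihood fitting failed (",
            if (inherits(fit, "error")) conditionMessage(fit) else "non-finite coefficients",
            "); falling back to logistic event-by-median-follow-up")
    fit <- fit_logistic_fallback(Xk, time, event, ridge)
    family <- "logistic_fallback"
  }

  coefs <- stats::setNames(rep(0, ncol(X)), colnames(X))
  coefs[colnames(Xk)] <- fit$coef
  structure(
    list(block = block, coefficients = coefs,
         covariate_names = colnames(X),
         family = family, fit_pool = fit_pool,
         treatment_coef = fit$treatment_coef,
         n = length(rows), n_events = sum(event)),
    class = "basal_model"
  )
}

# Ridge fit at a small target lambda, approached through a descending
# lambda path: warm starts keep the solver stable where a lone tiny
# lambda can fail outright (glmnet error -30001 on wide Cox problems).
# If the solver truncates the path, the smallest lambda it did reach is
# used, with a message.
glmnet_ridge_path <- function(x, y, family, target_lambda, ...) {
  lambdas <- target_lambda * 10^seq(3, 0, length.out = 10)
  f <- glmnet::glmnet(x, y, family = family, alpha = 0, lambda = lambdas,
                      standardize = TRUE, ...)
  got <- length(f$lambda)
  if (got < length(lambdas)) {
    message("ridge path truncated at lambda = ", signif(f$lambda[got], 3),
            " (target ", signif(target_lambda, 3), ")")
  }
  if (got == 0) stop("ridge fit failed at every lambda")
  as.matrix(stats::coef(f))[, got]
}

# Ridge Cox risk score. p >= 2 goes through glmnet (fast for the wide
# genetic block); p == 1 through coxph. `adjust` is an unpenalized
# treatment column excluded from the returned block coefficients.
fit_cox_ridge <- function(X, time, event, adjust = NULL, ridge = 0.1) {
  p <- ncol(X)
  if (p == 0) stop("no usable covariate columns")
  n <- nrow(X)
  y <- survival::Surv(time, event)
  if (p == 1 && is.null(adjust)) {
    f <- survival::coxph(y ~ X[, 1])
    return(list(coef = unname(stats::coef(f)), treatment_coef = NA_real_))
  }
  Xf <- if (is.null(adjust)) X else cbind(X, .treatment = adjust)
  pf <- c(rep(1, p), if (is.null(adjust)) NULL else 0)
  if (ncol(Xf) < 2) { # single penalized column is impossible here, guard anyway
    f <- survival::coxph(y ~ Xf[, 1])
    return(list(coef = unname(stats::coef(f)), treatment_coef = NA_real_))
  }
  b <- glmnet_ridge_path(Xf, y, "cox", ridge / n, penalty.factor = pf)
  if (all(b == 0)) stop("ridge Cox fit returned an empty model")
  list(coef = b[seq_len(p)],
       treatment_coef = if (is.null(adjust)) NA_real_ else b[p + 1])
}

fit_logistic_fallback <- function(X, time, event, ridge = 0.1) {
  med <- stats::median(time)
  y <- as.integer(event == 1 & time <= med)
  if (length(unique(y)) < 2) y <- event
  n <- nrow(X)
  if (ncol(X) >= 2) {
    b <- glmnet_ridge_path(X, y, "binomial", ridge / n)[-1]
  } else {
    f <- stats::glm(y ~ X[, 1], family = stats::binomial())
    b <- unname(stats::coef(f))[-1]
  }
  list(coef = b, treatment_coef = NA_real_)
}

#' @export
print.basal_model <- function(x, ...) {
  cat(sprintf("Basal %s model (%s, pool = %s): %d covariates, %d obs, %d events\n",
              x$block, x$family, x$fit_pool,
              length(x$coefficients), x$n, x$n_events))
  invisible(x)
}

#' Project individuals through a basal model
#'
#' Returns the scalar linear risk score `X %*% coef` for each individual,
#' using only the block's own coefficients (the treatment adjustment, if
#' any, is excluded, so the projection is a baseline-risk score). Only
#' projection differences matter downstream, so the score carries no
#' centering.
#'
#' @param model A `"basal_model"`.
#' @param newdata A `"csearch_cohort"`, or a numeric matrix whose columns
#'   match the model's covariates.
#' @return Named numeric vector of projections.
#' @export
project <- function(model, newdata) {
  stopifnot(inherits(model, "basal_model"))
  X <- if (inherits(newdata, "csearch_cohort")) {
    block_matrix(newdata, model$block)
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != length(model$coefficients)) {
    stop("projection dimension mismatch: model has ",
         length(model$coefficients), " covariates, data has ", ncol(X))
  }
  drop(X %*% model$coefficients)
}
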