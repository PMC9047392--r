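#' Boltzmann similarity weights over a counterpart pool
#'
#' Converts basal-projection differences into normalized similarity
#' weights: `w_j` is proportional to `exp(-|p_i - p_j| / k_tau)`, so a
#' counterpart whose projected survival state is closer to individual `i`
#' receives more weight. `k_tau` (the product of the kernel constant and
#' the temperature) acts as a bandwidth: very large values give uniform
#' weights, very small values concentrate all mass on the nearest
#' counterpart(s), ties split equally. The exponent is shifted by the
#' per-row minimum distance before exponentiation so the computation is
#' stable at tiny bandwidths.
#'
#' @param p_i Scalar projection of the index individual.
#' @param p_pool Numeric vector of counterpart projections (non-empty).
#' @param k_tau Positive bandwidth.
#' @param pool_ids Optional counterpart ids (default: names of `p_pool`,
#'   else indices).
#' @return Object of class `"similarity_weights"`: list with `weights`
#'   (non-negative, summing to 1), `pool_ids`, `k_tau`.
#' @export
#' @examples
#' boltzmann_weights(0, c(0, 1), k_tau = 1)$weights  # c(0.731..., 0.268...)
boltzmann_weights <- function(p_i, p_pool, k_tau, pool_ids = NULL) {
  if (length(p_pool) == 0) stop("counterpart pool is empty")
  if (!is.numeric(k_tau) || length(k_tau) != 1L || !is.finite(k_tau) || k_tau <= 0) {
    stop("k_tau must be a positive number")
  }
  stopifnot(length(p_i) == 1L, is.finite(p_i), all(is.finite(p_pool)))
  if (is.null(pool_ids)) {
    pool_ids <- if (!is.null(names(p_pool))) names(p_pool) else as.character(seq_along(p_pool))
  }
  d <- abs(p_i - p_pool)
  w <- exp(-(d - min(d)) / k_tau)
  w <- w / sum(w)
  structure(list(weights = w, pool_ids = pool_ids, k_tau = k_tau),
            class = "similarity_weights")
}

#' Combine clinical and genetic similarity weights
#'
#' Elementwise product of the two normalized weight vectors over the same
#' counterpart pool. The product of two normalized vectors does not itself
#' sum to one; by default it is renormalized so that each treated
#' individual still contributes exactly one pseudo-observation to its Beta
#' posterior, preserving the Bernoulli-trial interpretation of the update
#' (`renormalize = FALSE` keeps the raw product).
#'
#' @param w_clinical,w_genetic `"similarity_weights"` over identical pools
#'   (same ids, same order).
#' @param renormalize Logical, default `TRUE`.
#' @return A `"similarity_weights"` object (with `k_tau = NA`).
#' @export
combine_weights <- function(w_clinical, w_genetic, renormalize = TRUE) {
  stopifnot(inherits(w_clinical, "similarity_weights"),
            inherits(w_genetic, "similarity_weights"))
  if (!identical(w_clinical$pool_ids, w_genetic$pool_ids)) {
    stop("clinical and genetic weights refer to different counterpart pools")
  }
  w <- w_clinical$weights * w_genetic$weights
  if (renormalize) w <- w / sum(w)
  structure(list(weights = w, pool_ids = w_clinical$pool_ids, k_tau = NA_real_),
            class = "similarity_weights")
}

# Adaptive bandwidth: empirical SD of the pool's projections; degenerate
# pools (all projections equal) get bandwidth 1, under which all distances
# are zero and the kernel is uniform anyway.
resolve_k_tau <- function(k_tau, p_pool) {
  if (identical(k_tau, "auto")) {
    s <- stats::sd(p_pool)
    if (!is.finite(s) || s < 1e-12) 1 else s
  } else {
    k_tau
  }
}

# Row-normalized weight matrix W[i, j] = exp(-|p_i - p_j|/k_tau) / rowsum,
# the batch form of boltzmann_weights used by the pipeline.
weight_matrix <- function(p_i_side, p_pool, k_tau) {
  D <- abs(outer(p_i_side, p_pool, "-"))
  D <- D - D[cbind(seq_len(nrow(D)), max.col(-D, ties.method = "first"))]
  W <- exp(-D / k_tau)
  W / rowSums(W)
}
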