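#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-squared statistic (1 df), accumulating
#' hypergeometric expected event counts over the distinct event times, with
#' the p-value from the chi-squared tail. Wraps `survival::survdiff`.
#'
#' @param time_a,event_a Survival outcome of group A.
#' @param time_b,event_b Survival outcome of group B.
#' @return List: `statistic`, `p_value`, and `direction` (+1 when group A
#'   has fewer events than expected, i.e. fares better; -1 when worse;
#'   0 when exactly as expected).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank test undefined: no events in either group")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(sd$exp[1] - sd$obs[1]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: reject the `j` smallest p-values where `j` is the
#' largest rank with `p_(j) <= j * fdr / m`; q-values are the standard
#' monotone cumulative-minimum transform (as in `p.adjust`).
#'
#' @param p_values Numeric vector in `[0, 1]` (`NA` allowed; never
#'   rejected).
#' @param fdr Target false discovery rate (default 0.05).
#' @return List: `q_values` (same length/order as input) and `rejected`
#'   (logical mask).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            fdr > 0, fdr < 1)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = !is.na(q) & q <= fdr)
}

#' Per-gene log-rank screen among treated patients
#'
#' The conventional comparator: for each gene, the treated patients are
#' split into mutation carriers and non-carriers and compared with a
#' log-rank test, after an optional 1:1 propensity-score matching step on
#' the clinical covariates to balance the covariate profile (the matching
#' is done once for the treated-vs-untreated contrast and reused across
#' genes; `per_gene_match` re-matches within every gene's carrier split
#' instead). P-values are Benjamini-Hochberg adjusted across all testable
#' genes, and the suggested list keeps the rejected genes whose carriers
#' fare better, ranked by p-value, truncated at `k`.
#'
#' @param cohort A `"csearch_cohort"` with both arms and a gene matrix.
#' @param fdr Target FDR (0.05 for the simulation benchmark; the
#'   real-data screen conventionally uses 0.01).
#' @param k Maximum number of suggested genes (default 10).
#' @param match Logical; apply propensity matching first (default `TRUE`).
#' @param caliper_sd Matching caliper in logit SD units (default 0.2).
#' @param per_gene_match Logical; match carriers to non-carriers within
#'   each gene on the clinical propensity instead (default `FALSE`).
#' @param min_carriers Minimum carriers (and non-carriers) among the
#'   treated for a gene to be testable (default 10): the log-rank
#'   chi-squared approximation is anti-conservative for very small groups,
#'   so rarer genes are skipped rather than tested on bad asymptotics.
#' @return Object of class `"logrank_result"`: data frame with one row per
#'   gene (`gene`, `statistic`, `p_value`, `q_value`, `rejected`,
#'   `direction`, `n_carriers`; untestable genes carry `NA`), with
#'   attribute `"suggested"` (character vector) and `"fdr"`.
#' @export
discover_logrank <- function(cohort, fdr = 0.05, k = 10, match = TRUE,
                             caliper_sd = 0.2, per_gene_match = FALSE,
                             min_carriers = 10) {
  stopifnot(inherits(cohort, "csearch_cohort"))
  stop_if_single_arm(cohort)
  if (is.null(cohort$G)) stop("discover_logrank needs a gene matrix")

  work <- cohort
  pmodel <- NULL
  if (match || per_gene_match) {
    pmodel <- fit_propensity(cohort, "clinical")
  }
  if (match && !per_gene_match) {
    work <- propensity_match(cohort, pmodel, caliper_sd = caliper_sd)
  }
  cl <- work$clinical
  treated <- which(cl$treatment == 1)
  Gt <- work$G[treated, , drop = FALSE]
  time <- cl$time[treated]
  event <- cl$event[treated]

  genes <- work$gene_names
  stat <- p <- rep(NA_real_, length(genes))
  dir <- rep(NA_real_, length(genes))
  n_carriers <- as.integer(colSums(Gt))
  skipped <- 0L
  for (j in seq_along(genes)) {
    carr <- Gt[, j] == 1
    if (sum(carr) < min_carriers || sum(!carr) < min_carriers) {
      skipped <- skipped + 1L; next
    }
    ia <- which(carr); ib <- which(!carr)
    if (per_gene_match) {
      # carrier-vs-noncarrier matching on the clinical propensity
      sub <- subset_cohort(work, treated)
      sub$clinical$treatment <- as.integer(carr)
      m <- tryCatch(propensity_match(sub, pmodel, caliper_sd = caliper_sd),
                    error = function(e) NULL)
      if (is.null(m)) { skipped <- skipped + 1L; next }
      mc <- m$clinical
      ia <- which(mc$treatment == 1); ib <- which(mc$treatment == 0)
      res <- tryCatch(logrank_test(mc$time[ia], mc$event[ia],
                                   mc$time[ib], mc$event[ib]),
                      error = function(e) NULL)
    } else {
      res <- tryCatch(logrank_test(time[ia], event[ia], time[ib], event[ib]),
                      error = function(e) NULL)
    }
    if (is.null(res)) { skipped <- skipped + 1L; next }
    stat[j] <- res$statistic
    p[j] <- res$p_value
    dir[j] <- res$direction
  }
  if (skipped > 0) {
    message(skipped, " gene(s) untestable (zero carriers or no events); skipped")
  }
  adj <- bh_adjust(p, fdr)
  out <- data.frame(gene = genes, statistic = stat, p_value = p,
                    q_value = adj$q_values, rejected = adj$rejected,
                    direction = dir, n_carriers = n_carriers,
                    stringsAsFactors = FALSE)
  cand <- which(out$rejected & out$direction > 0)
  suggested <- out$gene[cand[order(out$p_value[cand])]]
  suggested <- utils::head(suggested, k)
  attr(out, "suggested") <- suggested
  attr(out, "fdr") <- fdr
  class(out) <- c("logrank_result", "data.frame")
  out
}
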