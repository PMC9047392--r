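#' Number of true causal genes among the top-k suggestions
#' @param suggested Ordered character vector of suggested genes.
#' @param truth Character set of planted causal genes.
#' @param k Suggestion budget (default: length of `suggested`).
#' @return Integer in `[0, min(k, |truth|)]`.
#' @export
precision_at_k <- function(suggested, truth, k = length(suggested)) {
  length(intersect(utils::head(suggested, k), truth))
}

#' Five-fold precision of a discovery method on a simulated cohort
#'
#' Splits the cohort into `folds` disjoint subsets by stratified (treatment
#' x event) random assignment and runs the discovery method once per fold
#' on the complement of that fold (the standard cross-validation training
#' split, i.e. each run sees `(folds - 1) / folds` of the cohort), scoring
#' each run's top-k suggestions against the planted truth.
#'
#' @param simcohort A `"csearch_simcohort"` from [simulate_cohort()].
#' @param method `"csearch"` or `"logrank"`.
#' @param folds Number of folds (default 5).
#' @param k Suggestion budget (default 10).
#' @param seed Seed for the fold assignment (default 1).
#' @param scheme `"complement"` (default; run on each fold's complement)
#'   or `"fold"` (run on each fold subset itself).
#' @param config [csearch_config()] for the C-search runs.
#' @param fdr FDR for the log-rank runs (default 0.05).
#' @return Data frame with one row per fold: `n` (cohort size), `method`,
#'   `fold`, `n_used`, `true_positives_at_k`, `k`; failed folds carry `NA`
#'   and are excluded from the `"mean_precision"` attribute.
#' @export
crossval_precision <- function(simcohort, method = c("csearch", "logrank"),
                               folds = 5L, k = 10L, seed = 1L,
                               scheme = c("complement", "fold"),
                               config = csearch_config(k = k),
                               fdr = 0.05) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  stopifnot(inherits(simcohort, "csearch_simcohort"), folds >= 2)
  cohort <- simcohort$cohort
  truth <- simcohort$truth
  n <- n_individuals(cohort)

  assign_folds <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    f <- integer(n)
    strata <- interaction(cohort$clinical$treatment, cohort$clinical$event)
    for (s in levels(strata)) {
      idx <- which(strata == s)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })

  tp <- rep(NA_integer_, folds)
  n_used <- integer(folds)
  for (fold in seq_len(folds)) {
    idx <- if (scheme == "complement") which(assign_folds != fold) else which(assign_folds == fold)
    n_used[fold] <- length(idx)
    sub <- subset_cohort(cohort, idx)
    suggested <- tryCatch({
      if (method == "csearch") {
        run_csearch(sub, config)$suggested
      } else {
        attr(discover_logrank(sub, fdr = fdr, k = k), "suggested")
      }
    }, error = function(e) {
      warning("fold ", fold, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(suggested)) {
      tp[fold] <- precision_at_k(suggested, truth, k)
    }
  }
  out <- data.frame(n = n, method = method, fold = seq_len(folds),
                    n_used = n_used, true_positives_at_k = tp, k = k,
                    stringsAsFactors = FALSE)
  attr(out, "mean_precision") <- mean(tp, na.rm = TRUE)
  out
}

#' Discovery-versus-sample-size benchmark curves
#'
#' For each cohort size in the grid, simulates a cohort under the base
#' scenario (child seed per grid point) and records the per-fold precision
#' of each method, yielding the data behind a discovery-rate curve.
#'
#' @param n_grid Integer vector of cohort sizes.
#' @param methods Character subset of `c("csearch", "logrank")`.
#' @param folds Folds per cohort (default 5).
#' @param k Suggestion budget (default 10).
#' @param scenario Base [simulation_scenario()] (its `n` is overridden).
#' @param master_seed Master seed for the per-n child seeds and the fold
#'   assignment (default 1).
#' @param config,fdr Passed to [crossval_precision()].
#' @param path Optional TSV output path; a `<path>.config` snapshot is
#'   written alongside.
#' @return Data frame of per-fold records (rows = n x method x fold), with
#'   attribute `"summary"`: mean precision per n and method.
#' @export
discovery_curve <- function(n_grid, methods = c("csearch", "logrank"),
                            folds = 5L, k = 10L,
                            scenario = simulation_scenario(n = 1000L),
                            master_seed = 1L,
                            config = csearch_config(k = k), fdr = 0.05,
                            path = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- scenario_grid(n_grid, scenario, master_seed)
  rows <- list()
  for (i in seq_along(grid)) {
    sim <- simulate_cohort(grid[[i]])
    for (m in methods) {
      rows[[length(rows) + 1L]] <-
        crossval_precision(sim, m, folds = folds, k = k,
                           seed = child_seed(master_seed, 1000L + i),
                           config = config, fdr = fdr)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(true_positives_at_k ~ n + method, data = out,
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "mean_precision"
  attr(out, "summary") <- agg[order(agg$method, agg$n), ]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(config_snapshot_lines(c(list(master_seed = master_seed,
                                            folds = folds, k = k, fdr = fdr),
                                       unclass(config))),
               paste0(path, ".config"))
  }
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve with log-transformed pointwise confidence
#' band, via `survival::survfit`.
#'
#' @param time,event Survival outcome vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame: `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`, starting with the `time = 0, surv = 1` row.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) > 0, length(time) == length(event))
  f <- survival::survfit(survival::Surv(time, event) ~ 1,
                         conf.type = "log", conf.int = conf_level)
  out <- data.frame(time = c(0, f$time),
                    n_risk = c(length(time), f$n.risk),
                    n_event = c(0, f$n.event),
                    surv = c(1, f$surv),
                    lower = c(1, f$lower),
                    upper = c(1, f$upper))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier policy comparison for a causal gene set
#'
#' Partitions patients into the causal-gene group (carrying at least one
#' suggested gene) and the other-gene group and produces the six standard
#' contrasts: (a) causal vs other overall, (b) treated vs untreated within
#' the causal group, (c) treated vs untreated within the other group,
#' (d) causal vs other among the treated, (e) causal vs other among the
#' untreated, and (f) the optimal policy (treat carriers, don't treat
#' non-carriers) vs the opposite policy. Each contrast carries the two
#' product-limit curves and a log-rank p-value; curves are computed on the
#' propensity-matched cohort when `match = TRUE`.
#'
#' @param cohort A `"csearch_cohort"`.
#' @param causal_genes Non-empty character vector of suggested genes.
#' @param match Logical; 1:1 propensity matching on the clinical
#'   covariates before estimating the curves (default `TRUE`).
#' @param caliper_sd Matching caliper in logit SD units.
#' @return Object of class `"policy_curves"`: named list of contrasts, each
#'   a list with `label`, group labels/sizes, `km1`, `km2` (from
#'   [km_estimate()]), `statistic` and `p_value`. Contrasts with an empty
#'   side are skipped with a message.
#' @export
policy_comparison <- function(cohort, causal_genes, match = TRUE,
                              caliper_sd = 0.2) {
  stopifnot(length(causal_genes) >= 1)
  unknown <- setdiff(causal_genes, cohort$gene_names)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  work <- if (match) propensity_match(cohort, caliper_sd = caliper_sd) else cohort
  cl <- work$clinical
  causal <- rowSums(work$G[, causal_genes, drop = FALSE]) > 0
  treated <- cl$treatment == 1
  optimal <- (treated & causal) | (!treated & !causal)

  contrasts <- list(
    a = list(label = "causal vs other, all patients",
             g1 = causal, g2 = !causal, n1 = "causal", n2 = "other"),
    b = list(label = "treated vs untreated, causal-gene group",
             g1 = causal & treated, g2 = causal & !treated,
             n1 = "treated", n2 = "untreated"),
    c = list(label = "treated vs untreated, other-gene group",
             g1 = !causal & treated, g2 = !causal & !treated,
             n1 = "treated", n2 = "untreated"),
    d = list(label = "causal vs other, treated patients",
             g1 = causal & treated, g2 = !causal & treated,
             n1 = "causal", n2 = "other"),
    e = list(label = "causal vs other, untreated patients",
             g1 = causal & !treated, g2 = !causal & !treated,
             n1 = "causal", n2 = "other"),
    f = list(label = "optimal policy vs other policy",
             g1 = optimal, g2 = !optimal, n1 = "optimal", n2 = "other")
  )
  out <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (!any(ct$g1) || !any(ct$g2)) {
      message("contrast ", nm, " (", ct$label, ") skipped: empty group")
      next
    }
    lr <- tryCatch(
      logrank_test(cl$time[ct$g1], cl$event[ct$g1],
                   cl$time[ct$g2], cl$event[ct$g2]),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               direction = NA_real_))
    out[[nm]] <- list(
      label = ct$label,
      groups = c(ct$n1, ct$n2),
      n = c(sum(ct$g1), sum(ct$g2)),
      km1 = km_estimate(cl$time[ct$g1], cl$event[ct$g1]),
      km2 = km_estimate(cl$time[ct$g2], cl$event[ct$g2]),
      statistic = lr$statistic, p_value = lr$p_value,
      direction = lr$direction
    )
  }
  structure(out, class = "policy_curves")
}

#' @export
print.policy_curves <- function(x, ...) {
  cat("Kaplan-Meier policy comparison\n")
  for (nm in names(x)) {
    ct <- x[[nm]]
    cat(sprintf("  (%s) %s: %s n=%d vs %s n=%d, log-rank p = %.4g\n",
                nm, ct$label, ct$groups[1], ct$n[1],
                ct$groups[2], ct$n[2], ct$p_value))
  }
  invisible(x)
}
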