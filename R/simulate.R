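#' Define a simulation scenario
#'
#' Parameters of the benchmark generator: a cohort with i.i.d. binary gene
#' alterations, of which `n_causal` genes are planted positive treatment
#' modulators (they lower the hazard only in treated carriers), and
#' `n_hidden_confounders` standard-normal confounders that push both
#' treatment assignment and hazard. The confounders are withheld from the
#' discovery algorithms, which see only age, sex, treatment, the gene
#' matrix and the censored outcome.
#'
#' Event times are exponential with a log-linear hazard
#' \deqn{h_i = h_0 \exp(\beta_{age}(age_i-60) + \beta_{sex} sex_i +
#'   \beta_c^\top C_i + T_i(\beta_T + \gamma \sum_{k \in truth} g_{ik}) +
#'   m \sum_{k \in truth} g_{ik})}
#' and are administratively censored at `censor_time`.
#'
#' @param n Number of individuals.
#' @param n_genes Total genes (default 300).
#' @param n_causal Planted treatment modulators (default 10).
#' @param n_hidden_confounders Hidden confounders (default 10).
#' @param gene_prevalence Per-gene alteration rate (default 0.1).
#' @param baseline_hazard Baseline exponential hazard per time unit
#'   (default 0.02; with the default censoring horizon this yields roughly
#'   two-thirds observed events).
#' @param beta_treatment Main treatment log-hazard effect (default 0: the
#'   treatment helps only through the modulators).
#' @param gamma_modulation Treatment-interaction log-hazard per carried
#'   causal gene (default -1; negative = protective when treated).
#' @param beta_confounder Per-confounder log-hazard effect (default 0.3).
#' @param alpha_confounder Per-confounder treatment-assignment log-odds
#'   (default 0.3).
#' @param beta_age,beta_sex Log-hazard effects of the observed clinical
#'   covariates (defaults 0.03 per year from age 60, and 0.2).
#' @param causal_main_effect Optional prognostic (treatment-independent)
#'   log-hazard per carried causal gene (default 0).
#' @param treatment_offset Intercept of the assignment log-odds (default 0,
#'   i.e. about half the cohort treated).
#' @param censor_time Administrative censoring horizon (default 60 time
#'   units).
#' @param seed Integer seed; the generated cohort is a deterministic
#'   function of the scenario.
#'
#' @return A validated list of class `"csearch_scenario"`.
#' @seealso [simulate_cohort()], [scenario_grid()]
#' @export
simulation_scenario <- function(n,
                                n_genes = 300L,
                                n_causal = 10L,
                                n_hidden_confounders = 10L,
                                gene_prevalence = 0.1,
                                baseline_hazard = 0.02,
                                beta_treatment = 0,
                                gamma_modulation = -1,
                                beta_confounder = 0.3,
                                alpha_confounder = 0.3,
                                beta_age = 0.03,
                                beta_sex = 0.2,
                                causal_main_effect = 0,
                                treatment_offset = 0,
                                censor_time = 60,
                                seed = 1L) {
  stopifnot(
    n >= 2, n_genes >= 1, n_causal >= 0, n_causal <= n_genes,
    n_hidden_confounders >= 0,
    gene_prevalence > 0, gene_prevalence < 1,
    baseline_hazard > 0, censor_time > 0,
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(n = as.integer(n), n_genes = as.integer(n_genes),
         n_causal = as.integer(n_causal),
         n_hidden_confounders = as.integer(n_hidden_confounders),
         gene_prevalence = gene_prevalence,
         baseline_hazard = baseline_hazard,
         beta_treatment = beta_treatment,
         gamma_modulation = gamma_modulation,
         beta_confounder = beta_confounder,
         alpha_confounder = alpha_confounder,
         beta_age = beta_age, beta_sex = beta_sex,
         causal_main_effect = causal_main_effect,
         treatment_offset = treatment_offset,
         censor_time = censor_time,
         seed = as.integer(seed)),
    class = "csearch_scenario"
  )
}

#' Simulate a benchmark cohort with planted causal genes
#'
#' Draws a cohort under a [simulation_scenario()]: genes are i.i.d.
#' Bernoulli, hidden confounders standard normal, treatment assignment
#' logistic in the confounders, and event times exponential under the
#' scenario's log-linear hazard with administrative censoring. The same
#' scenario (including its seed) always yields a bit-identical cohort.
#'
#' @param scenario A `"csearch_scenario"`.
#' @return An object of class `"csearch_simcohort"`: list with `cohort`
#'   (a [make_cohort()] cohort exposing only age, sex, treatment, genes and
#'   outcome), `truth` (names of the planted causal genes), `confounders`
#'   (hidden matrix, for diagnostics only) and `scenario`.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "csearch_scenario"))
  sc <- scenario
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(sc$seed)

  n <- sc$n
  gene_names <- sprintf("g%03d", seq_len(sc$n_genes))
  G <- matrix(stats::rbinom(n * sc$n_genes, 1L, sc$gene_prevalence),
              nrow = n, dimnames = list(NULL, gene_names))
  truth <- sort(sample(gene_names, sc$n_causal))
  causal_load <- if (sc$n_causal > 0) {
    rowSums(G[, truth, drop = FALSE])
  } else {
    rep(0, n)
  }

  C <- matrix(stats::rnorm(n * sc$n_hidden_confounders),
              nrow = n)
  conf_assign <- if (sc$n_hidden_confounders > 0) {
    drop(C %*% rep(sc$alpha_confounder, sc$n_hidden_confounders))
  } else rep(0, n)
  conf_hazard <- if (sc$n_hidden_confounders > 0) {
    drop(C %*% rep(sc$beta_confounder, sc$n_hidden_confounders))
  } else rep(0, n)

  age <- stats::rnorm(n, mean = 60, sd = 10)
  sex <- stats::rbinom(n, 1L, 0.5)
  treatment <- stats::rbinom(n, 1L, stats::plogis(sc$treatment_offset + conf_assign))

  log_hazard <- log(sc$baseline_hazard) +
    sc$beta_age * (age - 60) +
    sc$beta_sex * sex +
    conf_hazard +
    treatment * (sc$beta_treatment + sc$gamma_modulation * causal_load) +
    sc$causal_main_effect * causal_load
  event_time <- stats::rexp(n, rate = exp(log_hazard))
  time <- pmin(event_time, sc$censor_time)
  event <- as.integer(event_time <= sc$censor_time)

  if (sum(event) == 0L) {
    stop("degenerate scenario: no observed events (baseline_hazard ",
         sc$baseline_hazard, ", censor_time ", sc$censor_time, ")")
  }
  if (all(treatment == 1L) || all(treatment == 0L)) {
    stop("degenerate scenario: single treatment arm (treatment_offset ",
         sc$treatment_offset, ")")
  }

  clinical <- data.frame(
    id = sprintf("s%05d", seq_len(n)),
    age = age, sex = sex, treatment = treatment,
    time = time, event = event,
    stringsAsFactors = FALSE
  )
  attr(clinical, "covariate_names") <- c("age", "sex")
  mutations <- t(G)
  colnames(mutations) <- clinical$id
  cohort <- make_cohort(clinical, mutations, covariate_names = c("age", "sex"))

  structure(
    list(cohort = cohort, truth = truth, confounders = C, scenario = sc),
    class = "csearch_simcohort"
  )
}

#' @export
print.csearch_simcohort <- function(x, ...) {
  cat(sprintf("Simulated cohort (seed %d): %d planted causal genes\n",
              x$scenario$seed, length(x$truth)))
  print(x$cohort)
  invisible(x)
}

#' Scenario grid over cohort sizes
#'
#' Clones a base scenario across a grid of sample sizes, deriving one
#' reproducible child seed per grid point from a master seed.
#'
#' @param n_values Integer vector of cohort sizes. Default: the benchmark
#'   grid 100, 200, 500, 1000, 1500, 2000, 2500, 3000, 3500, 4000.
#' @param scenario Base `"csearch_scenario"` whose non-`n` parameters are
#'   reused (default: `simulation_scenario(n = 1000)`).
#' @param master_seed Integer master seed for the child-seed stream
#'   (default: the base scenario's seed).
#' @return List of `"csearch_scenario"` objects, one per `n`.
#' @export
scenario_grid <- function(n_values = c(100L, 200L, 500L, 1000L, 1500L,
                                       2000L, 2500L, 3000L, 3500L, 4000L),
                          scenario = simulation_scenario(n = 1000L),
                          master_seed = NULL) {
  stopifnot(length(n_values) >= 1, all(n_values >= 2))
  if (is.null(master_seed)) master_seed <- scenario$seed
  lapply(seq_along(n_values), function(i) {
    sc <- scenario
    sc$n <- as.integer(n_values[i])
    sc$seed <- child_seed(master_seed, i)
    sc
  })
}

# Deterministic child seed: a fixed multiplicative hash of (master, index),
# kept inside 32-bit integer range.
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 104729) %% 2147483647)
}
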