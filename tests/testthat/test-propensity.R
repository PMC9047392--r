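make_propensity_cohort <- function(n, beta_x = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  clinical <- data.frame(id = sprintf("i%04d", 1:n),
                         x = x, sex = rbinom(n, 1, 0.5),
                         treatment = rbinom(n, 1, plogis(beta_x * x)),
                         time = rexp(n, 0.05), event = 1L)
  make_cohort(clinical, covariate_names = c("x", "sex"))
}

test_that("null assignment yields propensities near one half", {
  coh <- make_propensity_cohort(2000, beta_x = 0, seed = 31)
  m <- fit_propensity(coh, "clinical")
  expect_lt(mean(abs(m$fitted - 0.5)), 0.03)
  expect_lt(max(abs(m$fitted - 0.5)), 0.1)
})

test_that("assignment coefficient is recovered within 3 SE", {
  coh <- make_propensity_cohort(2000, beta_x = 2, seed = 32)
  m <- suppressMessages(fit_propensity(coh, "clinical"))
  # independent refit for the standard error
  f <- glm(treatment ~ x + sex, data = coh$clinical, family = binomial())
  se <- sqrt(diag(vcov(f)))[["x"]]
  expect_lt(abs(m$coefficients[["x"]] - 2), 3 * se)
})

test_that("constant covariates are dropped, leaving an intercept fit", {
  coh <- make_propensity_cohort(200, seed = 33)
  coh$clinical$x <- 1
  expect_warning(m <- fit_propensity(coh, "clinical"), "constant")
  expect_equal(unname(m$coefficients["x"]), 0)
  # both columns constant: intercept-only fit at the empirical rate
  coh$clinical$sex <- 0
  expect_warning(m2 <- fit_propensity(coh, "clinical"), "constant")
  expect_equal(length(unique(m2$fitted)), 1L)
  expect_equal(unname(m2$fitted[1]), mean(coh$clinical$treatment))
})

test_that("propensities are clipped into the declared bounds", {
  coh <- make_propensity_cohort(500, beta_x = 4, seed = 34)
  m <- suppressMessages(fit_propensity(coh, "clinical"))
  expect_true(all(m$fitted >= 0.05 & m$fitted <= 0.95))
  expect_gt(m$n_clipped, 0)
})

test_that("IPW gene posterior matches hand arithmetic", {
  # e(V) = e(G) = 0.5, Pw = (0.8, 0.6): Beta(1 + 1.4/0.25, 1 + 0.6/0.25)
  post <- ipw_gene_posterior(c(0.8, 0.6), c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(post$alpha, 6.6)
  expect_equal(post$beta, 3.4)

  # stabilized: totals rescale to the number of carriers, mean unchanged
  st <- ipw_gene_posterior(c(0.8, 0.6), c(0.5, 0.5), c(0.5, 0.5),
                           stabilized = TRUE)
  expect_equal((st$alpha - 1) + (st$beta - 1), 2)
  expect_equal(posterior_mean(beta_posterior(st$alpha - 1 + 1e-12, st$beta - 1 + 1e-12)),
               posterior_mean(beta_posterior(5.6, 2.4)), tolerance = 1e-9)

  # empty carrier list returns the prior
  pr <- beta_posterior(2, 3)
  expect_identical(ipw_gene_posterior(numeric(0), numeric(0), numeric(0),
                                      prior = pr), pr)
})

test_that("stabilized IPW at constant 1/2 propensity equals the unweighted update", {
  set.seed(35)
  pw <- runif(20)
  e <- rep(0.5, 20)
  st <- ipw_gene_posterior(pw, e, e, stabilized = TRUE)
  plain <- beta_posterior(1 + sum(pw), 1 + 20 - sum(pw))
  expect_equal(st$alpha, plain$alpha, tolerance = 1e-9)
  expect_equal(st$beta, plain$beta, tolerance = 1e-9)
})

test_that("greedy matching pairs nearest logits deterministically", {
  clinical <- data.frame(id = c("t1", "t2", "u1", "u2"),
                         age = 60, sex = 0,
                         treatment = c(1L, 1L, 0L, 0L),
                         time = c(5, 6, 7, 8), event = 1L)
  coh <- make_cohort(clinical, covariate_names = c("age", "sex"))
  model <- structure(list(block = "clinical",
                          coefficients = c(age = 0, sex = 0),
                          intercept = 0, clip = c(0.001, 0.999),
                          fitted = NULL, n_clipped = 0L),
                     class = "propensity_model")
  # inject logits (0, 5) vs (0.1, 5.1) through a handcrafted model
  model$coefficients <- c(age = 1, sex = 0)
  coh$clinical$age <- c(0, 5, 0.1, 5.1)
  m <- propensity_match(coh, model, caliper_sd = 100)
  pairs <- attr(m, "pairs")
  expect_equal(pairs$treated_id, c("t1", "t2"))
  expect_equal(pairs$untreated_id, c("u1", "u2"))

  # identical propensities: full pairing up to the smaller arm
  coh$clinical$age <- 1
  m2 <- propensity_match(coh, model, caliper_sd = 0.2)
  expect_equal(nrow(attr(m2, "pairs")), 2)

  # a treated far outside the caliper is excluded and logged
  coh$clinical$age <- c(0, 50, 0.1, 0.2)
  expect_message(m3 <- propensity_match(coh, model, caliper_sd = 0.2),
                 "unmatched")
  expect_equal(attr(m3, "unmatched_treated"), "t2")
})

test_that("matching on a correct model balances the covariates", {
  # assignment driven by x: after matching the standardized mean
  # difference of x between arms should collapse below 0.1
  coh <- make_propensity_cohort(2000, beta_x = 1, seed = 36)
  cl <- coh$clinical
  smd <- function(d) {
    (mean(d$x[d$treatment == 1]) - mean(d$x[d$treatment == 0])) / sd(d$x)
  }
  expect_gt(abs(smd(cl)), 0.3)
  m <- suppressMessages(propensity_match(coh))
  expect_lt(abs(smd(m$clinical)), 0.1)
})
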