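test_that("pairwise scoring enumerates all censoring patterns correctly", {
  # both events
  expect_equal(compare_pair(10, 1, 5, 1), 1)
  expect_equal(compare_pair(5, 1, 10, 1), 0)
  expect_equal(compare_pair(7, 1, 7, 1), 0.5)   # tie in event times
  # i censored, j event
  expect_equal(compare_pair(10, 0, 5, 1), 1)    # i known to outlive j
  expect_equal(compare_pair(5, 0, 5, 1), 1)     # alive at j's death
  expect_true(is.na(compare_pair(3, 0, 5, 1)))  # order unknowable
  # i event, j censored
  expect_equal(compare_pair(5, 1, 10, 0), 0)
  expect_equal(compare_pair(5, 1, 5, 0), 0)
  expect_true(is.na(compare_pair(5, 1, 3, 0)))
  # both censored
  expect_true(is.na(compare_pair(5, 0, 10, 0)))
  expect_error(compare_pair(-1, 1, 5, 1), "negative")
})

test_that("single-pair and two-pair posteriors match hand arithmetic", {
  one <- structure(list(weights = 1, pool_ids = "j1", k_tau = 1),
                   class = "similarity_weights")
  wp <- individual_win_posterior(1, one, one)
  expect_equal(wp$posterior$alpha, 2)
  expect_equal(wp$posterior$beta, 1)
  expect_equal(wp$pw, 2 / 3)

  wv <- boltzmann_weights(0, c(0, 1), 1)   # (0.73106, 0.26894)
  wu <- structure(list(weights = c(0.5, 0.5), pool_ids = wv$pool_ids,
                       k_tau = 1), class = "similarity_weights")
  wp2 <- individual_win_posterior(c(1, 0), wv, wu)
  expect_equal(wp2$posterior$alpha, 1.73106, tolerance = 1e-5)
  expect_equal(wp2$posterior$beta, 1.26894, tolerance = 1e-5)
  expect_equal(wp2$pw, 0.5770, tolerance = 1e-4)
})

test_that("all-incomparable evidence returns the flagged prior", {
  w <- boltzmann_weights(0, c(0, 1), 1)
  wp <- individual_win_posterior(c(NA, NA), w, w,
                                 prior = beta_posterior(1, 1))
  expect_true(wp$no_evidence)
  expect_equal(wp$posterior$alpha, 1)
  expect_equal(wp$posterior$beta, 1)
})

test_that("each individual contributes exactly one pseudo-observation", {
  # conservation property under renormalized combining, random fixtures
  set.seed(21)
  for (rep in 1:25) {
    nj <- sample(2:15, 1)
    s <- sample(c(0, 0.5, 1, NA), nj, replace = TRUE)
    if (all(is.na(s))) s[1] <- 1
    wv <- boltzmann_weights(rnorm(1), rnorm(nj), runif(1, 0.1, 3))
    wg <- boltzmann_weights(rnorm(1), rnorm(nj), runif(1, 0.1, 3),
                            pool_ids = wv$pool_ids)
    wp <- individual_win_posterior(s, wv, wg)
    expect_equal(wp$posterior$alpha + wp$posterior$beta - 2, 1,
                 tolerance = 1e-9)
    expect_equal(wp$n_effective, 1, tolerance = 1e-9)
  }
})

test_that("uniform weights reduce the posterior to the censored WMW oracle", {
  # 10 treated x 10 untreated with censoring; huge bandwidth makes the
  # kernel uniform, so the posterior mean must equal the brute-force
  # weighted Wilcoxon-Mann-Whitney fraction over comparable pairs
  coh <- toy_cohort(nt = 10, nu = 10, n_genes = 5, censor = TRUE, seed = 22)
  bv <- fit_basal(coh, "clinical")
  bg <- fit_basal(coh, "genetic")
  wp <- all_win_posteriors(coh, bv, bg, k_tau = 1e9)
  cl <- coh$clinical
  tr <- which(cl$treatment == 1); un <- which(cl$treatment == 0)
  for (r in seq_along(tr)) {
    i <- tr[r]
    sbar <- oracle_win_fraction(cl$time[i], cl$event[i],
                                cl$time[un], cl$event[un])
    expect_equal(wp$alpha[r], 1 + sbar, tolerance = 1e-9)
    expect_equal(wp$pw[r], (1 + sbar) / 3, tolerance = 1e-9)
  }
})

test_that("non-uniform weighted posteriors match the brute-force oracle", {
  coh <- toy_cohort(nt = 8, nu = 10, n_genes = 5, censor = TRUE, seed = 23)
  bv <- fit_basal(coh, "clinical")
  bg <- fit_basal(coh, "genetic")
  kt <- 0.5
  wp <- all_win_posteriors(coh, bv, bg, k_tau = kt)
  cl <- coh$clinical
  pv <- project(bv, coh); pg <- project(bg, coh)
  tr <- which(cl$treatment == 1); un <- which(cl$treatment == 0)
  for (r in seq_along(tr)) {
    i <- tr[r]
    wv <- boltzmann_weights(pv[i], pv[un], kt)$weights
    wg <- boltzmann_weights(pg[i], pg[un], kt)$weights
    w <- wv * wg
    sbar <- oracle_win_fraction(cl$time[i], cl$event[i],
                                cl$time[un], cl$event[un], w = w)
    expect_equal(wp$pw[r], (1 + sbar) / 3, tolerance = 1e-9)
  }
})

test_that("dominant treated arm pushes every posterior mean above 1/2", {
  n <- 6
  clinical <- data.frame(id = sprintf("p%02d", 1:(2 * n)),
                         age = 55 + seq_len(2 * n), sex = rep(0:1, n),
                         treatment = rep(c(1L, 0L), each = n),
                         time = c(100 + 1:n, 1:n),
                         event = 1L)
  mut <- matrix(rep(c(0L, 1L), n), 1, 2 * n,
                dimnames = list("G1", clinical$id))
  coh <- make_cohort(clinical, mut, covariate_names = c("age", "sex"))
  bv <- fit_basal(coh, "clinical")
  bg <- fit_basal(coh, "genetic")
  wp <- all_win_posteriors(coh, bv, bg)
  expect_true(all(wp$pw > 0.5))
})

test_that("direction swap reflects aggregate win probability around 1/2", {
  # no censoring + uniform weights: treated-vs-untreated and
  # untreated-vs-treated mean win fractions are complementary
  coh <- toy_cohort(nt = 7, nu = 7, n_genes = 4, censor = FALSE, seed = 24)
  bv <- fit_basal(coh, "clinical")
  bg <- fit_basal(coh, "genetic")
  fwd <- all_win_posteriors(coh, bv, bg, k_tau = 1e9)
  rev <- all_win_posteriors(coh, bv, bg, k_tau = 1e9,
                            direction = "untreated_vs_treated")
  sbar_fwd <- mean(fwd$alpha - 1)
  sbar_rev <- mean(rev$alpha - 1)
  expect_equal(sbar_fwd + sbar_rev, 1, tolerance = 1e-9)
})

test_that("permuting the pool never changes a posterior", {
  coh <- toy_cohort(nt = 6, nu = 9, n_genes = 4, censor = TRUE, seed = 25)
  bv <- fit_basal(coh, "clinical")
  bg <- fit_basal(coh, "genetic")
  wp1 <- all_win_posteriors(coh, bv, bg)
  set.seed(1)
  un <- which(coh$clinical$treatment == 0)
  perm <- c(which(coh$clinical$treatment == 1), sample(un))
  wp2 <- all_win_posteriors(subset_cohort(coh, perm), bv, bg)
  m1 <- wp1[order(wp1$id), ]; m2 <- wp2[order(wp2$id), ]
  expect_equal(m1$alpha, m2$alpha, tolerance = 1e-12)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-12)
})

test_that("single-arm cohorts are rejected", {
  coh <- toy_cohort(nt = 5, nu = 5, n_genes = 3)
  coh$clinical$treatment <- 1L
  bv <- list()
  expect_error(all_win_posteriors(coh, bv, bv), "both treated and untreated")
})
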