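# Fixture builders shared across the suite. Everything is generated in
# code; files go to tempdir().

# Minimal deterministic cohort: nt treated + nu untreated, optional genes.
toy_cohort <- function(nt = 5, nu = 5, n_genes = 0, seed = 1,
                       censor = FALSE) {
  set.seed(seed)
  n <- nt + nu
  clinical <- data.frame(
    id = sprintf("p%02d", seq_len(n)),
    age = round(rnorm(n, 60, 8), 1),
    sex = rbinom(n, 1, 0.5),
    treatment = rep(c(1L, 0L), c(nt, nu)),
    time = round(rexp(n, 0.05), 2),
    event = if (censor) rbinom(n, 1, 0.7) else 1L,
    stringsAsFactors = FALSE
  )
  mut <- NULL
  if (n_genes > 0) {
    mut <- matrix(rbinom(n_genes * n, 1L, 0.3), n_genes, n,
                  dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                  clinical$id))
  }
  make_cohort(clinical, mut, covariate_names = c("age", "sex"))
}

write_clinical_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# Brute-force weighted win fraction: the independent oracle for the
# pairwise stage. Scores every (i, j) pair by direct case analysis and
# averages with the supplied weights over comparable pairs.
oracle_win_fraction <- function(ti, ei, tj, ej, w = NULL) {
  nj <- length(tj)
  if (is.null(w)) w <- rep(1 / nj, nj)
  s <- numeric(nj); comp <- logical(nj)
  for (j in seq_len(nj)) {
    if (ei == 1 && ej[j] == 1) {
      comp[j] <- TRUE
      s[j] <- if (ti > tj[j]) 1 else if (ti < tj[j]) 0 else 0.5
    } else if (ei == 0 && ej[j] == 1 && ti >= tj[j]) {
      comp[j] <- TRUE; s[j] <- 1
    } else if (ei == 1 && ej[j] == 0 && tj[j] >= ti) {
      comp[j] <- TRUE; s[j] <- 0
    }
  }
  if (!any(comp)) return(NA_real_)
  sum(s[comp] * w[comp]) / sum(w[comp])
}

# Textbook two-group log-rank oracle: hypergeometric expected-event
# accumulation over distinct event times.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  taus <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tau in taus) {
    at_risk <- time >= tau
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(event == 1 & time == tau)
    d_a <- sum(event == 1 & time == tau & grp_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(statistic = chisq,
       p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# Hand step-up BH oracle.
oracle_bh_reject <- function(p, fdr) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * fdr / m)
  rej <- logical(m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}

# Hand product-limit oracle.
oracle_km <- function(time, event) {
  taus <- sort(unique(time[event == 1]))
  surv <- numeric(length(taus))
  s <- 1
  for (i in seq_along(taus)) {
    n <- sum(time >= taus[i])
    d <- sum(event == 1 & time == taus[i])
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = taus, surv = surv)
}
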