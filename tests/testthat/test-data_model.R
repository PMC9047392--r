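test_that("clinical table round-trips with missingness preserved", {
  df <- data.frame(id = c("a", "b", "c"),
                   age = c(50, NA, 70), sex = c(0, 1, 1),
                   treatment = c(1, 0, 1),
                   time = c(10.5, 20, 30), event = c(1, 0, 1))
  path <- write_clinical_fixture(df)
  got <- read_clinical_table(path)
  expect_s3_class(got, "csearch_clinical")
  expect_equal(nrow(got), 3)
  expect_equal(got$id, df$id)
  expect_equal(got$age, df$age)     # NA retained, row not dropped
  expect_equal(got$time, df$time)
  expect_equal(attr(got, "covariate_names"), c("age", "sex"))
})

test_that("declared event/treatment maps decode cBioPortal-style codings", {
  df <- data.frame(id = c("a", "b"), age = c(50, 60), sex = c(0, 1),
                   treatment = c("YES", "NO"),
                   time = c(10, 20),
                   event = c("1:DECEASED", "0:LIVING"))
  path <- write_clinical_fixture(df)
  got <- read_clinical_table(
    path,
    treatment_map = c(YES = 1, NO = 0),
    event_map = c("1:DECEASED" = 1, "0:LIVING" = 0))
  expect_equal(got$event, c(1, 0))
  expect_equal(got$treatment, c(1, 0))
  # without the map the same file is a parse error naming the row
  expect_error(read_clinical_table(path), "treatment.*row 1|row 1")
})

test_that("schema errors name the missing column", {
  df <- data.frame(id = c("a"), age = 1, sex = 0, time = 1, event = 1)
  path <- write_clinical_fixture(df)
  expect_error(read_clinical_table(path), "treatment")
})

test_that("mutation matrix reader enforces the binary dialect", {
  mat <- data.frame(gene = c("TP53", "KRAS"), s1 = c(0L, 0L), s2 = c(0L, 0L))
  path <- tempfile(fileext = ".tsv")
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_mutation_matrix(path)
  expect_identical(unname(got), matrix(0L, 2, 2))
  expect_equal(rownames(got), c("TP53", "KRAS"))

  mat$s2[1] <- 2L
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(got2 <- read_mutation_matrix(path), "coerced")
  expect_equal(got2["TP53", "s2"], 1L)
})

test_that("cohort assembly aligns by id, invariant to column order", {
  clin <- data.frame(id = c("s1", "s2", "s3"), age = c(50, 60, 70),
                     sex = c(0, 1, 0), treatment = c(1, 0, 1),
                     time = c(5, 10, 15), event = c(1, 1, 0))
  mut <- matrix(c(1L, 0L, 0L, 0L, 1L, 1L), 2, 3,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  coh1 <- make_cohort(clin, mut)
  coh2 <- make_cohort(clin, mut[, c("s3", "s1", "s2")])  # shuffled columns
  expect_identical(coh1$G, coh2$G)
  expect_equal(coh1$G["s1", ], c(A = 1L, B = 0L))
  # a clinical sample without genetic profile is a hard error
  expect_error(make_cohort(clin, mut[, c("s1", "s2")]), "s3")
})

test_that("MAF-like records collapse idempotently to a binary matrix", {
  rec1 <- data.frame(Tumor_Sample_Barcode = "s1", Hugo_Symbol = "TP53")
  m1 <- maf_to_matrix(rec1, samples = c("s1", "s2"))
  expect_identical(m1["TP53", ], c(s1 = 1L, s2 = 0L))

  rec2 <- rbind(rec1, rec1)  # duplicates are idempotent
  expect_identical(maf_to_matrix(rec2, samples = c("s1", "s2")), m1)

  rec3 <- data.frame(
    Tumor_Sample_Barcode = c("s1", "s1", "s2", "s2"),
    Hugo_Symbol = c("TP53", "KRAS", "KRAS", "EGFR"))
  m3 <- maf_to_matrix(rec3)
  expect_identical(
    m3,
    matrix(c(0L, 1L, 1L, 1L, 1L, 0L), 3, 2,
           dimnames = list(c("EGFR", "KRAS", "TP53"), c("s1", "s2"))))
})

test_that("complete-case filter bookkeeping is exact", {
  df <- data.frame(id = sprintf("p%d", 1:5),
                   age = c(50, NA, 60, NA, 70), sex = 0,
                   treatment = c(1, 0, 1, 0, 1),
                   time = 1:5, event = 1)
  attr(df, "covariate_names") <- c("age", "sex")
  got <- suppressMessages(filter_complete_cases(df))
  expect_equal(unname(attr(got, "counts")), c(5, 2, 3))
  expect_equal(got$id, c("p1", "p3", "p5"))

  # no missingness: identity
  full <- df[c(1, 3, 5), ]
  attr(full, "covariate_names") <- c("age", "sex")
  got2 <- suppressMessages(filter_complete_cases(full))
  expect_equal(got2$id, full$id)
  expect_equal(unname(attr(got2, "counts")), c(3, 0, 3))

  # all rows removed is an error
  bad <- df; bad$age <- NA
  attr(bad, "covariate_names") <- c("age", "sex")
  expect_error(suppressMessages(filter_complete_cases(bad)), "every record")
})

test_that("complete-case counts always partition the input", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    df <- data.frame(id = sprintf("p%d", 1:n),
                     age = ifelse(runif(n) < 0.3, NA, rnorm(n, 60)),
                     sex = rbinom(n, 1, 0.5),
                     treatment = rbinom(n, 1, 0.5),
                     time = rexp(n), event = rbinom(n, 1, 0.5))
    attr(df, "covariate_names") <- c("age", "sex")
    got <- tryCatch(suppressMessages(filter_complete_cases(df)),
                    error = function(e) NULL)
    if (is.null(got)) { expect_true(all(is.na(df$age))); next }
    cnt <- attr(got, "counts")
    expect_equal(unname(cnt["input"]), n)
    expect_equal(unname(cnt["omitted"] + cnt["retained"]), n)
  }
})

test_that("cohort write/read round-trip reproduces the cohort", {
  coh <- toy_cohort(nt = 4, nu = 4, n_genes = 6, censor = TRUE)
  cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_cohort(coh, cp, mp)
  clin <- read_clinical_table(cp)
  mut <- read_mutation_matrix(mp)
  coh2 <- make_cohort(clin, mut)
  expect_equal(coh2$clinical$id, coh$clinical$id)
  expect_equal(coh2$clinical$time, coh$clinical$time)
  expect_identical(coh2$G, coh$G)
  expect_equal(coh2$gene_names, coh$gene_names)
})
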