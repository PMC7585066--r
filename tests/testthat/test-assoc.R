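test_that("residualization is exact OLS with the documented edge behaviour", {
  set.seed(20)
  y <- rnorm(50)
  # intercept only: centering
  expect_equal(residualize(y, NULL), y - mean(y), tolerance = 1e-12)
  expect_equal(residualize(y, data.frame()), y - mean(y), tolerance = 1e-12)

  # residuals orthogonal to numeric and categorical covariates
  covs <- data.frame(age = runif(50, 40, 90),
                     sex = sample(c("F", "M"), 50, TRUE))
  y2 <- 2 * covs$age + rnorm(50)
  res <- residualize(y2, covs)
  expect_lt(abs(cor(res, covs$age)), 1e-12)
  X <- model.matrix(~ sex, covs)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  # single-level categorical dropped with warning
  covs$cohort <- "onlylevel"
  expect_warning(res2 <- residualize(y2, covs), "single level")
  expect_equal(res2, res, tolerance = 1e-12)

  # collinear design errors with the offending columns named
  covs2 <- data.frame(a = 1:50, b = 2 * (1:50))
  expect_error(residualize(y, covs2), "collinear.*b")

  # listwise deletion keeps alignment
  covs3 <- data.frame(age = c(NA, runif(49, 40, 90)))
  res3 <- residualize(y, covs3)
  expect_true(is.na(res3[1]))
  expect_equal(sum(is.na(res3)), 1L)
})

test_that("bicor matches its literal formula transcription", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(8:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    if (i %% 3 == 0) y[sample(n, 1)] <- 50  # contaminated pair
    expect_equal(bicor(x, y), oracle_bicor(x, y), tolerance = 1e-12)
  }
})

test_that("bicor is affine-equivariant and robust to a single outlier", {
  set.seed(22)
  x <- rnorm(20)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, 3 * x + 2), 1, tolerance = 1e-12)

  x10 <- 1:10
  y10 <- c(1:9, 100)
  r_bicor <- bicor(x10, y10)
  expect_equal(r_bicor, oracle_bicor(x10, y10), tolerance = 1e-12)
  # the outlier drags Pearson down; bicor stays near the clean value
  expect_gt(r_bicor, cor(x10, y10))

  # zero MAD: fall back to mean-centering with a warning (Pearson-style)
  xc <- c(rep(1, 8), 2, 3)
  y <- rnorm(10)
  expect_warning(r <- bicor(xc, y), "mean-centering")
  yt <- y - median(y)
  u <- yt / (9 * median(abs(yt)))
  w <- (1 - u^2)^2 * (abs(u) < 1)
  expect_equal(r, sum((xc - mean(xc)) * yt * w) /
                 (sqrt(sum((xc - mean(xc))^2)) * sqrt(sum((yt * w)^2))),
               tolerance = 1e-12)
})

test_that("the correlation test follows the Student-t mapping", {
  # symmetric construction gives r = 0 exactly: p must be 1
  x <- c(-2, -1, 0, 1, 2)
  y <- c(4, 1, 0, 1, 4)
  row <- bicor_test(x, y)
  expect_equal(row$r, 0, tolerance = 1e-12)
  expect_equal(row$p, 1, tolerance = 1e-12)

  # r = 0.5, n = 12: t = 0.5*sqrt(10/0.75), df = 10
  p_wanted <- 2 * pt(-0.5 * sqrt(10 / 0.75), df = 10)
  expect_equal(semload:::cor_t_pvalue(0.5, 12), p_wanted, tolerance = 1e-12)

  # p strictly decreases with n at fixed r
  ps <- vapply(c(10, 20, 40, 80), function(n) semload:::cor_t_pvalue(0.5, n),
               numeric(1))
  expect_true(all(diff(ps) < 0))

  # printed bisulfite-QC anchor: r = -0.085 at n = 237 maps to p ~ 0.194
  expect_equal(semload:::cor_t_pvalue(-0.085, 237), 0.194, tolerance = 0.01)
})

test_that("cohort association recovers a sex-independent effect in both strata", {
  co <- simulate_cohort(sim_config(n_samples = 400, n_probes = 2000, seed = 30,
                                   gamma_age = log(2) / 50, gamma_acc = 0))
  calls <- call_sems(co$beta, compute_fences(co$beta, 3))
  d <- merge(co$samples, compute_eml(calls), by = "sample_id")
  rows <- cohort_association(d, outcome = "log_eml", targets = "age",
                             covariates = c("age", "sex", "ethnicity"),
                             group_by = "sex", cohort = "sim")
  expect_setequal(rows$stratum, c("F", "M"))
  expect_true(all(rows$r > 0))
  expect_true(all(rows$p < 0.01))
})

test_that("sign splitting strata and small-stratum flags behave", {
  set.seed(31)
  d <- data.frame(log_eml = rnorm(40), age = runif(40, 40, 90),
                  accel = abs(rnorm(40)))  # all accelerations positive
  rows <- cohort_association(d, "log_eml", targets = "age",
                             sign_split = "accel")
  dec <- rows[rows$stratum == "deceleration", ]
  expect_true(dec$size_flag)
  expect_true(is.na(dec$r))
  acc <- rows[rows$stratum == "acceleration", ]
  expect_false(acc$size_flag)
  expect_equal(acc$n, 40L)
})

test_that("Stouffer meta-analysis reproduces the printed worked examples", {
  m_age <- stouffer_meta(printed_rows(c(0.244, 0.104, 0.145, 0.176)))
  expect_equal(round(m_age$meta_r, 3), 0.171)
  expect_equal(m_age$total_n, 6388)

  m_han <- stouffer_meta(printed_rows(c(0.225, 0.156, 0.148, 0.095)))
  expect_equal(round(m_han$meta_r, 3), 0.179)

  # all-null input: meta r 0, meta p 1
  m0 <- stouffer_meta(data.frame(r = c(0, 0), n = c(100, 200), p = c(1, 1)))
  expect_equal(m0$meta_r, 0)
  expect_equal(m0$meta_p, 1)

  # single cohort: meta p equals the cohort p
  one <- data.frame(r = 0.3, n = 50, p = 0.033)
  expect_equal(stouffer_meta(one)$meta_p, 0.033, tolerance = 1e-9)

  expect_error(stouffer_meta(data.frame(r = 0.1, n = NA)), "missing cohort size")
})

test_that("meta p is order-invariant and shrinks toward null with a null cohort", {
  rows <- printed_rows(c(0.244, 0.104, 0.145, 0.176),
                       p = c(7.15e-33, 1.73e-6, 1.50e-9, 6.45e-3))
  m1 <- stouffer_meta(rows)
  m2 <- stouffer_meta(rows[c(3, 1, 4, 2), ])
  expect_equal(m1$meta_p, m2$meta_p, tolerance = 1e-12)
  expect_equal(m1$meta_r, m2$meta_r, tolerance = 1e-12)

  with_null <- rbind(rows, data.frame(cohort = "null", r = 0, n = 1000, p = 1))
  expect_lt(abs(stouffer_meta(with_null)$meta_z), abs(m1$meta_z))

  # tanh back-transform is available but not the default
  expect_equal(stouffer_meta(rows, backtransform = TRUE)$meta_r,
               tanh(m1$meta_r), tolerance = 1e-12)
})

test_that("batch ANOVA flags a planted batch effect and rejects degenerate input", {
  set.seed(33)
  log_eml <- rnorm(60)
  batch <- rep(c("b1", "b2", "b3"), each = 20)
  log_eml[batch == "b2"] <- log_eml[batch == "b2"] + 5  # 5 SD apart
  res <- qc_batch_anova(log_eml, batch)
  expect_lt(res$p, 1e-6)
  expect_error(qc_batch_anova(rnorm(3), c("a", "b", "c")), "at least 2 observations")
  expect_error(qc_batch_anova(rnorm(5), rep("a", 5)), "at least 2 batch groups")

  # matches the reference one-way ANOVA
  set.seed(34)
  y <- rnorm(45); g <- sample(c("x", "y", "z"), 45, TRUE)
  ref <- summary(aov(y ~ factor(g)))[[1]]
  got <- qc_batch_anova(y, g)
  expect_equal(got$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("bisulfite-conversion QC is plain Pearson with sane edges", {
  set.seed(35)
  x <- rnorm(100)
  expect_equal(qc_conversion_pearson(x, x)$r, 1, tolerance = 1e-12)
  big <- qc_conversion_pearson(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  expect_true(is.na(qc_conversion_pearson(rep(1, 10), rnorm(10))$r))
})
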