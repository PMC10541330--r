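test_that("build_table tabulates with denominator-aware exclusion", {
  recs <- data.frame(category = c("MILD", "MODERATE", "SEVERE"),
                     dead = c(0, 1, 1))
  tab <- build_table(recs, "dead")
  expect_equal(unname(tab$row_margins), c(1, 1, 1))
  expect_equal(sum(tab$counts), 3)
  expect_equal(tab$n_excluded, 0)
  recs$dead[2] <- NA
  expect_equal(build_table(recs, "dead")$n_excluded, 1)
  expect_error(build_table(recs, "nonexistent"),
               class = "hrfph_validation_error")
  expect_error(build_table(recs[0, ], "dead"),
               class = "hrfph_validation_error")
})

test_that("2x2 Fisher matches the frozen example and the hypergeometric form", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  # oracle: dhyper over the support, point-probability rule
  hyper_oracle <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    a <- max(0, c1 - (n - r1)):min(r1, c1)
    p <- dhyper(a, r1, n - r1, c1)
    sum(p[p <= p[a == m[1, 1]] * (1 + 1e-7)])
  }
  set.seed(66)
  for (i in 1:300) {
    m <- random_table(2, 2, sample(1:60, 1))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m), hyper_oracle(m), tolerance = 1e-12)
  }
})

test_that("Fisher agrees with stats::fisher.test on 2x2 and r x c tables", {
  set.seed(77)
  for (i in 1:60) {
    m <- random_table(2, 2, sample(5:80, 1))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m), fisher.test(m)$p.value, tolerance = 1e-7)
  }
  for (i in 1:40) {
    m <- random_table(3, 2, sample(6:40, 1))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m), fisher.test(m)$p.value, tolerance = 1e-6)
  }
})

test_that("Freeman-Halton matches brute-force enumeration on the fixture table", {
  m <- matrix(c(0, 2, 3, 5, 63, 10), nrow = 3)  # lung malformation by category
  expect_equal(fisher_exact(m), fisher_oracle(m), tolerance = 1e-10)
})

test_that("degenerate tables behave as enumeration dictates", {
  expect_equal(fisher_exact(matrix(c(3, 4, 0, 0), 2)), 1.0)
  expect_error(fisher_exact(matrix(0, 2, 2)),
               class = "hrfph_degenerate_table_error")
  expect_error(fisher_exact(matrix(c(300, 300, 1, 1), 2)),
               class = "hrfph_validation_error")
})

test_that("Fisher p is invariant under row and column permutation", {
  set.seed(88)
  for (i in 1:20) {
    m <- random_table(3, 2, 25)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact(m)
    expect_equal(fisher_exact(m[sample(3), sample(2)]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t(m)), p, tolerance = 1e-12)
  }
})

test_that("robust_ols reproduces normal-equation OLS and hand-coded HC1", {
  # 5-point toy set against the closed-form normal equations
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 7.8, 10.5)
  fit <- robust_ols(y, x)
  X <- cbind(1, x)
  oracle <- hc1_oracle(y, X)
  expect_equal(unname(fit$coefficients), oracle$coef, tolerance = 1e-10)
  expect_equal(unname(fit$robust_se), oracle$se, tolerance = 1e-10)
  # 10-point heteroskedastic example
  set.seed(99)
  x10 <- 1:10
  y10 <- 1 + 0.5 * x10 + rnorm(10, sd = 0.2 * x10)
  f10 <- robust_ols(y10, x10)
  o10 <- hc1_oracle(y10, cbind(1, x10))
  expect_equal(unname(f10$coefficients), o10$coef, tolerance = 1e-10)
  expect_equal(unname(f10$robust_se), o10$se, tolerance = 1e-10)
})

test_that("robust_ols handles perfect fits, permutations and rank deficiency", {
  x <- 1:6; y <- 3 + 2 * x
  fit <- suppressWarnings(robust_ols(y, x))  # lm warns on an exact fit
  expect_equal(unname(fit$coefficients), c(3, 2))
  expect_equal(unname(fit$robust_se), c(0, 0), tolerance = 1e-10)
  # permutation invariance
  set.seed(101)
  x2 <- runif(20); y2 <- 1 + x2 + rnorm(20)
  f_a <- robust_ols(y2, x2)
  p <- sample(20)
  f_b <- robust_ols(y2[p], x2[p])
  expect_equal(f_a$coefficients, f_b$coefficients, tolerance = 1e-12)
  expect_equal(f_a$robust_se, f_b$robust_se, tolerance = 1e-12)
  expect_error(robust_ols(y2, cbind(x2, 2 * x2)),
               class = "hrfph_singularity_error")
  expect_error(robust_ols(c(1, NA, 3), 1:3), class = "hrfph_validation_error")
})

test_that("HC1 tracks classical OLS SEs in a balanced homoskedastic layout", {
  set.seed(123)
  g <- rep(1:3, each = 40)
  ratio <- replicate(200, {
    y <- rnorm(length(g)) + g
    fit <- robust_ols(y, g)
    se_cl <- summary(fit$fit)$coefficients[2, 2]
    fit$robust_se[2] / se_cl
  })
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})

test_that("summaries give median/IQR or denominator-aware percentages", {
  s <- summarize_outcome(8)
  expect_equal(s$median, 8); expect_equal(c(s$q1, s$q3), c(8, 8))
  expect_equal(summarize_outcome(c(1, 2, 3, 4))$median, 2.5)
  d <- summarize_outcome(c(rep(1, 14), rep(0, 69)))
  expect_equal(d$count, 14); expect_equal(d$denominator, 83)
  expect_equal(d$percent_display, 17)  # overall mortality
  with_na <- summarize_outcome(c(1, 0, NA, NA, 1), "dichotomous")
  expect_equal(with_na$denominator, 3)
  expect_error(summarize_outcome(c(NA_real_, NA_real_)),
               class = "hrfph_missing_data_error")
})
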