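test_that("exact rank-sum matches full enumeration on tied samples", {
  expect_equal(wilcoxon_exact(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_exact(c(5, 5, 5), c(5, 5))$p_value, 1)
  # same multiset split across groups
  expect_equal(wilcoxon_exact(c(1, 2, 2), c(2, 1, 2))$p_value, 1)

  set.seed(17)
  for (i in 1:200) {
    n_x <- sample(2:5, 1); n_y <- sample(2:5, 1)
    vals <- sample(1:4, n_x + n_y, replace = TRUE)  # heavy ties
    x <- vals[seq_len(n_x)]; y <- vals[-seq_len(n_x)]
    side <- sample(c("two", "greater", "less"), 1)
    expect_equal(wilcoxon_exact(x, y, side)$p_value,
                 enumerate_wilcoxon(x, y, side), tolerance = 1e-12)
  }
})

test_that("rank-sum statistic reports both W and U and large-sample fallback works", {
  res <- wilcoxon_exact(c(1, 2, 5), c(3, 4))
  expect_equal(unname(res$statistic["W"]), 1 + 2 + 5)
  expect_equal(unname(res$statistic["U"]),
               unname(res$statistic["W"]) - 3 * 4 / 2)

  set.seed(2)
  x <- rnorm(40); y <- rnorm(40, 1)
  approx <- wilcoxon_exact(x, y, exact_limit = 50)
  expect_false(approx$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("rank-sum P is invariant under common monotone transforms", {
  set.seed(23)
  for (i in 1:25) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    p0 <- wilcoxon_exact(x, y)$p_value
    expect_equal(wilcoxon_exact(2 * x + 3, 2 * y + 3)$p_value, p0)
    expect_equal(wilcoxon_exact(exp(x), exp(y))$p_value, p0)
  }
})

test_that("exact binomial tails, point masses, and complements", {
  expect_equal(binom_exact(0, 5, 0.5, "less")$p_value, (1 / 2)^5)
  expect_equal(binom_exact(0, 7, 0.5, "less")$p_value, (1 / 2)^7)
  expect_equal(binom_exact(13, 14, 1 / 3, "greater")$p_value, 29 / 3^14)
  expect_equal(binom_exact(6, 6, 0.4, "greater")$p_value, 0.4^6)
  # two-sided minimum-likelihood equals binom.test
  for (k in 0:10) {
    expect_equal(binom_exact(k, 10, 0.3)$p_value,
                 stats::binom.test(k, 10, 0.3)$p.value, tolerance = 1e-12)
  }
  # tails and point mass partition the distribution
  for (k in 1:9) {
    expect_equal(binom_exact(k, 9, 0.37, "greater")$p_value +
                   binom_exact(k - 1, 9, 0.37, "less")$p_value, 1,
                 tolerance = 1e-12)
  }
})

test_that("pearson correlation: definition, bounds, and invariances", {
  expect_equal(unname(pearson_test(1:10, 2 * (1:10) + 1)$statistic["r"]), 1)
  expect_equal(unname(pearson_test(1:10, -(1:10))$statistic["r"]), -1)
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")

  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson_test(x, y)
    r_def <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(res$statistic["r"]), r_def, tolerance = 1e-12)
    expect_true(abs(res$statistic["r"]) <= 1)
    # scale/shift invariance
    expect_equal(unname(pearson_test(3 * x - 1, 0.5 * y + 7)$statistic["r"]),
                 r_def, tolerance = 1e-12)
    # P matches cor.test
    expect_equal(res$p_value, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("spearman equals pearson on independently computed mid-ranks", {
  res <- spearman_test(c(1, 2, 3, 5), c(2, 4, 9, 10))
  expect_equal(unname(res$statistic["rs"]), 1)
  expect_equal(unname(spearman_test(1:5, 5:1)$statistic["rs"]), -1)

  midrank <- function(v) {  # independent mid-rank routine
    vapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2, numeric(1))
  }
  set.seed(53)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    rs <- spearman_test(x, y)$statistic["rs"]
    expect_equal(unname(rs), unname(pearson_test(midrank(x), midrank(y))$statistic["r"]),
                 tolerance = 1e-12)
  }

  # exact permutation option agrees with the t approximation in direction
  # and is a valid probability
  p_ex <- spearman_test(c(1, 2, 3, 4, 7), c(2, 1, 4, 3, 6), exact = TRUE)
  expect_true(p_ex$exact)
  expect_gte(p_ex$p_value, 0); expect_lte(p_ex$p_value, 1)
})

test_that("OLS regression matches the normal equations and validates rank", {
  # exact linear data recovered with zero residuals
  x1 <- 1:8; x2 <- c(2, 1, 4, 3, 6, 5, 8, 7)
  y <- 3 + 2 * x1 - 0.5 * x2
  fit <- suppressWarnings(ols_regress(y, data.frame(x1 = x1, x2 = x2)))
  expect_equal(fit$coefficients$estimate, c(3, 2, -0.5), tolerance = 1e-10)
  expect_lt(sum(fit$residuals^2), 1e-20)

  # permutation of rows leaves estimates unchanged
  perm <- sample(8)
  fit_p <- suppressWarnings(
    ols_regress(y[perm], data.frame(x1 = x1[perm], x2 = x2[perm])))
  expect_equal(fit_p$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)

  # collinear design rejected by name
  expect_error(ols_regress(y, data.frame(a = x1, b = 2 * x1)), "collinear.*b")

  # normal-equations oracle on random designs
  set.seed(61)
  for (i in 1:100) {
    n <- sample(8:25, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    fit <- ols_regress(y, X)
    D <- cbind(1, X)
    beta <- solve(t(D) %*% D, t(D) %*% y)
    expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  }

  # interaction column is the elementwise product
  fit_i <- ols_regress(rnorm(8), data.frame(a = x1, b = x2), interaction = TRUE)
  expect_true("a:b" %in% fit_i$coefficients$term)
})
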