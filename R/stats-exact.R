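# Exact tied-rank Wilcoxon rank-sum, exact binomial, correlation tests, and
# OLS regression, all returning a uniform test_result record.

test_result <- function(name, statistic, p_value, sidedness, exact, n,
                        estimate = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  out <- list(name = name, statistic = statistic,
              p_value = if (is.na(p_value)) NA_real_ else min(p_value, 1),
              sidedness = sidedness, exact = exact, n = n, estimate = estimate)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$name, "\n")
  stat <- paste(names(x$statistic), "=",
                vapply(x$statistic, function(v) format(v, digits = 6), ""),
                collapse = ", ")
  cat(" ", stat, ";  P =", format(x$p_value, digits = 6),
      sprintf("(%s-sided, %s)", x$sidedness,
              if (isTRUE(x$exact)) "exact" else "approximate"), "\n")
  if (!is.null(x$estimate))
    cat("  estimate:", paste(names(x$estimate), "=",
                             vapply(x$estimate, function(v) format(v, digits = 6), ""),
                             collapse = ", "), "\n")
  invisible(x)
}

# Exact null distribution of the rank-sum of the first sample: shift
# algorithm over mid-ranks scaled by 2 to integers. Returns P(W <= w) and
# P(W >= w) computed from subset counts (exact rationals represented in
# doubles; counts stay below 2^53 for the supported sample sizes).
ranksum_tails <- function(scaled_ranks, n_x, w_scaled) {
  total <- sum(scaled_ranks)
  # f[j+1, s+1] = number of size-j subsets with scaled sum s
  f <- matrix(0, nrow = n_x + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in scaled_ranks) {
    jmax <- n_x
    for (j in seq.int(jmax, 1L)) {
      if (r + 1L <= total) {
        src <- f[j, seq_len(total + 1L - r)]
        idx <- seq.int(r + 1L, total + 1L)
        f[j + 1L, idx] <- f[j + 1L, idx] + src
      }
    }
  }
  counts <- f[n_x + 1L, ]
  n_subsets <- sum(counts)
  sums <- seq.int(0L, total)
  lower <- sum(counts[sums <= w_scaled + 1e-9]) / n_subsets
  upper <- sum(counts[sums >= w_scaled - 1e-9]) / n_subsets
  c(lower = lower, upper = upper)
}

#' Exact Wilcoxon rank-sum test with ties
#'
#' Two-sample rank-sum (Mann-Whitney) test using mid-ranks for ties and an
#' exact P-value from the permutation distribution of the rank sum, computed
#' by dynamic programming over integer-scaled mid-ranks (the shift
#' algorithm). The exact distribution is used up to `exact_limit` pooled
#' observations; above that a normal approximation with tie-corrected
#' variance and continuity correction is used and flagged `exact = FALSE`.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param sidedness `"two"` (default), `"greater"` (x tends larger), or
#'   `"less"`.
#' @param exact_limit Maximum pooled sample size for the exact distribution.
#' @return A `test_result` whose `statistic` holds both `W` (rank sum of
#'   `x`) and `U` (Mann-Whitney statistic, `W - n_x (n_x + 1) / 2`).
#' @examples
#' wilcoxon_exact(c(1, 2), c(3, 4))   # exact two-sided P = 1/3
#' @export
wilcoxon_exact <- function(x, y, sidedness = c("two", "greater", "less"),
                           exact_limit = 50) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n_x <- length(x); n_y <- length(y); N <- n_x + n_y
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  W <- sum(r[seq_len(n_x)])
  U <- W - n_x * (n_x + 1) / 2
  if (N <= exact_limit) {
    scaled <- as.integer(round(2 * r))
    tails <- ranksum_tails(scaled, n_x, round(2 * W))
    p <- switch(sidedness,
      two = min(1, 2 * min(tails["lower"], tails["upper"])),
      greater = tails[["upper"]],
      less = tails[["lower"]])
    exact <- TRUE
  } else {
    mu <- n_x * (N + 1) / 2
    ties <- table(r)
    sigma2 <- (n_x * n_y / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- 0.5
    z_hi <- (W - mu - cc) / sqrt(sigma2)
    z_lo <- (W - mu + cc) / sqrt(sigma2)
    p <- switch(sidedness,
      two = min(1, 2 * min(stats::pnorm(z_hi, lower.tail = FALSE),
                           stats::pnorm(z_lo))),
      greater = stats::pnorm(z_hi, lower.tail = FALSE),
      less = stats::pnorm(z_lo))
    exact <- FALSE
  }
  test_result("wilcoxon_exact", c(W = W, U = U), p, sidedness, exact,
              c(n_x = n_x, n_y = n_y))
}

#' Exact binomial test
#'
#' Exact tail (or minimum-likelihood two-sided) probabilities of
#' `Binomial(n, p0)`.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials.
#' @param p0 Null success probability (strictly between 0 and 1).
#' @param sidedness `"two"` (minimum-likelihood method: the sum of the
#'   probabilities of all outcomes no more likely than `k`), `"greater"`
#'   (`P(X >= k)`), or `"less"` (`P(X <= k)`).
#' @return A `test_result` with statistic `k` and estimate `k / n`.
#' @examples
#' binom_exact(0, 5, 0.5, "less")$p_value    # 0.03125
#' binom_exact(13, 14, 1/3, "greater")$p_value  # 29 / 3^14
#' @export
binom_exact <- function(k, n, p0 = 0.5, sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  p <- switch(sidedness,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two = {
      d <- stats::dbinom(seq.int(0L, n), n, p0)
      sum(d[d <= d[k + 1L] * (1 + 1e-7)])
    })
  test_result("binom_exact", c(k = k), min(p, 1), sidedness, TRUE,
              c(n = n), estimate = c(proportion = k / n, p0 = p0))
}

#' Pearson product-moment correlation test
#'
#' Correlation coefficient `r` with P-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both with non-zero
#'   variance.
#' @param sidedness `"two"` (default), `"greater"`, or `"less"`.
#' @return A `test_result` with statistic `r` and `t`.
#' @export
pearson_test <- function(x, y, sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- switch(sidedness,
    two = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE),
    greater = stats::pt(t, n - 2, lower.tail = FALSE),
    less = stats::pt(t, n - 2))
  test_result("pearson", c(r = r, t = t), min(p, 1), sidedness, FALSE,
              c(n = n))
}

# all permutations of 1..n (list of integer vectors); n kept small by callers
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    i <- i + 1L
    out[[i]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Spearman rank correlation test
#'
#' Pearson correlation of mid-ranks; the P-value uses the same t transform as
#' [pearson_test()], or (for `exact = TRUE` and `n <= 9`) the exact
#' permutation distribution of the rank correlation.
#'
#' @inheritParams pearson_test
#' @param exact Use the exact permutation distribution (only for `n <= 9`)?
#' @return A `test_result` with statistic `rs`.
#' @export
spearman_test <- function(x, y, sidedness = c("two", "greater", "less"),
                          exact = FALSE) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance in x or y: rank correlation undefined")
  rs <- stats::cor(rx, ry)
  if (exact && n <= 9L) {
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    robs <- sum(cx * cy) / denom
    rperm <- vapply(all_perms(n), function(p) sum(cx * cy[p]) / denom, numeric(1))
    eps <- 1e-12
    p <- switch(sidedness,
      two = mean(abs(rperm) >= abs(robs) - eps),
      greater = mean(rperm >= robs - eps),
      less = mean(rperm <= robs + eps))
    return(test_result("spearman", c(rs = rs), p, sidedness, TRUE, c(n = n)))
  }
  t <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
  p <- switch(sidedness,
    two = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE),
    greater = stats::pt(t, n - 2, lower.tail = FALSE),
    less = stats::pt(t, n - 2))
  test_result("spearman", c(rs = rs, t = t), min(p, 1), sidedness, FALSE,
              c(n = n))
}

#' Ordinary least-squares multiple regression
#'
#' Least-squares fit of `y` on the predictor columns of `X` (an intercept is
#' always added), optionally with the pairwise interaction of the first two
#' predictors. P-values come from t statistics on the residual degrees of
#' freedom. The fit is delegated to [stats::lm()]; a rank-deficient design
#' raises an error naming the collinear columns.
#'
#' @param y Numeric response.
#' @param X Data frame or matrix of predictors (named columns).
#' @param interaction Add the elementwise product of the first two predictor
#'   columns?
#' @return A list of class `ols_fit`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `r_squared`, `sigma`, `df_residual`,
#'   `fitted`, `residuals`.
#' @export
ols_regress <- function(y, X, interaction = FALSE) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_along(X))
  if (interaction) {
    if (ncol(X) < 2L) stop("interaction requires at least two predictors")
    X[[paste0(names(X)[1L], ":", names(X)[2L])]] <- X[[1L]] * X[[2L]]
  }
  n <- length(y)
  if (n != nrow(X)) stop("y and X have different numbers of rows")
  if (n < ncol(X) + 2L) stop("need at least ", ncol(X) + 2L, " observations")
  design <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[seq.int(qr_d$rank + 1L, ncol(design))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- list(
    coefficients = data.frame(term = gsub("`", "", rownames(co)), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              row.names = NULL),
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit)
  )
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (residual df =", x$df_residual,
      ", R^2 =", format(x$r_squared, digits = 4), ")\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
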