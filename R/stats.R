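#' Paired permutation test (sign-flip test on mean difference)
#'
#' Tests whether paired measurements differ, using |mean difference| as
#' the statistic. Under the null each pair's difference is equally
#' likely to carry either sign, so the null distribution is generated by
#' independent sign flips. For n at or below `exhaustive_threshold` all
#' 2^n assignments are enumerated (exact p); otherwise Monte Carlo
#' sampling is used with the observed assignment included in the
#' denominator, guaranteeing p >= 1/(n_perm + 1).
#'
#' @param x first member of each pair, or the differences themselves
#'   when `y` is NULL.
#' @param y second member of each pair (optional).
#' @param n_perm Monte Carlo sample size (default 10000).
#' @param seed RNG seed for the Monte Carlo path.
#' @param exhaustive_threshold maximum n for exact enumeration
#'   (default 20).
#' @return object of class `test_result`: list with `statistic` (mean
#'   difference), `p_value`, `method`, `exact` (logical),
#'   `n_permutations`, `seed`, `degenerate` (TRUE when all differences
#'   are zero, which returns p = 1).
#' @export
#' @examples
#' paired_permutation_test(c(0.1, 0.2, 0.3))$p_value  # exact 2/8 = 0.25
paired_permutation_test <- function(x, y = NULL, n_perm = 10000,
                                    seed = 1L, exhaustive_threshold = 20) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- as.numeric(d)
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  obs <- mean(d)
  res <- structure(list(statistic = obs, p_value = NA_real_,
                        method = "paired permutation (sign flip)",
                        exact = FALSE, n_permutations = NA_integer_,
                        seed = seed, degenerate = FALSE),
                   class = "test_result")
  if (all(d == 0)) {
    res$p_value <- 1; res$degenerate <- TRUE; res$exact <- TRUE
    return(res)
  }
  tol <- 1e-12 * max(abs(d))
  target <- abs(sum(d))
  if (n <= exhaustive_threshold) {
    # subset-sum doubling: all 2^n signed sums
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    res$p_value <- mean(abs(sums) >= target - tol)
    res$exact <- TRUE
    res$n_permutations <- length(sums)
  } else {
    count <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        s <- sum(d * sample(c(-1, 1), n, replace = TRUE))
        if (abs(s) >= target - tol) hits <- hits + 1L
      }
      hits
    })
    res$p_value <- (count + 1) / (n_perm + 1)  # observed assignment included
    res$n_permutations <- as.integer(n_perm)
  }
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method,
              x$statistic, x$p_value,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}

#' Rank-sum (Mann-Whitney) test
#'
#' U statistic computed from midranks with tie correction. For combined
#' sample sizes n + m <= 12 with no ties the exact two-sided p-value is
#' obtained by enumerating all choose(n+m, n) group assignments;
#' otherwise the normal approximation with continuity and tie correction
#' is used.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact force the exact (TRUE) or approximate (FALSE) path;
#'   NULL (default) decides by sample size and ties.
#' @return `test_result` with `statistic` = U for the first sample.
#' @export
#' @examples
#' rank_sum_test(1:3, 4:6)$p_value  # exact 2/20 = 0.1
rank_sum_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  u <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  res <- structure(list(statistic = u, p_value = NA_real_,
                        method = "rank-sum (Mann-Whitney)",
                        exact = FALSE, n_permutations = NA_integer_,
                        seed = NA_integer_, degenerate = FALSE),
                   class = "test_result")
  use_exact <- if (is.null(exact)) n + m <= 12 && !has_ties else exact
  if (use_exact && has_ties)
    stop("exact enumeration is not available with ties")
  if (use_exact) {
    combos <- utils::combn(n + m, n)
    u_all <- colSums(matrix(rk[combos], nrow = n)) - n * (n + 1) / 2
    center <- n * m / 2
    res$p_value <- mean(abs(u_all - center) >= abs(u - center) - 1e-9)
    res$exact <- TRUE
    res$n_permutations <- ncol(combos)
  } else {
    mu <- n * m / 2
    nt <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n * m / 12 * (nt + 1 - tie_term)
    if (sigma2 <= 0) {  # all values identical
      res$p_value <- 1
      res$degenerate <- TRUE
      return(res)
    }
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity correction
    z <- max(z, 0)
    res$p_value <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  res
}
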