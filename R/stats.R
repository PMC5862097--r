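# Inferential tests used to evaluate the laminar classifiers. Every test
# returns a one-row tibble (method, statistic, df, p_value, n) so results
# bind into uniform tables.

test_result <- function(method, statistic, p_value, df = NA_real_, n = NA_integer_,
                        ...) {
  extra <- list(...)
  out <- tibble(
    method = method, statistic = statistic, df = df,
    p_value = p_value, n = n
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Exact two-sided binomial test
#'
#' Exact two-sided p-value (the sum of outcome probabilities not exceeding
#' that of the observed count) for comparing a classification rate with a
#' chance level.
#'
#' @param k successes.
#' @param n trials (> 0).
#' @param p0 null success probability.
#' @return one-row tibble (`statistic` is the observed proportion).
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n <= 0) abort("n must be positive")
  bt <- binom.test(k, n, p = p0, alternative = "two.sided")
  test_result("binomial_exact", statistic = k / n, p_value = bt$p.value,
              n = n, k = k, p0 = p0)
}

#' Exact McNemar test for paired classifiers
#'
#' Compares two classifiers on the same cases through the discordant
#' pairs: `b` cases where A is right and B wrong, `c` the reverse. The
#' exact p is the two-sided binomial probability of `b` out of `b + c` at
#' one half; the continuity-corrected chi-square `(|b-c|-1)^2/(b+c)` is
#' reported alongside. With no discordant pairs the exact p is 1 and the
#' chi-square is reported as 0 with `degenerate = TRUE`.
#'
#' @param correct_a,correct_b logical vectors (same length): per-case
#'   correctness of the two classifiers.
#' @return one-row tibble: `statistic` (chi-square), `p_value` (exact),
#'   `p_chisq`, `b`, `c`.
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0) {
    return(test_result("mcnemar_exact", statistic = 0, p_value = 1,
                       df = 1, n = length(correct_a), p_chisq = 1,
                       b = b, c = cc, degenerate = TRUE))
  }
  p_exact <- binom.test(b, b + cc, 0.5)$p.value
  chi <- (abs(b - cc) - 1)^2 / (b + cc)
  test_result("mcnemar_exact", statistic = chi, p_value = p_exact,
              df = 1, n = length(correct_a),
              p_chisq = pchisq(chi, 1, lower.tail = FALSE),
              b = b, c = cc, degenerate = FALSE)
}

#' Spearman rank correlation test
#'
#' Rank correlation with mid-ranks for ties; the two-sided p-value uses
#' the t approximation on `df = n - 2` (the conventional reporting for
#' rho(df)).
#'
#' @param x,y numeric vectors, length >= 4.
#' @param method `"t"` (default) or `"permutation"` (seeded Monte Carlo).
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed permutation seed.
#' @return one-row tibble (`statistic` is rho).
#' @export
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000, seed = 0) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0) {
    return(test_result("spearman", statistic = NA_real_, p_value = NA_real_,
                       df = length(x) - 2, n = length(x), degenerate = TRUE))
  }
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (method == "t") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    p <- withr::with_seed(seed, {
      null <- replicate(n_perm, cor(rank(x), rank(sample(y))))
      (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
    })
  }
  test_result("spearman", statistic = rho, p_value = min(p, 1),
              df = n - 2, n = n, degenerate = FALSE)
}

#' Meng-Rosenthal-Rubin test for correlated correlation coefficients
#'
#' Compares the correlations of several predictors with a shared target
#' variable measured on the same cases: a heterogeneity chi-square over
#' the Fisher-z transformed correlations (with the median inter-predictor
#' correlation adjustment), followed by pairwise Z-tests of dependent
#' correlations. When `absolute = TRUE` the comparison is made on the
#' absolute correlations.
#'
#' @param target numeric vector (the shared criterion).
#' @param predictors named list of numeric vectors (k >= 2, same length
#'   as `target`, n >= 10).
#' @param absolute compare absolute correlations.
#' @param sided 2 (default) or 1 for the pairwise Z-tests.
#' @return list with `heterogeneity` (one-row tibble, df = k - 1),
#'   `pairwise` (tibble of Z-tests) and `correlations`.
#' @export
meng_test <- function(target, predictors, absolute = TRUE, sided = 2) {
  k <- length(predictors)
  stopifnot(k >= 2)
  n <- length(target)
  stopifnot(n >= 10, all(vapply(predictors, length, 1L) == n))
  if (is.null(names(predictors))) {
    names(predictors) <- paste0("x", seq_len(k))
  }
  r <- vapply(predictors, function(p) cor(target, p), 1)
  ru <- if (absolute) abs(r) else r
  if (any(abs(ru) >= 1)) abort("|r| = 1: Fisher transform overflows")
  z <- atanh(ru)
  P <- do.call(cbind, predictors)
  rx <- cor(P)
  rx_med <- median(rx[lower.tri(rx)])
  r2bar <- mean(ru^2)
  f <- min((1 - rx_med) / (2 * (1 - r2bar)), 1)
  h <- (1 - f * r2bar) / (1 - r2bar)
  zbar <- mean(z)
  ssz <- sum((z - zbar)^2)
  chi <- if (ssz == 0) 0 else (n - 3) * ssz / ((1 - rx_med) * h)
  het <- test_result("meng_heterogeneity", statistic = chi,
                     p_value = pchisq(chi, k - 1, lower.tail = FALSE),
                     df = k - 1, n = n)

  pw <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rij <- rx[i, j]
      r2b <- (ru[i]^2 + ru[j]^2) / 2
      fij <- min((1 - rij) / (2 * (1 - r2b)), 1)
      hij <- (1 - fij * r2b) / (1 - r2b)
      Z <- if (abs(z[i] - z[j]) < 1e-12) {
        0   # identical correlations (e.g. duplicated predictors)
      } else {
        unname((z[i] - z[j]) * sqrt((n - 3) / (2 * (1 - rij) * hij)))
      }
      p <- sided * pnorm(-abs(Z))
      pw <- bind_rows(pw, test_result(
        "meng_pairwise_z", statistic = Z, p_value = min(p, 1), n = n,
        pair = paste(names(predictors)[c(i, j)], collapse = " vs ")
      ))
    }
  }
  list(heterogeneity = het, pairwise = pw,
       correlations = tibble(predictor = names(predictors), r = r))
}
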