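#' @include AllClasses.R
NULL

new_test_result <- function(method, statistic, p, n1, n2, exact) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(min(1, max(0, p))), n1 = n1, n2 = n2,
                 exact = exact), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2,
              if (x$exact) "exact" else "asymptotic"))
  invisible(x)
}

## sup |ECDF_x - ECDF_y| evaluated over the pooled sample.
ks_statistic <- function(x, y) {
  z <- sort(unique(c(x, y)))
  Fx <- vapply(z, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(z, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

## Kolmogorov tail with Stephens' finite-sample correction: the classic
## asymptotic convention of most two-sample KS implementations.
ks_asymptotic_p <- function(D, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  if (lambda < 1e-8) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The p-value
#' is exact (lattice-path computation via [stats::psmirnov()], conditional
#' on the pooled sample when ties are present) for small problems, or the
#' classic finite-sample-corrected Kolmogorov asymptotic otherwise; `auto`
#' switches at `n1 * n2 <= 1e4`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode one of `"auto"`, `"exact"`, `"asymptotic"`.
#' @return A `TestResult` with `method = "ks_two_sample"`, `statistic`
#'   = D, `p_value`, `n1`, `n2`, `exact`.
#' @examples
#' ksTwoSample(c(80, 67, 79, 88, 61), c(69, 104, 77, 64, 63, 80),
#'             mode = "asymptotic")
#' @export
ksTwoSample <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample", call. = FALSE)
  D <- ks_statistic(x, y)
  exact <- switch(mode, exact = TRUE, asymptotic = FALSE,
                  auto = n1 * n2 <= 1e4)
  hasTies <- anyDuplicated(c(x, y)) > 0
  p <- if (exact) {
    psmirnov(D, sizes = c(n1, n2), z = if (hasTies) c(x, y) else NULL,
             two.sided = TRUE, lower.tail = FALSE)
  } else {
    ks_asymptotic_p(D, n1, n2)
  }
  new_test_result("ks_two_sample", D, p, n1, n2, exact)
}

#' Two-sample t-test
#'
#' Standard two-sided two-sample t-test on the means, pooled-variance by
#' default, Welch when `equalVar = FALSE`. Thin wrapper over
#' [stats::t.test()] returning the package's `TestResult` record.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param equalVar pooled-variance statistic when TRUE (default).
#' @return A `TestResult` with `method = "t_two_sample"`.
#' @export
tTwoSample <- function(x, y, equalVar = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("t-test needs at least 2 values per sample", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- t.test(x, y, var.equal = equalVar)
  new_test_result("t_two_sample", tt$statistic, tt$p.value,
                  length(x), length(y), exact = FALSE)
}

## Exact two-sided rank-sum p by complete enumeration of group assignments,
## valid with ties (midranks). Only used for small pooled samples.
wilcoxon_exact_enumeration <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  r <- rank(z)  # midranks
  Wobs <- sum(r[seq_len(n1)])
  E <- n1 * (length(z) + 1) / 2
  combos <- utils::combn(length(z), n1)
  Wall <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(Wall - E) >= abs(Wobs - E) - 1e-9)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midrank ties. Modes: `exact` uses the
#' exact null distribution ([stats::wilcox.test()] without ties; complete
#' enumeration over group assignments when ties are present and the
#' pooled sample is small), `asymptotic` uses the normal approximation
#' with tie correction and continuity correction, and `auto` picks exact
#' for `min(n1, n2) <= 10` tie-free samples.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode one of `"auto"`, `"exact"`, `"asymptotic"`.
#' @return A `TestResult` with `method = "wilcoxon_rank_sum"` and the
#'   Mann-Whitney U statistic of `x`.
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample", call. = FALSE)
  hasTies <- anyDuplicated(c(x, y)) > 0
  U <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2

  wantExact <- switch(mode, exact = TRUE, asymptotic = FALSE,
                      auto = min(n1, n2) <= 10 && !hasTies)
  if (wantExact && hasTies && choose(n1 + n2, n1) > 2e5) {
    warning("exact enumeration infeasible with ties at this size; ",
            "using normal approximation")
    wantExact <- FALSE
  }
  if (wantExact) {
    p <- if (hasTies) wilcoxon_exact_enumeration(x, y)
         else wilcox.test(x, y, exact = TRUE)$p.value
    return(new_test_result("wilcoxon_rank_sum", U, p, n1, n2, TRUE))
  }
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  new_test_result("wilcoxon_rank_sum", U, p, n1, n2, FALSE)
}

#' Summary statistics (n, mean, SD, min, max)
#'
#' Sample SD uses the n-1 denominator and is `NA` (with
#' `sd_defined = FALSE`) for a single value.
#'
#' @param values non-empty numeric vector.
#' @return A list with `n`, `mean`, `sd`, `sd_defined`, `min`, `max`.
#' @export
summarizeValues <- function(values) {
  x <- as.numeric(values)
  if (!length(x)) stop("empty sample", call. = FALSE)
  list(n = length(x), mean = mean(x),
       sd = if (length(x) >= 2L) sd(x) else NA_real_,
       sd_defined = length(x) >= 2L, min = min(x), max = max(x))
}
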