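## Two-group tests used for per-cell condensate statistics: a
## Mann-Whitney U test with exact small-sample enumeration, and the
## two-tailed Student's t-test.

#' Two-sided unpaired Mann-Whitney U test
#'
#' The U statistic is computed from midranks (ties allowed). For
#' combined sample sizes up to `exact_max_n` the two-sided p-value is
#' obtained by exact enumeration of all group assignments of the pooled
#' sample; above that, the normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param a,b Numeric samples (each nonempty).
#' @param exact_max_n Combined-size crossover for exact enumeration.
#' @return A `group_comparison`: list with `statistic` (U for sample
#'   `a`), `p_two_sided`, `n_per_group`, `test_name`, `method`
#'   ("exact" or "normal_approx").
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max_n = 12L) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            is.numeric(a), is.numeric(b))
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u_from_ranks <- function(rk_a) sum(rk_a) - n1 * (n1 + 1) / 2
  u_obs <- u_from_ranks(r[seq_len(n1)])
  mu <- n1 * n2 / 2
  if (n <= exact_max_n) {
    idx <- utils::combn(n, n1)
    us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal_approx"
  }
  structure(list(statistic = u_obs, p_two_sided = p,
                 n_per_group = c(n1 = n1, n2 = n2),
                 test_name = "two-sided unpaired Mann-Whitney",
                 method = method),
            class = "group_comparison")
}

#' Two-tailed two-sample Student's t-test
#'
#' Pooled-variance (Student) by default; set `welch = TRUE` for unequal
#' variances. Degenerate zero-variance inputs are handled explicitly:
#' equal means give p = 1, different means give p = 0 with a
#' `degenerate` flag.
#'
#' @param a,b Numeric samples of size >= 2.
#' @param welch Use the Welch unequal-variance form.
#' @return A `group_comparison`: list with `statistic` (t),
#'   `p_two_sided`, `df`, `n_per_group`, `test_name`, `degenerate`.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(
      statistic = if (same) 0 else Inf,
      p_two_sided = if (same) 1 else 0,
      df = length(a) + length(b) - 2,
      n_per_group = c(n1 = length(a), n2 = length(b)),
      test_name = "two-tailed Student's t-test",
      degenerate = !same), class = "group_comparison"))
  }
  tt <- t.test(a, b, var.equal = !welch)
  structure(list(statistic = unname(tt$statistic),
                 p_two_sided = tt$p.value,
                 df = unname(tt$parameter),
                 n_per_group = c(n1 = length(a), n2 = length(b)),
                 test_name = if (welch) "two-tailed Welch t-test"
                             else "two-tailed Student's t-test",
                 degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %d)\n",
              x$test_name, x$statistic, x$p_two_sided,
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}
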