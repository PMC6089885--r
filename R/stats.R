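# Group-comparison statistics for per-monomer transport metrics.

#' Mann-Whitney U test
#'
#' U is reported as `min(U1, U2)`, where U1 counts pairs in which sample 1
#' exceeds sample 2 (ties count 1/2). The exact two-sided p-value is
#' obtained by full enumeration of the label assignments of the pooled
#' ranks (valid with ties); the normal approximation uses the tie-corrected
#' variance and a continuity correction. With `method = "auto"`, the exact
#' route is taken for tie-free samples with n1, n2 <= 12.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return object of class `group_comparison`: `U`, `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(sample1, sample2,
                           method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  if (length(sample1) == 0L || length(sample2) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(sample1); n2 <- length(sample2)
  pooled <- c(sample1, sample2)
  r <- rank(pooled)
  has_ties <- anyDuplicated(pooled) > 0L
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (method == "auto")
    method <- if (n1 <= 12 && n2 <= 12 && !has_ties) "exact" else "normal_approx"
  if (method == "exact") {
    N <- n1 + n2
    sets <- combn(N, n1)
    u1s <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    umins <- pmin(u1s, n1 * n2 - u1s)
    p <- mean(umins <= U + 1e-9)
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu + 0.5) / sqrt(sigma2)   # U <= mu; continuity toward mean
      p <- min(1, 2 * pnorm(z))
    }
  }
  structure(list(U = U, p_two_sided = p, method = method, n1 = n1, n2 = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Mean and standard deviation of a group
#'
#' @param values non-empty numeric vector.
#' @return named vector `c(mean, sd)`; sd uses the n-1 denominator and is 0
#'   for a single value.
#' @export
summarize_group <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  c(mean = mean(values), sd = if (length(values) == 1L) 0 else sd(values))
}
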