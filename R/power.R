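#' Hanley--McNeil standard error of an empirical AUROC
#'
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos * n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#' Fractional group sizes are allowed (prevalence times a candidate total
#' n, without rounding).
#'
#' @param A AUROC, in (0, 1).
#' @param n_pos,n_neg Positive/negative group sizes (> 0, real-valued).
#' @return The standard error.
#' @export
auroc_se <- function(A, n_pos, n_neg) {
  if (A <= 0 || A >= 1) stop("A must lie in (0, 1)", call. = FALSE)
  if (n_pos <= 0 || n_neg <= 0) stop("group sizes must be > 0", call. = FALSE)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
         (n_pos * n_neg))
}

#' Minimum sample size for an AUROC confidence interval
#'
#' Smallest integer n such that a two-sided normal confidence interval for
#' the AUROC, with Hanley--McNeil standard error evaluated at
#' `n_pos = prevalence * n` and `n_neg = (1 - prevalence) * n`, has
#' half-width at most `ci_width / 2`.
#'
#' @param auc Anticipated AUROC, in (0.5, 1).
#' @param prevalence Proportion with the disease, in (0, 1).
#' @param ci_width Full width of the confidence interval (> 0).
#' @param confidence Confidence level, in (0, 1).
#' @param n_max Scan limit.
#' @return The minimum total sample size (integer).
#' @export
min_sample_size <- function(auc, prevalence, ci_width, confidence = 0.95,
                            n_max = 1e7) {
  if (auc <= 0.5 || auc >= 1) stop("auc must lie in (0.5, 1)", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (ci_width <= 0) stop("ci_width must be > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  half <- ci_width / 2
  ok <- function(n) {
    z * auroc_se(auc, prevalence * n, (1 - prevalence) * n) <= half
  }
  # SE is decreasing in n, so double to bracket then bisect
  hi <- 2
  while (!ok(hi)) {
    hi <- hi * 2
    if (hi > n_max)
      stop("no n <= ", format(n_max, scientific = FALSE),
           " attains the requested interval width", call. = FALSE)
  }
  lo <- max(2, hi %/% 2)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (ok(mid)) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}
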