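#' Pearson correlation with a small-sample p-value contract
#'
#' Product-moment correlation between two numeric vectors, with a two-sided
#' p-value from the t reference distribution with `n - 2` degrees of freedom.
#' With `n = 3` the t statistic has a single degree of freedom and its tail
#' area is not interpretable as a test, so the p-value is reported as `NA`
#' rather than computed; the correlation itself is still returned.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each nonconstant.
#' @return A one-row tibble with columns `r`, `p` (two-sided, `NA` when
#'   `n < 4`), and `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3)) # r = 0.6
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric vectors.", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (", length(x), " vs ",
         length(y), ").", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("Need at least 3 paired observations.", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("Missing values are not allowed.", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; correlation undefined.", call. = FALSE)
  if (stats::sd(y) == 0) stop("`y` is constant; correlation undefined.", call. = FALSE)
  r <- stats::cor(x, y)
  p <- if (n >= 4) {
    # guard |r| = 1 exactly: t is infinite, p = 0
    if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    NA_real_
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. Equal
#' raw p-values receive equal adjusted values.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of the same length, elementwise `>= p`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric.", call. = FALSE)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("Missing p-values are not allowed.", call. = FALSE)
  if (any(p < 0 | p > 1)) {
    bad <- which(p < 0 | p > 1)[1]
    stop("p-value out of [0, 1] at position ", bad, ": ", p[bad], call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sample t test (Welch or pooled-variance)
#'
#' Two-tailed unpaired t test. The Welch variant (unequal variances,
#' Welch-Satterthwaite degrees of freedom) is the default, appropriate for
#' the small, possibly heteroscedastic well counts typical of flux assays;
#' the classical pooled-variance Student variant is available via
#' `variant = "student"`.
#'
#' @param x,y Numeric vectors, each of length `>= 2`.
#' @param variant `"welch"` (default) or `"student"`.
#' @return A one-row tibble with columns `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("Each group needs at least 2 observations.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("Missing values are not allowed.", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    # degenerate but well-defined: identical constants in both groups
    return(tibble::tibble(t = 0, df = NA_real_, p = 1,
                          mean_x = mean(x), mean_y = mean(y)))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "student"),
                       alternative = "two.sided")
  tibble::tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}
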