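#' Hypothesis-test result container
#'
#' Light container for the package's test results, with broom-style
#' [generics::tidy()] / [generics::glance()] methods. Degenerate inputs
#' (zero variance) yield a flagged result with `NA` statistic and p-value
#' instead of an error or a fake `p = 0`.
#'
#' @param statistic,df,p_value,estimate,n,method Components of the result.
#' @param degenerate Logical flag for zero-variance inputs.
#' @param extra Optional named list merged into the object.
#' @return An object of class `lt_htest`.
#' @keywords internal
lt_htest <- function(statistic, df, p_value, estimate, n, method,
                     degenerate = FALSE, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   estimate = estimate, n = n, method = method,
                   degenerate = degenerate), extra),
            class = "lt_htest")
}

#' @export
print.lt_htest <- function(x, ...) {
  cat(x$method, "\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate (zero variance); estimate =",
        format(x$estimate, digits = 4), " n =", x$n, "\n")
  } else {
    cat(sprintf("  statistic = %.4f, df = %g, p = %.4g (estimate = %.4g, n = %d)\n",
                x$statistic, x$df, x$p_value, x$estimate, x$n))
  }
  invisible(x)
}

#' One-sample t-test from raw values or printed summary statistics
#'
#' Two-sided one-sample t-test of the mean against `mu0`:
#' `t = (mean - mu0) / (sd / sqrt(n))` on `n - 1` degrees of freedom.
#' Accepts either a raw vector or the (mean, sd, n) triple as printed in a
#' results section, so published summaries are first-class inputs — e.g.
#' testing a cohort's midline shift against 0, or hemispheric change
#' against 100%.
#'
#' @param x Optional numeric vector of raw values (NAs dropped).
#' @param mean,sd,n Summary statistics, used when `x` is `NULL`.
#' @param mu0 Null value of the mean.
#' @return An `lt_htest`; `estimate` is `mean - mu0`.
#' @export
#' @examples
#' # midline shift 1.57 +/- 0.83 mm in 7 subjects, tested against 0:
#' one_sample_t(mean = 1.57, sd = 0.83, n = 7, mu0 = 0)
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                         mu0 = 0) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n)) {
    stop("supply either raw values `x` or all of `mean`, `sd`, `n`",
         call. = FALSE)
  }
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("invalid sd", call. = FALSE)
  if (sd == 0) {
    return(lt_htest(NA_real_, n - 1, NA_real_, mean - mu0, n,
                    "One-sample t-test", degenerate = TRUE))
  }
  tstat <- (mean - mu0) / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  lt_htest(tstat, n - 1, p, mean - mu0, n, "One-sample t-test")
}

#' Paired t-test
#'
#' Two-sided paired t-test, i.e. a one-sample t-test of the within-pair
#' differences `x - y` against 0. Pairs with a missing value in either
#' member are dropped and the number dropped is recorded on the result.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method Label stored on the result.
#' @return An `lt_htest`; `estimate` is the mean difference, and
#'   `n_dropped` records incomplete pairs removed.
#' @export
paired_t <- function(x, y, method = "Paired t-test") {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  d <- (x - y)[keep]
  if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  res <- one_sample_t(d, mu0 = 0)
  res$method <- method
  res$n_dropped <- sum(!keep)
  res
}

#' Pearson correlation with t-distributed p-value
#'
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`,
#' with the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors.
#' @return An `lt_htest` with `estimate` = r. Zero variance in either
#'   variable yields a degenerate-flagged result.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(lt_htest(NA_real_, n - 2, NA_real_, NA_real_, n,
                    "Pearson correlation", degenerate = TRUE))
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
    tstat <- Inf * sign(r)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  lt_htest(tstat, n - 2, p, r, n, "Pearson correlation")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: with p-values sorted ascending,
#' `adj_i = min_{j >= i} ( p_j * m / j )` capped at 1, returned in the
#' original order. Controls the expected false discovery rate at the
#' nominal level for independent (or positively dependent) tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; `NA`s pass
#'   through untouched and do not count toward `m`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    ranked <- pv[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Sidak multiple-comparison adjustment
#'
#' Closed form `p_adj = 1 - (1 - p)^k` for `k` comparisons.
#'
#' @param p Numeric vector of raw p-values.
#' @param k Number of comparisons in the family.
#' @return Adjusted p-values, capped at 1.
#' @export
#' @examples
#' sidak_adjust(0.01, 4)  # 0.0394
sidak_adjust <- function(p, k) {
  stopifnot(k >= 1)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1 - (1 - p)^k, 1)
}
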