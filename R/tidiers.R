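#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x An `lt_htest`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `estimate`, `n`,
#'   `method`, `degenerate`.
#' @export
tidy.lt_htest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 estimate = x$estimate, n = x$n, method = x$method,
                 degenerate = x$degenerate)
}

#' @rdname tidy.lt_htest
#' @export
glance.lt_htest <- function(x, ...) tidy(x, ...)

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `lt_rm_anova`.
#' @param ... Unused.
#' @return The effects table (tidy) or a one-row model summary (glance).
#' @export
tidy.lt_rm_anova <- function(x, ...) x$anova

#' @rdname tidy.lt_rm_anova
#' @export
glance.lt_rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, gg_epsilon = x$gg_epsilon,
                 baseline_day = x$baseline_day,
                 n_pairwise = nrow(x$pairwise))
}
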