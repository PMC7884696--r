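#' Two-way repeated-measures ANOVA with Sidak post-hoc comparisons
#'
#' Split-plot ANOVA for longitudinal functional outcomes: `group`
#' (stroked vs control) is the between-subject factor and `timepoint_day`
#' the within-subject factor. The model is fitted with [stats::aov()] using
#' an `Error(subject)` stratum, yielding F tests for the group main effect
#' (between stratum) and for timepoint and group x timepoint (within
#' stratum). No sphericity correction is applied to the reported p-values;
#' a Greenhouse-Geisser epsilon is computed for information.
#'
#' Sidak-adjusted pairwise comparisons accompany the table: between groups
#' at each timepoint (two-sample Welch t, adjusted over the number of
#' timepoints) and within each group against the baseline timepoint
#' (paired t, adjusted over the number of post-baseline timepoints).
#'
#' @param data Tidy outcome rows with columns `subject_id`, `group`,
#'   `timepoint_day`, `value` (already restricted to one parameter/limb).
#' @param baseline_day Timepoint treated as baseline for within-group
#'   comparisons (default: the smallest `timepoint_day`).
#' @return An `lt_rm_anova` list: `anova` (tibble of effects), `pairwise`
#'   (tibble of adjusted comparisons), `gg_epsilon`, `n_subjects`.
#'   Unbalanced designs (missing subject x timepoint cells) are rejected
#'   with an error naming the missing cells.
#' @export
rm_anova_sidak <- function(data, baseline_day = NULL) {
  needed <- c("subject_id", "group", "timepoint_day", "value")
  if (!all(needed %in% names(data))) {
    stop("`data` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::as_tibble(data)
  df$subject_id <- factor(df$subject_id)
  df$group <- factor(df$group)
  df$time_f <- factor(df$timepoint_day)
  if (nlevels(df$group) < 2 || nlevels(df$time_f) < 2) {
    stop("need at least 2 levels of both group and timepoint", call. = FALSE)
  }
  # balance check: every subject must appear exactly once per timepoint
  grid <- df |>
    dplyr::count(.data$subject_id, .data$time_f)
  full <- tidyr::expand_grid(subject_id = levels(df$subject_id),
                             time_f = levels(df$time_f))
  missing_cells <- dplyr::anti_join(
    full, dplyr::mutate(grid, subject_id = as.character(.data$subject_id),
                        time_f = as.character(.data$time_f)),
    by = c("subject_id", "time_f"))
  if (nrow(missing_cells) > 0 || any(grid$n != 1)) {
    bad <- if (nrow(missing_cells)) {
      paste0(missing_cells$subject_id, " @ day ", missing_cells$time_f)
    } else {
      dup <- grid[grid$n != 1, ]
      paste0(dup$subject_id, " @ day ", dup$time_f, " (x", dup$n, ")")
    }
    stop("unbalanced repeated-measures design; offending cells: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  constant <- stats::var(df$value) == 0
  if (constant) {
    eff <- c("group", "time_f", "group:time_f")
    tab <- tibble::tibble(effect = c("group", "timepoint",
                                     "group:timepoint"),
                          df = NA_real_, df_error = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          degenerate = TRUE)
  } else {
    fit <- stats::aov(value ~ group * time_f + Error(subject_id), data = df)
    s <- summary(fit)
    pull_stratum <- function(stratum) {
      tb <- s[[stratum]][[1]]
      tibble::tibble(effect = trimws(rownames(tb)),
                     df = tb[, "Df"],
                     statistic = tb[, "F value"],
                     p_value = tb[, "Pr(>F)"])
    }
    btw <- pull_stratum("Error: subject_id")
    wth <- pull_stratum("Error: Within")
    err_b <- btw[btw$effect == "Residuals", ]
    err_w <- wth[wth$effect == "Residuals", ]
    tab <- dplyr::bind_rows(
      dplyr::mutate(btw[btw$effect != "Residuals", ], df_error = err_b$df),
      dplyr::mutate(wth[wth$effect != "Residuals", ], df_error = err_w$df)
    )
    tab$effect <- sub("^time_f$", "timepoint", tab$effect)
    tab$effect <- sub("^group:time_f$", "group:timepoint", tab$effect)
    tab$degenerate <- FALSE
    tab <- tab[, c("effect", "df", "df_error", "statistic", "p_value",
                   "degenerate")]
  }

  eps <- gg_epsilon(df)

  # ---- Sidak pairwise comparisons ---------------------------------------
  tps <- sort(unique(df$timepoint_day))
  if (is.null(baseline_day)) baseline_day <- tps[1]
  k_between <- length(tps)
  groups <- levels(df$group)
  between <- purrr::map_dfr(tps, function(tp) {
    sub <- df[df$timepoint_day == tp, ]
    a <- sub$value[sub$group == groups[1]]
    b <- sub$value[sub$group == groups[2]]
    if (stats::sd(c(a, b)) == 0) {
      tibble::tibble(comparison = "between_groups", timepoint_day = tp,
                     group = NA_character_, p_raw = 1, p_sidak = 1)
    } else {
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      tibble::tibble(comparison = "between_groups", timepoint_day = tp,
                     group = NA_character_, p_raw = p,
                     p_sidak = sidak_adjust(p, k_between))
    }
  })
  post <- setdiff(tps, baseline_day)
  k_within <- length(post)
  within <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(post, function(tp) {
      sub <- df[df$group == g, ]
      wide <- tidyr::pivot_wider(sub[, c("subject_id", "timepoint_day",
                                         "value")],
                                 names_from = "timepoint_day",
                                 values_from = "value")
      a <- wide[[as.character(baseline_day)]]
      b <- wide[[as.character(tp)]]
      d <- a - b
      if (stats::sd(d) == 0) {
        p <- if (all(d == 0)) 1 else NA_real_
      } else {
        p <- paired_t(a, b)$p_value
      }
      tibble::tibble(comparison = "vs_baseline", timepoint_day = tp,
                     group = g, p_raw = p,
                     p_sidak = sidak_adjust(p, k_within))
    })
  })

  structure(list(anova = tab, pairwise = dplyr::bind_rows(between, within),
                 gg_epsilon = eps,
                 n_subjects = nlevels(df$subject_id),
                 baseline_day = baseline_day),
            class = "lt_rm_anova")
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix,
# computed across all subjects (informational only; no correction applied)
gg_epsilon <- function(df) {
  wide <- tidyr::pivot_wider(df[, c("subject_id", "time_f", "value")],
                             names_from = "time_f", values_from = "value")
  m <- as.matrix(wide[, -1])
  k <- ncol(m)
  if (k < 3 || nrow(m) <= k) return(NA_real_)
  S <- stats::cov(m)
  C <- diag(k) - matrix(1 / k, k, k)
  SC <- C %*% S %*% C
  tr <- sum(diag(SC))
  (tr^2) / ((k - 1) * sum(SC^2))
}

#' @export
print.lt_rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (between: group, within: timepoint)\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("Greenhouse-Geisser epsilon (informational):",
      format(x$gg_epsilon, digits = 3), "\n")
  invisible(x)
}
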