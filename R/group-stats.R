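#' Normality gate for the group-comparison layer
#'
#' Tests each group for Gaussianity and decides between the parametric
#' branch (one-way ANOVA with Bonferroni post-hoc tests) and the rank branch
#' (Kruskal-Wallis with Dunn's tests). The parametric branch is taken only
#' when no group rejects normality at `alpha` — the conservative reading.
#' `method = "ks"` is the Lilliefors-corrected Kolmogorov-Smirnov test
#' against a Gaussian with estimated mean and SD (the population parameters
#' are unknown a priori); `"shapiro"` is Shapiro-Wilk. Groups too small to
#' test (n below 5 for `"ks"`, 3 for `"shapiro"`) or with zero variance
#' force the rank branch with a warning.
#'
#' @param data Data frame with one row per image.
#' @param value,group Column names (strings) of the metric value and the
#'   group label.
#' @param alpha Significance level of the gate (default 0.05).
#' @param method `"ks"` (default) or `"shapiro"`.
#' @return List with `branch` (`"parametric"` or `"rank"`), `per_group`
#'   tibble (group, n, statistic, p_value, testable), `method`, `alpha`.
#' @export
normality_gate <- function(data, value, group, alpha = 0.05,
                           method = c("ks", "shapiro")) {
  method <- match.arg(method)
  v <- data[[value]]; g <- data[[group]]
  if (length(v) == 0) tj_abort("validation", "No data supplied to the normality gate.")
  if (anyNA(v)) tj_abort("validation", "Metric values contain NA.")
  min_n <- if (method == "ks") 5L else 3L
  per_group <- tibble::tibble(group = unique(as.character(g))) %>%
    dplyr::mutate(purrr::map_dfr(.data$group, function(gl) {
      x <- v[g == gl]
      if (length(x) == 0) tj_abort("validation", paste0("Empty group: ", gl))
      if (length(x) < min_n || stats::sd(x) == 0) {
        return(tibble::tibble(n = length(x), statistic = NA_real_,
                              p_value = NA_real_, testable = FALSE))
      }
      t <- if (method == "ks") nortest::lillie.test(x) else stats::shapiro.test(x)
      tibble::tibble(n = length(x), statistic = unname(t$statistic),
                     p_value = t$p.value, testable = TRUE)
    }))
  forced <- !all(per_group$testable)
  if (forced) {
    warning("Some groups are untestable for normality (too small or constant); ",
            "taking the rank branch.", call. = FALSE)
  }
  reject <- any(per_group$p_value < alpha, na.rm = TRUE)
  list(
    branch = if (forced || reject) "rank" else "parametric",
    per_group = per_group, method = method, alpha = alpha
  )
}

# Dunn's all-pairs rank comparisons after Kruskal-Wallis, with mid-ranks,
# the standard tie correction, and Bonferroni adjustment over all pairs.
dunn_pairs <- function(v, g) {
  rk <- rank(v)
  N <- length(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- unique(as.character(g))
  rbar <- vapply(groups, function(gl) mean(rk[g == gl]), 1)
  ns <- vapply(groups, function(gl) sum(g == gl), 1)
  pairs <- utils::combn(groups, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[g1] + 1 / ns[g2]))
    z <- (rbar[g1] - rbar[g2]) / se
    tibble::tibble(group1 = g1, group2 = g2, statistic = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
}

#' Compare metric values across groups
#'
#' The full statistical layer of the study design: normality gate, then
#' either one-way ANOVA with all-pairs Bonferroni-adjusted t-tests on the
#' pooled error variance, or Kruskal-Wallis with Dunn's all-pairs z-tests
#' (Bonferroni-adjusted). Significance is flagged at `alpha` on the adjusted
#' p-values; group means and standard errors of the mean are carried in the
#' result.
#'
#' @inheritParams normality_gate
#' @param gate Normality-gate method, passed to [normality_gate()].
#' @param branch Optional override: `"parametric"` or `"rank"` skips the gate.
#' @return Object of class `tj_group_comparison`: list with `summary`
#'   (group, n, mean, sem), `gate`, `branch`, `omnibus` (method, statistic,
#'   df, p_value), `pairwise` (group1, group2, statistic, p_raw, p_adj,
#'   significant), `alpha`, `value`, `group`.
#' @export
#' @examples
#' df <- data.frame(group = rep(c("control", "1d"), each = 8),
#'                  y = c(rnorm(8, 10), rnorm(8, 12)))
#' fit <- compare_groups(df, "y", "group")
#' glance(fit)
#' tidy(fit)
compare_groups <- function(data, value, group, alpha = 0.05,
                           gate = c("ks", "shapiro"), branch = NULL) {
  gate <- match.arg(gate)
  v <- data[[value]]
  g <- factor(as.character(data[[group]]), levels = unique(as.character(data[[group]])))
  if (nlevels(g) < 2) tj_abort("validation", "At least two groups are required.")
  gate_res <- NULL
  if (is.null(branch)) {
    gate_res <- normality_gate(data, value, group, alpha = alpha, method = gate)
    branch <- gate_res$branch
  } else {
    branch <- match.arg(branch, c("parametric", "rank"))
  }
  if (branch == "parametric" && any(table(g) < 2)) {
    warning("A group has n = 1; forcing the rank branch.", call. = FALSE)
    branch <- "rank"
  }
  summary_tbl <- tibble::tibble(group = levels(g)) %>%
    dplyr::mutate(
      n = as.integer(table(g)[.data$group]),
      mean = vapply(.data$group, function(gl) mean(v[g == gl]), 1,
                    USE.NAMES = FALSE),
      sem = vapply(.data$group, function(gl) {
        x <- v[g == gl]
        if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
      }, 1, USE.NAMES = FALSE)
    )
  n_pairs <- choose(nlevels(g), 2)
  if (branch == "parametric") {
    fit <- stats::aov(v ~ g)
    an <- stats::anova(fit)
    mse <- an["Residuals", "Mean Sq"]
    df_err <- an["Residuals", "Df"]
    omnibus <- tibble::tibble(
      method = "one-way ANOVA", statistic = an["g", "F value"],
      df1 = an["g", "Df"], df2 = df_err, p_value = an["g", "Pr(>F)"]
    )
    pairs <- utils::combn(levels(g), 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x1 <- v[g == g1]; x2 <- v[g == g2]
      tstat <- (mean(x1) - mean(x2)) /
        sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      tibble::tibble(group1 = g1, group2 = g2, statistic = tstat,
                     p_raw = 2 * stats::pt(-abs(tstat), df_err))
    })
    posthoc <- "pooled t, Bonferroni"
  } else {
    kw <- stats::kruskal.test(v, g)
    omnibus <- tibble::tibble(
      method = "Kruskal-Wallis", statistic = unname(kw$statistic),
      df1 = unname(kw$parameter), df2 = NA_real_, p_value = kw$p.value
    )
    pairwise <- dunn_pairs(v, g)
    posthoc <- "Dunn's z, Bonferroni"
  }
  pairwise <- pairwise %>%
    dplyr::mutate(p_adj = pmin(1, .data$p_raw * n_pairs),
                  significant = .data$p_adj < alpha)
  structure(
    list(summary = summary_tbl, gate = gate_res, branch = branch,
         omnibus = omnibus, pairwise = pairwise, posthoc = posthoc,
         alpha = alpha, value = value, group = group),
    class = "tj_group_comparison"
  )
}

#' @export
print.tj_group_comparison <- function(x, ...) {
  cat(sprintf("<tj_group_comparison> %s by %s — %s branch\n",
              x$value, x$group, x$branch))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$summary)
  cat("  Post hoc (", x$posthoc, "):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of a group comparison
#'
#' @param x A `tj_group_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with adjusted p-values,
#'   significance flags and star annotations.
#' @export
tidy.tj_group_comparison <- function(x, ...) {
  x$pairwise %>%
    dplyr::mutate(stars = sig_stars(.data$p_adj), method = x$posthoc)
}

#' One-row summary of a group comparison
#'
#' @param x A `tj_group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with branch, omnibus statistic and p-value, group
#'   and observation counts.
#' @export
glance.tj_group_comparison <- function(x, ...) {
  tibble::tibble(
    branch = x$branch, method = x$omnibus$method,
    statistic = x$omnibus$statistic, df1 = x$omnibus$df1, df2 = x$omnibus$df2,
    p_value = x$omnibus$p_value,
    n_groups = nrow(x$summary), n_obs = sum(x$summary$n), alpha = x$alpha
  )
}

#' Express per-image values as percent of the control-group mean
#'
#' The normalization convention of the study: the unstressed control group's
#' mean defines 100%, and every value (control included) is rescaled by it.
#' Sign is preserved, so a negative corrected intensity stays negative.
#'
#' @param data Data frame of per-image values.
#' @param value,group Column names (strings).
#' @param control_group Label of the control group (default `"control"`).
#' @return `data` with an added `percent_of_control` column.
#' @export
percent_of_control <- function(data, value, group, control_group = "control") {
  g <- as.character(data[[group]])
  if (!any(g == control_group)) {
    tj_abort("normalization", paste0("Control group '", control_group, "' not found."))
  }
  ctrl_mean <- mean(data[[value]][g == control_group])
  if (!is.finite(ctrl_mean) || ctrl_mean == 0) {
    tj_abort("normalization", "Control-group mean is zero or non-finite; cannot normalize.")
  }
  data %>% dplyr::mutate(percent_of_control = .data[[value]] / ctrl_mean * 100)
}

#' Figure-style percent-of-control report
#'
#' Builds the per-group report the study's figures show: mean and SEM in
#' percent-of-control units, with the adjusted p-value of each group's
#' comparison against control and the conventional star annotations
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param comparison A `tj_group_comparison` from [compare_groups()], or a
#'   plain data frame of per-image values (then `value` and `group` must be
#'   given and no p-values are reported — e.g. a control-only table).
#' @param control_group Label of the control group (default `"control"`).
#' @param value,group Column names, used only when `comparison` is a data
#'   frame.
#' @return Tibble with `group`, `n`, `mean`, `sem`, `pct_mean`, `pct_sem`,
#'   `p_adj_vs_control`, `stars`.
#' @export
report_figure_table <- function(comparison, control_group = "control",
                                value = NULL, group = NULL) {
  if (!inherits(comparison, "tj_group_comparison")) {
    data <- comparison
    v <- data[[value]]
    g <- factor(as.character(data[[group]]),
                levels = unique(as.character(data[[group]])))
    comparison <- list(
      summary = tibble::tibble(group = levels(g)) %>%
        dplyr::mutate(
          n = as.integer(table(g)[.data$group]),
          mean = vapply(.data$group, function(gl) mean(v[g == gl]), 1,
                        USE.NAMES = FALSE),
          sem = vapply(.data$group, function(gl) {
            x <- v[g == gl]
            if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
          }, 1, USE.NAMES = FALSE)
        ),
      pairwise = tibble::tibble(group1 = character(0), group2 = character(0),
                                p_adj = numeric(0)),
      empty = TRUE
    )
  }
  s <- comparison$summary
  if (!control_group %in% s$group) {
    tj_abort("normalization", paste0("Control group '", control_group, "' not found."))
  }
  ctrl_mean <- s$mean[s$group == control_group]
  if (ctrl_mean == 0) tj_abort("normalization", "Control-group mean is zero.")
  vs_ctrl <- comparison$pairwise %>%
    dplyr::filter(.data$group1 == control_group | .data$group2 == control_group) %>%
    dplyr::mutate(other = as.character(ifelse(.data$group1 == control_group,
                                              .data$group2, .data$group1))) %>%
    dplyr::select("other", "p_adj")
  s %>%
    dplyr::left_join(vs_ctrl, by = c(group = "other")) %>%
    dplyr::rename(p_adj_vs_control = "p_adj") %>%
    dplyr::mutate(
      pct_mean = .data$mean / ctrl_mean * 100,
      pct_sem = .data$sem / ctrl_mean * 100,
      stars = ifelse(.data$group == control_group, "",
                     sig_stars(.data$p_adj_vs_control))
    )
}
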