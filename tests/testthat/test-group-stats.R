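gauss_table <- function(k = 4, n = 10, means = rep(0, k), seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      group = rep(c("control", "1d", "3d", "21d")[seq_len(k)], each = n),
      value = unlist(lapply(seq_len(k), function(i) stats::rnorm(n, means[i])))
    )
  })
}

test_that("the normality gate passes Gaussian groups and catches heavy tails and degenerate groups", {
  parametric_hits <- sum(vapply(1:40, function(s) {
    normality_gate(gauss_table(seed = s), "value", "group")$branch == "parametric"
  }, TRUE))
  expect_gte(parametric_hits, 32)  # gate type-I error is about alpha per group
  heavy <- withr::with_seed(2, data.frame(
    group = rep(c("a", "b"), each = 50),
    value = c(stats::rnorm(50), stats::rcauchy(50))
  ))
  expect_equal(normality_gate(heavy, "value", "group")$branch, "rank")
  const <- data.frame(group = rep(c("a", "b"), each = 10),
                      value = c(rep(5, 10), stats::rnorm(10)))
  expect_warning(g <- normality_gate(const, "value", "group"))
  expect_equal(g$branch, "rank")
  expect_error(normality_gate(data.frame(group = character(0), value = numeric(0))[0, ],
                              "value", "group"),
               class = "tjquant_error_validation")
})

test_that("the parametric branch on two groups reduces to the pooled t-test (F = t^2)", {
  for (s in 1:10) {
    d <- gauss_table(k = 2, means = c(0, 0.5), seed = s)
    fit <- compare_groups(d, "value", "group", branch = "parametric")
    tt <- stats::t.test(value ~ group, d, var.equal = TRUE)
    expect_equal(glance(fit)$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(glance(fit)$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment matches brute-force pair enumeration and caps at 1", {
  d <- gauss_table(k = 4, means = c(0, 1, 0, 0.2), seed = 3)
  fit <- compare_groups(d, "value", "group", branch = "parametric")
  pw <- tidy(fit)
  expect_equal(nrow(pw), choose(4, 2))
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * choose(4, 2)))
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
  expect_identical(pw$significant, pw$p_adj < 0.05)
})

test_that("identical samples give a Kruskal-Wallis p of 1 and no significant pairs", {
  d <- data.frame(group = rep(c("a", "b"), each = 3), value = c(1, 2, 3, 1, 2, 3))
  fit <- compare_groups(d, "value", "group", branch = "rank")
  expect_equal(glance(fit)$p_value, 1)
  expect_false(any(tidy(fit)$significant))
})

test_that("the rank branch is invariant under strictly monotone transforms", {
  d <- gauss_table(k = 3, means = c(0, 1, 2), seed = 6)
  f1 <- compare_groups(d, "value", "group", branch = "rank")
  d$value <- exp(d$value)
  f2 <- compare_groups(d, "value", "group", branch = "rank")
  expect_equal(tidy(f1)$p_adj, tidy(f2)$p_adj)
  expect_identical(tidy(f1)$significant, tidy(f2)$significant)
  expect_equal(glance(f1)$statistic, glance(f2)$statistic)
})

test_that("percent-of-control rescales by the control mean, preserving sign", {
  d <- data.frame(group = c("control", "control", "control", "1d"),
                  value = c(2, 2, 2, 3))
  out <- percent_of_control(d, "value", "group")
  expect_equal(out$percent_of_control, c(100, 100, 100, 150))
  d2 <- data.frame(group = c("control", "1d"), value = c(10, -2))
  expect_equal(percent_of_control(d2, "value", "group")$percent_of_control[2], -20)
  dz <- data.frame(group = c("control", "1d"), value = c(0, 1))
  expect_error(percent_of_control(dz, "value", "group"),
               class = "tjquant_error_normalization")
  expect_error(percent_of_control(d, "value", "group", control_group = "sham"),
               class = "tjquant_error_normalization")
})

test_that("figure tables carry percent-of-control means, SEMs and star annotations", {
  d <- gauss_table(k = 4, n = 10, means = c(10, 14, 10.1, 9.9), seed = 8)
  fit <- compare_groups(d, "value", "group", branch = "parametric")
  tbl <- report_figure_table(fit)
  expect_equal(tbl$pct_mean[tbl$group == "control"],
               100 * tbl$mean[tbl$group == "control"] / tbl$mean[tbl$group == "control"])
  expect_equal(tbl$stars[tbl$group == "control"], "")
  strong <- tbl[tbl$group == "1d", ]
  expect_true(strong$p_adj_vs_control < 0.001)
  expect_equal(strong$stars, "***")
  # star thresholds follow the conventional cuts
  d4 <- data.frame(group = rep(c("control", "1d"), each = 4),
                   value = c(0.9, 1.0, 1.1, 1.0, 1.32, 1.15, 1.3, 1.34))
  fit4 <- compare_groups(d4, "value", "group", branch = "parametric")
  p <- report_figure_table(fit4)$p_adj_vs_control[2]
  expected <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  expect_equal(report_figure_table(fit4)$stars[2], expected)
  # a control-only table reports a single bar at 100% with no stars
  solo <- data.frame(group = rep("control", 6), value = stats::rnorm(6, 50))
  tbl0 <- report_figure_table(solo, value = "value", group = "group")
  expect_equal(nrow(tbl0), 1)
  expect_equal(tbl0$pct_mean, 100)
  expect_equal(tbl0$stars, "")
})

test_that("a group of size one forces the rank branch with a warning", {
  d <- data.frame(group = c(rep("control", 5), "1d"),
                  value = c(stats::rnorm(5), 2))
  expect_warning(fit <- compare_groups(d, "value", "group", branch = "parametric"))
  expect_equal(fit$branch, "rank")
})
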