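#' One-way analysis of variance
#'
#' Standard one-way ANOVA of a measurement across genotype or treatment
#' groups, as used for group comparisons of sleep and response measures,
#' with per-group means and standard errors alongside the F test.
#'
#' @param values numeric measurements.
#' @param group group label per measurement.
#' @return an object of class `anova_result`: list with `F`,
#'   `df_between`, `df_within`, `p_value`, and a `groups` data.frame
#'   (`group`, `n`, `mean`, `sem`).
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("need at least two groups", call. = FALSE)
  n <- tapply(values, group, length)
  if (any(n < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (all(tapply(values, group, stats::var) == 0))
    stop("zero within-group variance in every group; ANOVA degenerate",
         call. = FALSE)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1L]]
  structure(
    list(F = tab[1L, "F value"],
         df_between = tab[1L, "Df"], df_within = tab[2L, "Df"],
         p_value = tab[1L, "Pr(>F)"],
         groups = data.frame(
           group = levels(group), n = as.integer(n),
           mean = as.numeric(tapply(values, group, mean)),
           sem = as.numeric(tapply(values, group, stats::sd)) /
             sqrt(as.integer(n)),
           stringsAsFactors = FALSE),
         aov = fit),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$F, digits = digits), ", p = ",
      format.pval(x$p_value, digits = digits), "\n", sep = "")
  print(x$groups, digits = digits)
  invisible(x)
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Pairwise group comparisons with family-wise error control by the
#' studentized range, following a one-way ANOVA.
#'
#' @inheritParams one_way_anova
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, group) {
  a <- one_way_anova(values, group)
  th <- stats::TukeyHSD(a$aov)$group
  data.frame(comparison = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"],
             p_adj = th[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Proportion with exact binomial confidence interval
#'
#' Clopper-Pearson exact interval for a success proportion, e.g. the
#' fraction of a genotype among raised embryos.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf_level confidence level.
#' @return list with `k`, `n`, `estimate`, `percent`, `conf_low`,
#'   `conf_high`.
#' @export
proportion <- function(k, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(k = k, n = n, estimate = k / n, percent = 100 * k / n,
       conf_low = bt$conf.int[1L], conf_high = bt$conf.int[2L])
}
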