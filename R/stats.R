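#' Paired two-sided comparison
#'
#' Paired t-test of two equal-length sample vectors (e.g. per-organ FBV
#' under the two quantification methods). Degenerate inputs — zero
#' variance of the paired differences — are reported as such rather than
#' erroring: identical vectors give statistic 0 and p = 1; a constant
#' nonzero shift gives an infinite statistic with p = 0 and
#' `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return A `comparison_result` list: `test`, `statistic`, `p_value`,
#'   `estimate` (mean difference), `n`, `degenerate`.
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) <= max(abs(mean(d)), 1) * 1e-12) {
    res <- list(test = "paired t-test",
                statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 0,
                estimate = mean(d), n = length(x), degenerate = TRUE)
    return(structure(res, class = "comparison_result"))
  }
  tt <- t.test(x, y, paired = TRUE)
  structure(list(test = "paired t-test",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, estimate = unname(tt$estimate),
                 n = length(x), degenerate = FALSE),
            class = "comparison_result")
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha family-wise significance level for the post-hoc decisions.
#' @return A `comparison_result`: F `statistic`, `p_value`, and `tukey`, a
#'   data frame of all pairwise comparisons (difference, adjusted p,
#'   `significant` at `alpha`).
#' @export
groupwise_anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha)
  rownames(tukey) <- NULL
  structure(list(test = "one-way ANOVA + Tukey HSD",
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 tukey = tukey, alpha = alpha,
                 n = nrow(df), degenerate = FALSE),
            class = "comparison_result")
}

#' Simple linear regression with R-squared
#'
#' OLS of `y` on `x` with intercept; reports slope, intercept, R-squared
#' and the two-sided p-value for slope = 0.
#'
#' @param x,y numeric vectors, length >= 3, `x` non-degenerate.
#' @return A `comparison_result` with `slope`, `intercept`, `r_squared`,
#'   `p_value`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 (x, y) points", call. = FALSE)
  if (sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  s <- summary(fit)
  structure(list(test = "linear regression",
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 statistic = s$coefficients[2, "t value"],
                 p_value = s$coefficients[2, "Pr(>|t|)"],
                 n = length(x), degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> n = %d\n", x$test, x$n))
  if (!is.null(x$r_squared))
    cat(sprintf("  slope %.4g, intercept %.4g, R^2 = %.4f\n",
                x$slope, x$intercept, x$r_squared))
  cat(sprintf("  statistic = %.4g, p = %.4g%s\n", x$statistic, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}
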