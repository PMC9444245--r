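#' Mean and sample standard deviation
#'
#' Descriptive summary used throughout the package: arithmetic mean and
#' the n-1 (sample) standard deviation, the convention behind every
#' "mean +/- SD" reported by the analysis functions.
#'
#' @param values numeric vector (>= 1 value; SD is `NA` for a single
#'   value).
#' @return named numeric `c(mean, sd)`.
#' @examples
#' mean_sd(c(0.092, 0.059, 0.17))
#' @export
mean_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be a non-empty finite numeric vector",
         call. = FALSE)
  c(mean = mean(values),
    sd = if (length(values) >= 2L) sd(values) else NA_real_)
}

# normalize (values, group) / named-list input into a clean pair
.as_groups <- function(values, group = NULL) {
  if (is.null(group)) {
    if (!is.list(values))
      stop("supply either (values, group) or a named list of groups",
           call. = FALSE)
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- is.finite(values)
  if (!all(keep)) stop("group values must be finite", call. = FALSE)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  list(values = as.numeric(values), group = group)
}

#' One-way analysis of variance
#'
#' Standard between/within variance decomposition for k independent
#' groups, fitted via [stats::lm()]: `F = MSB / MSW` on `(k-1, N-k)`
#' degrees of freedom. When all groups share a common value the F
#' statistic is 0 (p = 1); when the within-group variance is exactly zero
#' but group means differ, F is infinite and p is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param values numeric vector of observations, or a named list of
#'   per-group vectors.
#' @param group group labels (ignored when `values` is a list).
#' @return list of class `anova_result`: `f, df_between, df_within, p,
#'   mse, ss_between, ss_within, group_means, group_n, degenerate`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
one_way_anova <- function(values, group = NULL) {
  g <- .as_groups(values, group)
  k <- nlevels(g$group)
  n <- length(g$values)
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  fit <- lm(g$values ~ g$group)
  # sums of squares straight from the fit (anova.lm warns on the
  # zero-residual degenerate case handled explicitly below)
  ssw <- sum(residuals(fit)^2)
  ssb <- sum((fitted(fit) - mean(g$values))^2)
  dfb <- k - 1L
  dfw <- n - k
  mse <- ssw / dfw
  scale <- mean(g$values^2) + 1
  degenerate <- ssw <= 1e-12 * scale
  if (degenerate) {
    if (ssb <= 1e-12 * scale) { f <- 0; p <- 1 }
    else { f <- Inf; p <- 0 }
  } else {
    f <- (ssb / dfb) / mse
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(f = f, df_between = dfb, df_within = dfw, p = p,
                 mse = mse, ss_between = ssb, ss_within = ssw,
                 group_means = tapply(g$values, g$group, mean),
                 group_n = as.vector(table(g$group)),
                 degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g%s\n",
              x$df_between, x$df_within, x$f, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Levene's test for homogeneity of variances
#'
#' Mean-centered Levene test: a one-way ANOVA on the absolute deviations
#' from each group's mean. Reported alongside the group comparison as a
#' diagnostic; it flags heteroscedasticity but never gates the analysis.
#' If every deviation is zero (all groups constant) the statistic is 0
#' and p = 1.
#'
#' @inheritParams one_way_anova
#' @return list with `statistic, df, p, method`.
#' @export
homogeneity_test <- function(values, group = NULL) {
  g <- .as_groups(values, group)
  if (any(table(g$group) < 2L))
    stop("every group needs >= 2 values for a variance test",
         call. = FALSE)
  z <- abs(g$values - ave(g$values, g$group))
  if (all(z < 1e-14 * (1 + mean(abs(g$values)))))
    return(list(statistic = 0, df = c(nlevels(g$group) - 1L,
                                      length(z) - nlevels(g$group)),
                p = 1, method = "Levene (mean-centered)"))
  a <- one_way_anova(z, g$group)
  list(statistic = a$f, df = c(a$df_between, a$df_within), p = a$p,
       method = "Levene (mean-centered)")
}

#' Fisher's LSD post hoc pairwise comparisons
#'
#' Unadjusted pairwise t tests using the ANOVA's pooled error variance:
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` on the ANOVA's
#' within-group degrees of freedom, with two-sided p values. By
#' definition no multiple-testing correction is applied; the procedure is
#' conventionally read after a significant omnibus F.
#'
#' @inheritParams one_way_anova
#' @param anova optional precomputed [one_way_anova()] result for the
#'   same data (recomputed when omitted).
#' @return data.frame of class `lsd_result`, one row per unordered pair:
#'   `group1, group2, diff, t, p, signif` (significance code at 0.05 /
#'   0.01 / 0.001).
#' @export
lsd_posthoc <- function(values, group = NULL, anova = NULL) {
  g <- .as_groups(values, group)
  if (is.null(anova)) anova <- one_way_anova(g$values, g$group)
  lev <- levels(g$group)
  means <- tapply(g$values, g$group, mean)
  ns <- table(g$group)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(anova$mse * (1 / ns[[a]] + 1 / ns[[b]]))
    d <- means[[a]] - means[[b]]
    if (se == 0) {
      t <- if (abs(d) < 1e-12) 0 else Inf * sign(d)
      p <- if (t == 0) 1 else 0
    } else {
      t <- d / se
      p <- 2 * pt(-abs(t), anova$df_within)
    }
    data.frame(group1 = a, group2 = b, diff = d, t = t, p = p)
  })
  out <- do.call(rbind, rows)
  out$signif <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", "n.s."))
  class(out) <- c("lsd_result", class(out))
  out
}
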