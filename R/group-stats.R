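# Group-level statistics: one-way ANOVA reconstructed from printed summary
# statistics, covariate-adjusted group models, pairwise post-hoc tests,
# Kruskal-Wallis, brain-behavior regression, and Benjamini-Hochberg FDR.

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the fixed-effects F test from per-group means, standard
#' deviations and sizes alone (as printed in a demographics table):
#' `MSB = sum n_g (m_g - m.)^2 / (G - 1)`,
#' `MSW = sum (n_g - 1) s_g^2 / (N - G)`, `F = MSB / MSW`, with the grand
#' mean weighted by group size. Equals classical one-way ANOVA computed on
#' the raw vectors that produced the summaries.
#'
#' @param means,sds,ns Numeric vectors (one entry per group), or pass a data
#'   frame as `means` with columns `mean`, `sd`, `n` (and optionally
#'   `group`).
#' @return An object of class `"htest"` with the F statistic, numerator and
#'   denominator df, and p value. Zero within-group variance with non-zero
#'   between-group variance yields `F = Inf`, `p = 0`.
#' @export
#' @examples
#' # age row of a published demographics table
#' anova_from_summary(means = c(24.39, 23.23, 24.64),
#'                    sds = c(3.49, 5.26, 4.22), ns = c(26, 26, 25))
anova_from_summary <- function(means, sds = NULL, ns = NULL) {
  if (is.data.frame(means)) {
    df <- means
    stopifnot(all(c("mean", "sd", "n") %in% names(df)))
    means <- df$mean; sds <- df$sd; ns <- df$n
  }
  G <- length(means)
  stopifnot(length(sds) == G, length(ns) == G)
  if (G < 2) stop("need at least two groups")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (G - 1)
  msw <- sum((ns - 1) * sds^2) / (N - G)
  if (msw == 0) {
    f <- if (msb > 0) Inf else 0
    p <- if (msb > 0) 0 else 1
  } else {
    f <- msb / msw
    p <- pf(f, G - 1, N - G, lower.tail = FALSE)
  }
  structure(list(statistic = c(F = f),
                 parameter = c(df1 = G - 1, df2 = N - G),
                 p.value = p,
                 method = "One-way ANOVA from group summary statistics",
                 data.name = paste(G, "group summaries")),
            class = "htest")
}

#' Covariate-adjusted group effect
#'
#' Least-squares linear model of a per-subject measure on group (indicator
#' contrasts) plus binary covariates (e.g. medication use, comorbid anxiety
#' or mood disorder). The group effect is tested by the extra-sum-of-squares
#' F comparing the full model against the covariates-only model; with no
#' covariates this reduces exactly to one-way ANOVA.
#'
#' @param values Numeric vector of per-subject measures.
#' @param groups Factor (or coercible) of group labels.
#' @param covariates Optional data frame / matrix of binary covariates.
#' @return List of class `"adjusted_group_test"`: the `"htest"` for the
#'   group term (`test`) and the fitted full model (`model`).
#' @export
adjusted_group_model <- function(values, groups, covariates = NULL) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  dat <- data.frame(.y = values, .g = groups)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(values))
    bad <- !vapply(covariates, function(v) all(v %in% c(0, 1)), logical(1))
    if (any(bad))
      stop("covariates must be binary indicators: ",
           paste(names(covariates)[bad], collapse = ", "))
    dat <- cbind(dat, covariates)
    f_red <- stats::reformulate(names(covariates), response = ".y")
    f_full <- stats::reformulate(c(".g", names(covariates)),
                                 response = ".y")
  } else {
    f_red <- .y ~ 1
    f_full <- .y ~ .g
  }
  full <- lm(f_full, data = dat)
  if (any(is.na(coef(full)))) {
    aliased <- names(coef(full))[is.na(coef(full))]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  red <- lm(f_red, data = dat)
  cmp <- anova(red, full)
  test <- structure(list(
    statistic = c(F = cmp$F[2]),
    parameter = c(df1 = cmp$Df[2], df2 = cmp$Res.Df[2]),
    p.value = cmp$`Pr(>F)`[2],
    method = "Covariate-adjusted group effect (extra-sum-of-squares F)",
    data.name = deparse(f_full)), class = "htest")
  structure(list(test = test, model = full), class = "adjusted_group_test")
}

#' @export
print.adjusted_group_test <- function(x, ...) {
  print(x$test)
  invisible(x)
}

#' Pairwise post-hoc comparisons
#'
#' All pairwise Welch two-sample t tests between groups, with either
#' Bonferroni adjustment (p multiplied by the number of pairs, capped at 1)
#' or a Dunnett-T3-style adjustment referring |t| to the studentized maximum
#' modulus with Welch df, here approximated by the independence form
#' `1 - (2 P(T <= |t|) - 1)^m`.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group labels.
#' @param method `"bonferroni_welch"` (default) or `"dunnett_t3"`.
#' @return Data frame: `group1`, `group2`, `statistic`, `df`, `p_value`,
#'   `adjusted_p`, `method`.
#' @export
pairwise_posthoc <- function(values, groups,
                             method = c("bonferroni_welch", "dunnett_t3")) {
  method <- match.arg(method)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs n >= 2; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  pairs <- combn(lev, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- t.test(values[groups == g1], values[groups == g2])
    data.frame(group1 = g1, group2 = g2,
               statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$adjusted_p <- switch(method,
    bonferroni_welch = pmin(1, out$p_value * m),
    dunnett_t3 = {
      q <- 2 * pt(abs(out$statistic), out$df) - 1
      1 - q^m
    })
  out$method <- method
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Non-parametric alternative to one-way ANOVA; wraps
#' [stats::kruskal.test()] (rank-based H with tie correction, chi-square
#' reference with G-1 df) with input validation, and defines the degenerate
#' all-identical case as `H = 0`, `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group labels.
#' @return An `"htest"` object.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(values) < 3) stop("need at least three observations in total")
  if (length(unique(values)) == 1) {
    return(structure(list(
      statistic = c(`Kruskal-Wallis chi-squared` = 0),
      parameter = c(df = nlevels(groups) - 1), p.value = 1,
      method = "Kruskal-Wallis rank sum test",
      data.name = "values by groups"), class = "htest"))
  }
  kruskal.test(values, groups)
}

#' Brain-behavior linear regression
#'
#' Ordinary least-squares regression of a connectivity measure on a
#' behavioral score, reporting the slope, Pearson correlation, and the
#' two-sided t test on the slope.
#'
#' @param x Behavioral scores (predictor).
#' @param y Connection strengths (response).
#' @return List of class `"brain_behavior_fit"`: `slope`, `intercept`, `r`,
#'   `statistic` (t), `df`, `p.value`, `n`.
#' @export
#' @examples
#' brain_behavior_regression(1:10, 2 * (1:10))$r  # 1
brain_behavior_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least three paired finite observations")
  if (var(x) == 0) stop("predictor has zero variance; slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = unname(cor(x, y)),
                 statistic = sm$coefficients[2, "t value"],
                 df = n - 2,
                 p.value = sm$coefficients[2, "Pr(>|t|)"],
                 n = n),
            class = "brain_behavior_fit")
}

#' @export
print.brain_behavior_fit <- function(x, ...) {
  cat("Brain-behavior regression (n =", x$n, ")\n")
  cat("  slope =", format(x$slope, digits = 4),
      " r =", format(x$r, digits = 4),
      " t(", x$df, ") =", format(x$statistic, digits = 4),
      " p =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p values (`stats::p.adjust(method = "BH")` with
#' range validation): sorted ascending, `q_(i) = min_{j >= i} p_(j) m / j`,
#' capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted vector, same length and order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.001, 0.5))  # 0.002 0.500
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
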