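#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 template
#' dilution. Amplification efficiency is derived from the slope as
#' E = (10^(-1/slope) - 1) * 100 and reported to one decimal; curves with
#' E outside the 90-110% band or R^2 <= 0.98 are flagged.
#'
#' @param dilution_log10 numeric vector of log10 dilutions (>= 3 distinct).
#' @param cq numeric vector of Cq values.
#' @return list: `slope`, `intercept`, `r_squared`, `efficiency`
#'   (percent, 1 decimal), `flagged` (logical), `n`.
#' @export
fit_standard_curve <- function(dilution_log10, cq) {
  stopifnot(length(dilution_log10) == length(cq), length(cq) >= 3L)
  if (length(unique(dilution_log10)) < 2L)
    stop("degenerate standard curve: dilutions are not distinct")
  fit <- lm(cq ~ dilution_log10)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate standard curve fit")
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  eff <- .round_half_up((10^(-1 / slope) - 1) * 100, 1L)
  list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
       efficiency = eff, flagged = (eff < 90 || eff > 110 || r2 <= 0.98),
       n = length(cq))
}

#' NORMA-Gene normalization of a qPCR expression table
#'
#' Reference-gene-free normalization: per-sample multiplicative correction
#' factors minimizing, in log space, the summed squared deviation of each
#' gene's expression from its cross-sample mean. The least-squares
#' solution is closed-form - each sample's factor is the geometric mean,
#' across genes, of that sample's entry over the gene's cross-sample
#' geometric mean - and factors are anchored to geometric mean 1 so the
#' global expression level is preserved. An iterative optimizer over the
#' same objective is used as a cross-check in the test suite.
#'
#' @param table positive numeric matrix (genes x samples), >= 3 genes
#'   (>= 5 recommended; a warning is issued below that).
#' @return list: `normalized` (matrix), `factors` (per-sample).
#' @export
normagene <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("NORMA-Gene requires positive finite expression values")
  if (nrow(m) < 3L) stop("NORMA-Gene requires >= 3 genes")
  if (nrow(m) < 5L) warning("fewer than 5 genes; normalization is weak")
  y <- log(m)
  phi <- colMeans(y - rowMeans(y))          # per-sample log factors
  phi <- phi - mean(phi)                    # geometric-mean-1 anchor
  factors <- exp(phi)
  list(normalized = sweep(m, 2L, factors, "/"), factors = factors)
}

# Residual sum of squares of the NORMA-Gene objective (internal, used by
# tests and the iterative cross-check).
.normagene_rss <- function(m) {
  y <- log(as.matrix(m))
  sum((y - rowMeans(y))^2)
}

#' Grubbs single-outlier test
#'
#' Two-sided Grubbs statistic G = max|x - mean| / sd compared against the
#' t-distribution-based critical value at level `alpha`; at most one value
#' is ever flagged.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list: `outlier_index` (or `NA` when none), `G`, `critical`,
#'   `p_threshold_alpha`.
#' @export
grubbs <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test requires n >= 3")
  s <- sd(values)
  if (s == 0)
    return(list(outlier_index = NA_integer_, G = 0, critical = NA_real_,
                alpha = alpha))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  idx <- if (G > crit) which.max(dev) else NA_integer_
  list(outlier_index = idx, G = G, critical = crit, alpha = alpha)
}

#' One-tailed Welch's t-test
#'
#' Welch t statistic with Satterthwaite degrees of freedom and a
#' one-tailed p-value in the stated direction (`"greater"` tests
#' mean(a) > mean(b)). Reported with fractional df in the conventional
#' "df = 5.229, t = 4.184" style via `format_comparison()`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param direction "greater" or "less" (alternative for mean(a) - mean(b)).
#' @return list of class `group_comparison`: `test`, `t`, `df`, `p`,
#'   `direction`.
#' @export
welch_t_one_tailed <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(test = "welch_one_tailed", t = 0, df = NA_real_,
                            p = 0.5, direction = direction),
                       class = "group_comparison"))
    p <- if ((mean(a) > mean(b)) == (direction == "greater")) 0 else 1
    return(structure(list(test = "welch_one_tailed",
                          t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                          p = p, direction = direction),
                     class = "group_comparison"))
  }
  tt <- t.test(a, b, alternative = direction, var.equal = FALSE)
  structure(list(test = "welch_one_tailed", t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 direction = direction),
            class = "group_comparison")
}

#' One-way ANOVA with Tukey's HSD post-hoc test
#'
#' @param groups named list of numeric vectors (typically the three
#'   SI/SD/SS treatment groups, each n >= 2; two groups are accepted, where
#'   the F statistic equals the squared pooled t statistic).
#' @return list of class `group_comparison`: `test`, `F`, `df1`, `df2`,
#'   `p`, `pairwise` (data.frame comparison/diff/p_adj).
#' @export
anova_tukey <- function(groups) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  if (var(df$value) == 0) {
    # all observations identical: no variance to partition
    prs <- utils::combn(names(groups), 2, function(x)
      paste(x[2], x[1], sep = "-"))
    return(structure(list(test = "anova_tukey", F = 0,
                          df1 = length(groups) - 1L,
                          df2 = nrow(df) - length(groups), p = 1,
                          pairwise = data.frame(comparison = prs, diff = 0,
                                                p_adj = 1,
                                                stringsAsFactors = FALSE)),
                     class = "group_comparison"))
  }
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(list(test = "anova_tukey",
                 F = an[1, "F value"], df1 = an[1, "Df"], df2 = an[2, "Df"],
                 p = an[1, "Pr(>F)"],
                 pairwise = data.frame(comparison = rownames(tk),
                                       diff = tk[, "diff"],
                                       p_adj = tk[, "p adj"],
                                       row.names = NULL,
                                       stringsAsFactors = FALSE)),
            class = "group_comparison")
}

#' Format a group comparison in the conventional reporting style
#'
#' e.g. `"df = 5.229, t = 4.184, p = 0.0039"` for a Welch test or
#' `"F_2,16 = 10.58, p = 0.0012"` for an ANOVA.
#'
#' @param x a `group_comparison`.
#' @return character scalar.
#' @export
format_comparison <- function(x) {
  stopifnot(inherits(x, "group_comparison"))
  if (x$test == "welch_one_tailed") {
    sprintf("df = %.3f, t = %.3f, p = %.4f", x$df, x$t, x$p)
  } else {
    sprintf("F_%d,%d = %.2f, p = %.4f", x$df1, x$df2, x$F, x$p)
  }
}

#' Fold changes relative to a reference group
#'
#' Divides each gene's entries by the mean of that gene over the reference
#' group's samples.
#'
#' @param table numeric matrix (genes x samples).
#' @param groups named character vector mapping sample -> group.
#' @param reference reference group label (e.g. "SI").
#' @return matrix of fold changes.
#' @export
fold_change <- function(table, groups, reference) {
  m <- as.matrix(table)
  grp <- groups[colnames(m)]
  if (!reference %in% grp) stop("reference group not present")
  ref_mean <- rowMeans(m[, grp == reference, drop = FALSE])
  if (any(ref_mean == 0)) stop("zero reference mean")
  sweep(m, 1L, ref_mean, "/")
}

#' Pearson correlation between a miRNA and a target mRNA
#'
#' Sample Pearson r with the two-sided p-value from the t transform.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list: `r`, `n`, `p`, `significant` (p < 0.05).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n = length(x), p = NA_real_,
                significant = NA, degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value,
       significant = ct$p.value < 0.05, degenerate = FALSE)
}
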