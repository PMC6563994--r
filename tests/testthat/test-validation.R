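# qPCR-side statistics: standard curves, NORMA-Gene, Grubbs, Welch,
# ANOVA/Tukey, fold change, Pearson.

test_that("standard-curve efficiency: slope -3.3219 gives exactly 100.0%
           and off-band slopes are computed analytically and flagged", {
  d <- c(0, -1, -2, -3, -4, -5, -6)
  cq100 <- 20 - 3.3219 * d
  sc <- fit_standard_curve(d, cq100)
  expect_equal(sc$efficiency, 100.0)
  expect_false(sc$flagged)
  cq31 <- 20 - 3.1 * d
  sc2 <- fit_standard_curve(d, cq31)
  analytic <- floor((10^(1 / 3.1) - 1) * 1000 + 0.5) / 10
  expect_equal(sc2$efficiency, analytic)
  expect_true(sc2$flagged)              # outside the 90-110% band
  # noisy but tight curve keeps R^2 > 0.98 and stays unflagged
  set.seed(100)
  sc3 <- fit_standard_curve(d, 20 - 3.3 * d + rnorm(7, 0, 0.05))
  expect_gt(sc3$r_squared, 0.98)
  expect_false(sc3$flagged)
  expect_error(fit_standard_curve(rep(1, 3), c(1, 2, 3)), "degenerate")
})

test_that("NORMA-Gene: fixed point on per-gene-constant tables, predictable
           column-scaling equivariance, objective never increases, and
           factors match a numerical optimizer", {
  tab <- matrix(rep(c(4, 9, 25, 2, 7), 6), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  out <- normagene(tab)
  expect_equal(unname(out$factors), rep(1, 6))
  expect_equal(out$normalized, tab)
  # scaling one of m columns by c rescales the anchored output globally by
  # c^(1/m); after dividing by that factor the output is unchanged
  set.seed(101)
  x <- matrix(exp(rnorm(5 * 6, 2, 0.4)), 5, 6,
              dimnames = dimnames(tab))
  c0 <- 3
  y <- x; y[, 2] <- y[, 2] * c0
  n1 <- normagene(x)$normalized
  n2 <- normagene(y)$normalized
  expect_equal(n2 / c0^(1 / 6), n1, tolerance = 1e-10)
  # objective never increases
  expect_lte(troutmir:::.normagene_rss(normagene(x)$normalized),
             troutmir:::.normagene_rss(x))
  # independent optimizer over per-sample log factors, same objective
  obj <- function(phi) {
    y2 <- log(x) - matrix(phi, nrow(x), ncol(x), byrow = TRUE)
    sum((y2 - rowMeans(y2))^2)
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  phi_opt <- opt$par - mean(opt$par)
  expect_equal(unname(normagene(x)$factors), unname(exp(phi_opt)),
               tolerance = 1e-5)
  expect_error(normagene(matrix(c(-1, 2, 3, 4, 5, 6), 3, 2)), "positive")
  expect_error(normagene(x[1:2, ]), ">= 3")
})

test_that("Grubbs flags the planted outlier against the t-based critical
           value, removes at most one value, and is silent on constants", {
  expect_true(is.na(grubbs(rep(2.5, 5))$outlier_index))
  v <- c(1.0, 1.1, 0.9, 5.0)
  g <- grubbs(v)
  expect_equal(g$outlier_index, 4L)
  # critical-value oracle from the t quantile
  n <- 4
  tcrit <- qt(1 - 0.05 / (2 * n), n - 2)
  expect_equal(g$critical, (n - 1) / sqrt(n) * sqrt(tcrit^2 /
                                                      (n - 2 + tcrit^2)))
  expect_gt(g$G, g$critical)
  # two extremes: still a single removal
  v2 <- c(1.0, 1.05, 0.95, 1.02, 40, -40.5)
  expect_length(grubbs(v2)$outlier_index, 1L)
  expect_error(grubbs(c(1, 2)), "n >= 3")
})

test_that("Grubbs removal rate on pure standard-normal samples stays near
           its nominal level", {
  set.seed(102)
  hits <- mean(replicate(200, !is.na(grubbs(rnorm(6))$outlier_index)))
  expect_lte(hits, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("one-tailed Welch reproduces the oracle with fractional df and
           reports in the conventional style", {
  a <- c(3.2, 4.1, 3.8, 4.4, 3.9)
  b <- c(2.1, 2.9, 2.4, 2.2)
  w <- welch_t_one_tailed(a, b, "greater")
  o <- oracle_welch(a, b, "greater")
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_false(w$df == round(w$df))     # fractional Satterthwaite df
  expect_match(format_comparison(w), "^df = \\d+\\.\\d{3}, t = ")
  # equal group means with zero variance: p = 0.5 by convention
  expect_equal(welch_t_one_tailed(c(2, 2), c(2, 2), "greater")$p, 0.5)
  # Welch df bounded by min(n) - 1 and n1 + n2 - 2
  expect_gte(w$df, min(length(a), length(b)) - 1)
  expect_lte(w$df, length(a) + length(b) - 2)
})

test_that("ANOVA with Tukey post-hoc matches the hand-computed F and the
           studentized-range oracle, and degenerates sensibly", {
  g <- list(SI = c(1.0, 1.2, 0.8), SD = c(2.1, 2.0, 2.4),
            SS = c(3.0, 3.3, 2.9))
  res <- anova_tukey(g)
  # hand-computed one-way F
  k <- 3; ns <- lengths(g); N <- sum(ns)
  gm <- mean(unlist(g))
  ssb <- sum(ns * (vapply(g, mean, 0) - gm)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  Fhand <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$F, Fhand, tolerance = 1e-12)
  expect_equal(res$df1, 2L); expect_equal(res$df2, 6L)
  expect_match(format_comparison(res), "^F_2,6 = ")
  # Tukey pairwise p against the studentized-range oracle
  o <- oracle_tukey(g)
  for (cmp in res$pairwise$comparison)
    expect_equal(res$pairwise$p_adj[res$pairwise$comparison == cmp],
                 o[[cmp]], tolerance = 1e-9, info = cmp)
  # identical groups: F = 0, p = 1
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  expect_equal(anova_tukey(same)$F, 0)
  expect_equal(anova_tukey(same)$p, 1)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2), c = c(1, 2))),
               "n >= 2")
})

test_that("two-group ANOVA reproduces the squared pooled t statistic", {
  a <- c(3.1, 2.8, 3.5, 3.0); b <- c(2.2, 2.6, 2.1, 2.4)
  res <- anova_tukey(list(A = a, B = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("fold changes divide by the reference-group mean and are scale
           invariant", {
  m <- rbind(g1 = c(2, 4, 6, 8), g2 = c(1, 1, 3, 5))
  colnames(m) <- c("si1", "si2", "x1", "x2")
  groups <- c(si1 = "SI", si2 = "SI", x1 = "SS", x2 = "SS")
  fc <- fold_change(m, groups, "SI")
  expect_equal(unname(fc["g1", ]), c(2, 4, 6, 8) / 3)
  expect_equal(rowMeans(fc[, 1:2]), c(g1 = 1, g2 = 1))
  expect_equal(fold_change(m * 7, groups, "SI"), fc)
  expect_error(fold_change(m, groups, "SD"), "not present")
  m0 <- m; m0["g2", 1:2] <- 0
  expect_error(fold_change(m0, groups, "SI"), "zero reference")
})

test_that("Pearson correlation: perfect affine relations give r of +/-1,
           toys match the covariance-formula oracle, and affine transforms
           leave r unchanged", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(103)
  a <- rnorm(10); b <- 0.6 * a + rnorm(10, 0, 0.5)
  pc <- pearson(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt((10 - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), 10 - 2)
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  expect_equal(pc$p, p_hand, tolerance = 1e-12)
  expect_equal(pearson(3 * a + 2, b)$r, pc$r, tolerance = 1e-12)
  expect_true(pearson(a, rep(1, 10))$degenerate)
})
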