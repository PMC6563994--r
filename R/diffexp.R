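#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over miRNAs
#' with nonzero counts in every sample, of the ratio of each count to the
#' miRNA's geometric mean across samples; factors are rescaled to
#' geometric mean 1. When no miRNA is nonzero everywhere, falls back to
#' total-count scaling with a warning.
#'
#' @param m non-negative integer count matrix (miRNAs x samples).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(m >= 0))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    warning("no miRNA with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    f <- colSums(m)
    f <- f / exp(mean(log(f)))
    return(f)
  }
  sub <- m[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  f <- apply(sub / geo, 2L, median)
  f / exp(mean(log(f)))
}

#' Two-group differential expression of miRNA counts
#'
#' Default method: Welch's two-sample t-test on log2(normalized count +
#' pseudocount), with log2 fold change defined as mean(SS) - mean(SD) and
#' two-sided p-values; no multiplicity correction enters the call (raw
#' p < alpha), but BH-adjusted values are reported alongside. A
#' negative-binomial Wald alternative (DESeq2) is available behind
#' `method = "nbinom"`.
#'
#' @param m count matrix (miRNAs x samples) with rownames.
#' @param groups named character vector mapping sample -> "SS"/"SD".
#' @param factors size factors (default [size_factors()]).
#' @param method "welch" (default) or "nbinom".
#' @param pseudocount added before log2 (default 0.5).
#' @param alpha significance threshold on raw p (default 0.05).
#' @return data.frame: `mirna`, `baseMean`, `log2FC`, `t`, `df`, `p`,
#'   `padj`, `significant`, `direction`.
#' @export
de_test <- function(m, groups, factors = size_factors(m),
                    method = c("welch", "nbinom"), pseudocount = 0.5,
                    alpha = 0.05) {
  method <- match.arg(method)
  m <- as.matrix(m)
  stopifnot(!is.null(rownames(m)), all(colnames(m) %in% names(groups)))
  grp <- groups[colnames(m)]
  stopifnot(sum(grp == "SS") >= 2L, sum(grp == "SD") >= 2L)
  norm <- sweep(m, 2L, factors, "/")
  if (method == "nbinom") {
    if (!requireNamespace("DESeq2", quietly = TRUE))
      stop("method = 'nbinom' requires the DESeq2 package")
    cd <- data.frame(group = factor(grp, levels = c("SD", "SS")))
    dds <- DESeq2::DESeqDataSetFromMatrix(round(m), cd, ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("group", "SS", "SD"))
    out <- data.frame(mirna = rownames(m), baseMean = res$baseMean,
                      log2FC = res$log2FoldChange, t = res$stat,
                      df = NA_real_, p = res$pvalue,
                      stringsAsFactors = FALSE)
    out$p[is.na(out$p)] <- 1
  } else {
    lg <- log2(norm + pseudocount)
    ss <- lg[, grp == "SS", drop = FALSE]
    sd_ <- lg[, grp == "SD", drop = FALSE]
    res <- lapply(seq_len(nrow(m)), function(i) {
      a <- ss[i, ]; b <- sd_[i, ]
      fc <- mean(a) - mean(b)
      if (var(a) == 0 && var(b) == 0) {
        if (mean(a) == mean(b)) return(c(fc = fc, t = 0, df = NA, p = 1))
        return(c(fc = fc, t = sign(fc) * Inf, df = NA, p = 0))
      }
      tt <- t.test(a, b, var.equal = FALSE)
      c(fc = fc, t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    })
    res <- do.call(rbind, res)
    out <- data.frame(mirna = rownames(m), baseMean = rowMeans(norm),
                      log2FC = res[, "fc"], t = res[, "t"],
                      df = res[, "df"], p = res[, "p"],
                      stringsAsFactors = FALSE)
  }
  out$padj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out$direction <- ifelse(out$log2FC > 0, "up_SS", "up_SD")
  rownames(out) <- NULL
  out
}

#' Partition significant calls by direction
#'
#' @param results data.frame from [de_test()].
#' @return list with `up_SS` and `up_SD` character vectors of miRNA ids.
#' @export
call_and_split <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  list(up_SS = sig$mirna[sig$direction == "up_SS"],
       up_SD = sig$mirna[sig$direction == "up_SD"])
}

#' Row/column ordering for the DE heat map
#'
#' Average-linkage hierarchical clustering on Euclidean distances of
#' row-z-scored log2 normalized counts, as used for displaying
#' differentially regulated miRNAs. Rows are pre-sorted by id so equal
#' distances resolve deterministically.
#'
#' @param m normalized count matrix restricted to significant miRNAs.
#' @param pseudocount added before log2.
#' @return list with `row_order` and `col_order` (integer permutations of
#'   the sorted-by-id input), plus the `hclust` objects.
#' @export
cluster_order <- function(m, pseudocount = 0.5) {
  m <- as.matrix(m)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2L)
    return(list(row_order = seq_len(nrow(m)),
                col_order = seq_len(ncol(m)),
                row_hclust = NULL, col_hclust = NULL))
  lg <- log2(m + pseudocount)
  z <- t(scale(t(lg)))
  z[!is.finite(z)] <- 0
  hr <- hclust(dist(z), method = "average")
  hc <- if (ncol(m) >= 2L) hclust(dist(t(z)), method = "average") else NULL
  list(row_order = hr$order,
       col_order = if (is.null(hc)) seq_len(ncol(m)) else hc$order,
       row_hclust = hr, col_hclust = hc,
       ids = rownames(m))
}
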