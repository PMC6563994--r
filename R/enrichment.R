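#' Unique target-gene set of a prediction table
#'
#' @param predictions data.frame from [scan_targets()].
#' @return sorted character vector of genes with >= 1 passing prediction.
#' @export
build_target_set <- function(predictions) {
  sort(unique(predictions$gene))
}

#' Upper-tail hypergeometric (Fisher) over-representation p-value
#'
#' P(X >= k) for X hypergeometric with `n` draws, `K` annotated genes in a
#' background of `N`.
#'
#' @param k targets annotated with the term.
#' @param n target-set size.
#' @param K background genes annotated with the term.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
fisher_term <- function(k, n, K, N) {
  if (k > n || K > N || k > K || n > N || any(c(k, n, K, N) < 0))
    stop("inconsistent counts for hypergeometric test")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term over-representation of a target-gene set
#'
#' One-sided hypergeometric test per term against a genome background,
#' with Benjamini-Hochberg adjustment across all tested terms. Terms with
#' fewer than `min_bg` background genes are excluded as uninformative.
#'
#' @param target_set character vector of target genes.
#' @param go_map data.frame with `gene`, `term` columns covering the
#'   background.
#' @param background character vector of all background genes.
#' @param min_bg minimum background genes per tested term (default 2).
#' @return data.frame sorted by p: `term`, `k`, `n`, `K`, `N`, `p`, `q`.
#' @export
enrich <- function(target_set, go_map, background, min_bg = 2L) {
  if (!length(target_set)) {
    warning("empty target set; returning empty enrichment table")
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  stopifnot(all(target_set %in% background))
  go_map <- go_map[go_map$gene %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(target_set))
  terms <- split(go_map$gene, go_map$term)
  terms <- lapply(terms, unique)
  terms <- terms[lengths(terms) >= min_bg]
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- sum(target_set %in% terms[[tm]])
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = fisher_term(k, n, K, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
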