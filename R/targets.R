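#' Duplex alignment scoring scheme
#'
#' The miRanda-convention residue-pair scores used by [align_duplex()]:
#' Watson-Crick match +5, G:U wobble +1, mismatch -3, affine gaps -9 to
#' open and -4 to extend, with scores at miRNA seed positions (2-8 from
#' the 5' end) scaled by 4. Only the acceptance thresholds (S > 140,
#' duplex free energy < -20 kcal/mol) are fixed by the method; the scheme
#' itself is fully configurable.
#'
#' @param match,mismatch,wobble residue-pair scores (match > 0 > mismatch).
#' @param gap_open,gap_extend affine gap scores (negative).
#' @param seed_start,seed_end 5'-based miRNA positions of the seed.
#' @param seed_scale multiplier (>= 1) applied to seed-position scores.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -3, wobble = 1,
                           gap_open = -9, gap_extend = -4,
                           seed_start = 2L, seed_end = 8L,
                           seed_scale = 4) {
  stopifnot(match > 0, mismatch < 0, seed_scale >= 1,
            gap_open < 0, gap_extend < 0, seed_start <= seed_end)
  structure(list(match = match, mismatch = mismatch, wobble = wobble,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_scale = seed_scale),
            class = "scoring_scheme")
}

#' Align a miRNA against a 3'UTR window
#'
#' Best local alignment of the miRNA (read 3'->5') against the window
#' (5'->3') under the scheme, by affine-gap dynamic programming; residue
#' pairs at miRNA seed positions contribute scaled scores. Ties resolve
#' deterministically toward the earliest-scanned cell.
#'
#' @param mirna miRNA sequence (5'->3', 18-26 nt typical).
#' @param window UTR window sequence (5'->3').
#' @param scheme a [scoring_scheme()].
#' @return list with `S` (score), `trace` (data.frame `mirna_pos`
#'   (5'-based), `window_pos`, `type` in mismatch/wobble/match).
#' @export
align_duplex <- function(mirna, window, scheme = scoring_scheme()) {
  if (!nzchar(window) || !nzchar(mirna))
    return(list(S = 0, trace = data.frame(mirna_pos = integer(0),
                                          window_pos = integer(0),
                                          type = character(0))))
  res <- duplex_align_cpp(.as_dna(mirna), .as_dna(window),
                          scheme$match, scheme$mismatch, scheme$wobble,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$seed_start, scheme$seed_end,
                          scheme$seed_scale)
  type <- c("mismatch", "wobble", "match")[res$type + 1L]
  list(S = res$S,
       trace = data.frame(mirna_pos = res$mirna_pos,
                          window_pos = res$window_pos,
                          type = type, stringsAsFactors = FALSE))
}

#' Free energy of a duplex described by an alignment trace
#'
#' Nearest-neighbor sum over consecutive paired dinucleotide stacks of the
#' alignment trace (the same duplex the score S describes, not an
#' independent fold), plus a loop/bulge penalty for each interruption
#' between paired runs. A single isolated pair carries no stack and
#' contributes 0.
#'
#' @param trace trace data.frame from [align_duplex()].
#' @param mirna,window the aligned sequences.
#' @param intr_open,intr_per_nt interruption penalty parameters
#'   (kcal/mol), shared with the folding model defaults.
#' @return duplex free energy in kcal/mol.
#' @export
duplex_energy <- function(trace, mirna, window,
                          intr_open = 3.0, intr_per_nt = 0.5) {
  paired <- trace[trace$type %in% c("match", "wobble"), , drop = FALSE]
  if (nrow(paired) < 2L) return(0)
  mirna <- .as_rna(mirna); window <- .as_rna(window)
  stack <- stack_energy_table()
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  # order along the window (5'->3'); miRNA positions then descend
  paired <- paired[order(paired$window_pos), , drop = FALSE]
  dG <- 0
  any_stack <- FALSE
  for (k in seq_len(nrow(paired) - 1L)) {
    w1 <- paired$window_pos[k]; w2 <- paired$window_pos[k + 1L]
    m1 <- paired$mirna_pos[k];  m2 <- paired$mirna_pos[k + 1L]
    # pair as (window base, miRNA base), window strand read 5'->3'
    p1 <- paste0(substr(window, w1, w1), substr(mirna, m1, m1))
    p2 <- paste0(substr(window, w2, w2), substr(mirna, m2, m2))
    if (!(p1 %in% pairs) || !(p2 %in% pairs)) next
    if (w2 == w1 + 1L && m2 == m1 - 1L) {
      dG <- dG + stack[p1, p2]
      any_stack <- TRUE
    } else {
      gap <- (w2 - w1 - 1L) + (m1 - m2 - 1L)
      dG <- dG + intr_open + intr_per_nt * gap
    }
  }
  if (!any_stack) return(0)
  dG
}

#' Scan 3'UTRs for miRNA target sites
#'
#' Slides a window of width `length(miRNA) + 10` (stride 1) along each
#' UTR, aligns the miRNA, computes the duplex free energy from the
#' alignment trace, keeps hits with `S > s_min` and `dG < dg_max` (both
#' strict), and merges overlapping hits keeping the max-S representative.
#'
#' @param mirnas named character vector of mature sequences.
#' @param utrs named character vector of UTR sequences.
#' @param scheme a [scoring_scheme()].
#' @param s_min score threshold (exclusive; default 140).
#' @param dg_max free-energy threshold (exclusive; default -20 kcal/mol).
#' @return data.frame: `mirna`, `gene`, `start`, `end` (0-based half-open
#'   window coordinates on the UTR), `S`, `dG`, `passes` (all TRUE after
#'   filtering; retained for schema clarity).
#' @export
scan_targets <- function(mirnas, utrs, scheme = scoring_scheme(),
                         s_min = 140, dg_max = -20) {
  out <- list()
  for (mi in names(mirnas)) {
    mseq <- .as_dna(mirnas[[mi]])
    wlen <- nchar(mseq) + 10L
    for (g in names(utrs)) {
      u <- .as_dna(utrs[[g]])
      if (nchar(u) < wlen) next
      scores <- duplex_scan_cpp(mseq, u, wlen, scheme$match,
                                scheme$mismatch, scheme$wobble,
                                scheme$gap_open, scheme$gap_extend,
                                scheme$seed_start, scheme$seed_end,
                                scheme$seed_scale)
      cand <- which(scores > s_min)
      if (!length(cand)) next
      hits <- list()
      for (s0 in cand) {
        win <- substr(u, s0, s0 + wlen - 1L)
        aln <- align_duplex(mseq, win, scheme)
        dG <- duplex_energy(aln$trace, mseq, win)
        if (aln$S > s_min && dG < dg_max)
          hits[[length(hits) + 1L]] <- data.frame(
            mirna = mi, gene = g, start = s0 - 1L, end = s0 - 1L + wlen,
            S = aln$S, dG = dG, stringsAsFactors = FALSE)
      }
      if (!length(hits)) next
      h <- do.call(rbind, hits)
      # merge overlapping windows, keeping the max-S representative
      h <- h[order(h$start), , drop = FALSE]
      keep <- list()
      cur <- h[1, , drop = FALSE]
      cur_end <- h$end[1]
      for (r in seq_len(nrow(h))[-1]) {
        if (h$start[r] < cur_end) {
          if (h$S[r] > cur$S) cur <- h[r, , drop = FALSE]
          cur_end <- max(cur_end, h$end[r])
        } else {
          keep[[length(keep) + 1L]] <- cur
          cur <- h[r, , drop = FALSE]
          cur_end <- h$end[r]
        }
      }
      keep[[length(keep) + 1L]] <- cur
      out[[length(out) + 1L]] <- do.call(rbind, keep)
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(0), gene = character(0),
                      start = integer(0), end = integer(0),
                      S = numeric(0), dG = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$passes <- TRUE
  rownames(res) <- NULL
  res
}
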