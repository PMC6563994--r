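#' Match a tag against mature miRNA reference sets
#'
#' Bowtie-seed-style matching of a unique tag to mature references: the tag
#' is anchored at its 5' end, at most one mismatch is allowed within
#' positions 1-16, positions beyond 16 of the overlap must match exactly,
#' and the 3' length difference may be at most 2 nt (the pipeline's isomiR
#' tolerance).
#'
#' @param tag tag sequence (DNA or RNA alphabet).
#' @param db named list of reference sets, e.g.
#'   `list(specific = c(id = seq, ...), selected = c(...))`; names of each
#'   vector are reference miRNA ids.
#' @param max_len_diff maximum absolute 3' length difference (default 2).
#' @return data.frame with columns `ref_id`, `class`, `mismatches`,
#'   `mismatch_positions` (comma-separated, 1-based along the tag); zero
#'   rows when there is no hit.
#' @export
match_mirbase <- function(tag, db, max_len_diff = 2L) {
  stopifnot(length(db) > 0)
  tag <- .as_dna(tag)
  t_int <- utf8ToInt(tag)
  tlen <- length(t_int)
  out <- list()
  for (cls in names(db)) {
    refs <- db[[cls]]
    for (k in seq_along(refs)) {
      ref <- .as_dna(refs[[k]])
      rlen <- nchar(ref)
      if (abs(tlen - rlen) > max_len_diff) next
      L <- min(tlen, rlen)
      r_int <- utf8ToInt(ref)[seq_len(L)]
      mism <- which(t_int[seq_len(L)] != r_int)
      seed_m <- sum(mism <= 16L)
      rest_m <- sum(mism > 16L)
      if (seed_m <= 1L && rest_m == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = names(refs)[k], class = cls,
          mismatches = length(mism),
          mismatch_positions = paste(mism, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(ref_id = character(0), class = character(0),
                      mismatches = integer(0),
                      mismatch_positions = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Exact genome placement of a sequence
#'
#' All exact-match placements of a sequence on both strands of the genome
#' (reverse complement searched for the minus strand), in deterministic
#' (contig, start) order. Coordinates are 0-based half-open.
#'
#' @param seq sequence to place.
#' @param genome named character vector of contig sequences.
#' @return data.frame with `contig`, `start`, `end`, `strand`.
#' @export
map_genome <- function(seq, genome) {
  seq <- .as_dna(seq)
  subject <- Biostrings::DNAStringSet(.as_dna(unname(genome)))
  names(subject) <- names(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") seq else .revcomp(seq)
    m <- Biostrings::vmatchPattern(pat, subject)
    for (ci in seq_along(m)) {
      ir <- m[[ci]]
      if (length(ir) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig = names(subject)[ci],
        start = IRanges::start(ir) - 1L,
        end = IRanges::end(ir),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, hits)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the hairpin candidate window around a locus
#'
#' Returns the genomic window `[start - flank, end + flank)` on the locus
#' strand (reverse complemented for minus-strand loci), truncated silently
#' at contig ends, together with the mature's 1-based coordinates within
#' the window.
#'
#' @param locus one-row data.frame or list with `contig`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genome named character vector of contigs.
#' @param flank flank width in nt (default 80).
#' @return list with `window`, `mature_start`, `mature_end`, `truncated`.
#' @export
flanks <- function(locus, genome, flank = 80L) {
  contig <- genome[[locus$contig]]
  clen <- nchar(contig)
  stopifnot(locus$start >= 0, locus$end <= clen, locus$start < locus$end)
  w_start <- max(0L, locus$start - flank)          # 0-based
  w_end <- min(clen, locus$end + flank)
  window <- substr(contig, w_start + 1L, w_end)
  m_start <- locus$start - w_start + 1L            # 1-based in window
  m_end <- m_start + (locus$end - locus$start) - 1L
  if (identical(locus$strand, "-")) {
    wlen <- nchar(window)
    window <- .revcomp(window)
    new_start <- wlen - m_end + 1L
    m_end <- wlen - m_start + 1L
    m_start <- new_start
  }
  list(window = window, mature_start = m_start, mature_end = m_end,
       truncated = (locus$start - flank < 0L) || (locus$end + flank > clen))
}

#' Screen a tag against contaminant RNA classes
#'
#' Exact substring match against per-class reference sequences in fixed
#' precedence order (`mRNA`, then `otherRNA`, then `repeat`); the first
#' matching class wins.
#'
#' @param tag tag sequence.
#' @param contaminant_refs named list of character vectors of reference
#'   sequences per class.
#' @return class name, or `NA_character_` when no class matches.
#' @export
contaminant_screen <- function(tag, contaminant_refs) {
  tag <- .as_dna(tag)
  for (cls in intersect(c("mRNA", "otherRNA", "repeat"),
                        names(contaminant_refs))) {
    refs <- .as_dna(contaminant_refs[[cls]])
    if (any(grepl(tag, refs, fixed = TRUE))) return(cls)
  }
  NA_character_
}

#' Assign the gp1a-gp4b group label from collected evidence
#'
#' The decision tree combines three evidence channels: database-hit status
#' against mature reference sets, genome mappability (of the hit's
#' reference mature, the "gene placement", and of the tag itself), and the
#' hairpin verdict of the tag's flank windows.
#'
#' * database hit whose reference placement coincides with a known locus
#'   -> `gp1a`; with a novel genomic placement -> `gp1b` (either may carry
#'   the secondary `gp1c` flag when extra loci exist beyond the
#'   known/primary one);
#' * database hit without reference ("gene") placement but with a direct
#'   tag placement -> `gp2a` when a flank window qualifies as hairpin,
#'   `gp2b` otherwise;
#' * database hit with no genome placement at all -> `gp3a` when the tag
#'   matches a previously described trout mature, else `gp3b`;
#' * no database hit -> `gp4a`/`gp4b` by hairpin verdict when the tag maps,
#'   `nohit` when it does not.
#'
#' @param evidence list with elements `db_hits` (data.frame from
#'   [match_mirbase()]), `gene_maps` (logical), `tag_loci` (data.frame from
#'   [map_genome()]), `at_known` (logical), `hairpin_pass` (logical),
#'   `known_trout_hit` (logical).
#' @return list with `label` and logical `gp1c`.
#' @export
classify <- function(evidence) {
  has_hit <- nrow(evidence$db_hits) > 0L
  if (has_hit && any(is.na(evidence$db_hits$ref_id) |
                     !nzchar(evidence$db_hits$ref_id)))
    stop("contradictory evidence: database hit with no reference id")
  n_loci <- nrow(evidence$tag_loci)
  gp1c <- FALSE
  if (!has_hit) {
    label <- if (n_loci > 0L) {
      if (isTRUE(evidence$hairpin_pass)) "gp4a" else "gp4b"
    } else "nohit"
  } else if (isTRUE(evidence$gene_maps)) {
    label <- if (isTRUE(evidence$at_known)) "gp1a" else "gp1b"
    gp1c <- n_loci > 1L
  } else if (n_loci > 0L) {
    label <- if (isTRUE(evidence$hairpin_pass)) "gp2a" else "gp2b"
  } else {
    label <- if (isTRUE(evidence$known_trout_hit)) "gp3a" else "gp3b"
  }
  list(label = label, gp1c = gp1c)
}

.overlaps_known <- function(loci, known) {
  if (nrow(loci) == 0L || nrow(known) == 0L) return(FALSE)
  for (a in seq_len(nrow(loci))) {
    hit <- known$contig == loci$contig[a] &
      known$strand == loci$strand[a] &
      known$start < loci$end[a] & known$end > loci$start[a]
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Annotate a unique-tag table
#'
#' Runs the full annotation stage on a collapsed tag table: contaminant
#' screening first (a tag matching both an rRNA fragment and a mature
#' miRNA is counted as contaminant, following the screening-first order of
#' the pipeline), then database matching, genome placement, hairpin
#' evaluation where the tree requires it, and group labelling.
#'
#' @param tags data.frame with a `sequence` column (e.g. from
#'   [collapse_tags()]).
#' @param bundle a reference bundle (see [generate_references()]), or any
#'   list with `genome`, `known_locus_table`, `specific_species_matures`,
#'   `selected_species_matures`, `contaminant_refs`.
#' @param flank flank width for hairpin windows (default 80).
#' @param external_folds optional data.frame from [read_rnafold()]; windows
#'   whose sequence matches a record use the external structure instead of
#'   the internal folding.
#' @param max_loci_fold maximum number of loci folded per tag (default 4).
#' @return data.frame (one row per tag): `sequence`, `label`, `gp1c`,
#'   `n_db_hits`, `db_class`, `ref_id`, `n_loci`, `hairpin_pass`, `dG`.
#' @export
annotate_tags <- function(tags, bundle, flank = 80L, external_folds = NULL,
                          max_loci_fold = 4L) {
  db <- list(specific = bundle$specific_species_matures,
             selected = bundle$selected_species_matures)
  known <- bundle$known_locus_table
  trout_matures <- setNames(known$mature, known$id)
  trout_matures <- trout_matures[!is.na(trout_matures) & nzchar(trout_matures)]
  n <- nrow(tags)
  label <- character(n); gp1c <- logical(n)
  n_db <- integer(n); db_class <- character(n); ref_id <- character(n)
  n_loci <- integer(n); hp_pass <- logical(n); dG <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    seq <- tags$sequence[t]
    contam <- contaminant_screen(seq, bundle$contaminant_refs)
    if (!is.na(contam)) {
      label[t] <- contam
      db_class[t] <- ""; ref_id[t] <- ""
      next
    }
    hits <- match_mirbase(seq, db)
    loci <- map_genome(seq, bundle$genome)
    gene_maps <- FALSE
    if (nrow(hits) > 0L) {
      ref_seqs <- unique(unlist(lapply(seq_len(nrow(hits)), function(k)
        db[[hits$class[k]]][[hits$ref_id[k]]])))
      gene_maps <- any(vapply(ref_seqs, function(rs)
        nrow(map_genome(rs, bundle$genome)) > 0L, logical(1)))
    }
    needs_fold <- nrow(loci) > 0L &&
      ((nrow(hits) > 0L && !gene_maps) || nrow(hits) == 0L)
    pass <- FALSE; best_dG <- NA_real_
    if (needs_fold) {
      for (a in seq_len(min(nrow(loci), max_loci_fold))) {
        fw <- flanks(loci[a, ], bundle$genome, flank)
        ext <- NULL
        if (!is.null(external_folds)) {
          m <- match(.as_dna(fw$window), .as_dna(external_folds$sequence))
          if (!is.na(m)) ext <- external_folds[m, ]
        }
        ev <- evaluate_hairpin(fw$window, fw$mature_start, fw$mature_end,
                               external = ext)
        if (is.na(best_dG) || ev$dG < best_dG) best_dG <- ev$dG
        if (ev$pass) { pass <- TRUE; break }
      }
    }
    known_trout_hit <- length(trout_matures) > 0L &&
      nrow(match_mirbase(seq, list(trout = trout_matures))) > 0L
    cl <- classify(list(
      db_hits = hits, gene_maps = gene_maps, tag_loci = loci,
      at_known = .overlaps_known(loci, known),
      hairpin_pass = pass, known_trout_hit = known_trout_hit))
    label[t] <- cl$label; gp1c[t] <- cl$gp1c
    n_db[t] <- nrow(hits)
    db_class[t] <- if (nrow(hits)) paste(sort(unique(hits$class)),
                                         collapse = ",") else ""
    ref_id[t] <- if (nrow(hits)) hits$ref_id[1] else ""
    n_loci[t] <- nrow(loci); hp_pass[t] <- pass; dG[t] <- best_dG
  }
  data.frame(sequence = tags$sequence, label = label, gp1c = gp1c,
             n_db_hits = n_db, db_class = db_class, ref_id = ref_id,
             n_loci = n_loci, hairpin_pass = hp_pass, dG = dG,
             stringsAsFactors = FALSE)
}

#' Group-count report in the published two-table layout
#'
#' Aggregates annotation records into (A) a read-level table (one row per
#' group label with read counts and percent of mappable reads) and (B) a
#' unique-miRNA table (unique tag counts per miRNA group). Every mappable
#' tag carries exactly one label, so the read counts partition the
#' mappable total.
#'
#' @param records data.frame from [annotate_tags()].
#' @param tag_counts data.frame from [collapse_tags()] (sequence + one
#'   count column per sample); row order need not match `records`.
#' @return list with `reads` and `unique_mirnas` data.frames.
#' @export
group_report <- function(records, tag_counts) {
  count_cols <- setdiff(names(tag_counts), "sequence")
  totals <- rowSums(tag_counts[, count_cols, drop = FALSE])
  totals <- totals[match(records$sequence, tag_counts$sequence)]
  mappable <- sum(totals)
  levels_all <- c("gp1a", "gp1b", "gp2a", "gp2b", "gp3a", "gp3b",
                  "gp4a", "gp4b", "mRNA", "otherRNA", "repeat", "nohit")
  by_label <- tapply(totals, factor(records$label, levels = levels_all),
                     sum, default = 0)
  reads <- accounting(setNames(as.numeric(by_label), levels_all),
                      denominator = mappable)
  stopifnot(sum(reads$count) == mappable)
  mir_levels <- levels_all[1:8]
  uniq <- table(factor(records$label, levels = mir_levels))
  unique_mirnas <- data.frame(group = mir_levels,
                              unique_mirs = as.integer(uniq),
                              stringsAsFactors = FALSE)
  list(mappable = mappable, reads = reads, unique_mirnas = unique_mirnas)
}
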