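#' Fold a hairpin window into a single stem-loop
#'
#' Predicts the minimum-energy single stem-loop structure of a candidate
#' precursor window by dynamic programming over non-crossing pairs. The
#' energy model is the shipped nearest-neighbor stack table
#' ([stack_energy_table()]) for consecutive pairs, plus constant/linear
#' penalties for the terminal loop and for bulges or interior loops
#' ([fold_params()]). Multibranch structures are outside the model by
#' construction: the 11-criterion precursor filter presupposes one stem and
#' one loop.
#'
#' Sequences are accepted in DNA or RNA alphabet; folding is performed on
#' the RNA alphabet internally.
#'
#' @param window character scalar, the candidate window (mature plus
#'   flanks), length >= 40 recommended.
#' @param params folding parameters, see [fold_params()].
#' @return list with `dotbracket` (character), `dG` (kcal/mol, <= 0; 0 for
#'   an open structure), and `pairs` (two-column integer matrix of 1-based
#'   paired positions, outermost first).
#' @export
fold_hairpin <- function(window, params = fold_params()) {
  stopifnot(is.character(window), length(window) == 1L)
  seq <- .as_rna(window)
  res <- fold_hairpin_cpp(seq, stack_energy_table(),
                          params$hairpin, params$intr_open,
                          params$intr_per_nt, as.integer(params$max_intr),
                          as.integer(params$min_loop))
  pairs <- cbind(i = res$pair_i, j = res$pair_j)
  if (res$dG >= 0) {
    list(dotbracket = strrep(".", nchar(seq)), dG = 0,
         pairs = pairs[0, , drop = FALSE])
  } else {
    list(dotbracket = res$dotbracket, dG = res$dG, pairs = pairs)
  }
}

#' Parse an RNAfold-dialect structure file
#'
#' Reads externally produced structures in the classic RNAfold output
#' dialect: for each record, a (possibly FASTA-headed) sequence line
#' followed by a dot-bracket line ending in the free energy in parentheses,
#' e.g. `"((((...)))) ( -7.20)"`. Records parsed this way bypass the
#' internal folding when passed to [annotate_tags()].
#'
#' @param path file path.
#' @return data.frame with columns `name`, `sequence`, `dotbracket`, `dG`.
#' @export
read_rnafold <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    name <- NA_character_
    if (startsWith(lines[i], ">")) {
      name <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
    }
    seq <- trimws(lines[i])
    struct_line <- trimws(lines[i + 1L])
    m <- regmatches(struct_line,
                    regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)$",
                            struct_line))[[1]]
    if (length(m) != 3L)
      stop("malformed structure line: ", struct_line)
    k <- k + 1L
    out[[k]] <- data.frame(name = if (is.na(name)) paste0("record", k) else name,
                           sequence = .as_dna(seq), dotbracket = m[2],
                           dG = as.numeric(m[3]), stringsAsFactors = FALSE)
    i <- i + 2L
  }
  do.call(rbind, out)
}

# Internal: recover the nested pair list from a dot-bracket string,
# rejecting multibranch structures (more than one helix run).
.pairs_from_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (p in seq_along(chars)) {
    if (chars[p] == "(") stack <- c(stack, p)
    else if (chars[p] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      pairs <- rbind(pairs, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  if (nrow(pairs) == 0L) return(cbind(i = integer(0), j = integer(0)))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  # single stem-loop <=> i ascending implies j descending
  if (is.unsorted(rev(pairs[, 2])))
    stop("structure is not a single stem-loop")
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Evaluate the 11 hairpin precursor criteria
#'
#' Applies the structural filter that decides whether a genomic window can
#' plausibly act as a miRNA precursor. The criteria, evaluated on a single
#' stem-loop structure and the position of the candidate mature within the
#' window, are:
#'
#' 1. largest bulge in the stem <= 12 nt;
#' 2. >= 16 base pairs in the stem;
#' 3. folding free energy <= -15 kcal/mol;
#' 4. hairpin length (both stems plus loop) >= 50 nt;
#' 5. terminal loop <= 200 nt;
#' 6. largest bulge in the mature region <= 4 nt;
#' 7. <= 2 errors in any one bulge in the mature region;
#' 8. <= 2 biased bulges in the mature region;
#' 9. <= 4 errors in the mature region;
#' 10. >= 12 base pairs in the mature region;
#' 11. > 80% of mature positions located inside the stem.
#'
#' An "error" is an unpaired mature position; a "biased bulge" is an
#' interruption with unpaired nucleotides on only one strand; a bulge's
#' size is the larger of its two unpaired runs. These two terms are not
#' fixed by convention and are isolated here so they can be swapped.
#'
#' @param pairs two-column matrix of paired positions (1-based, outermost
#'   first), e.g. from [fold_hairpin()] or [.pairs_from_dotbracket].
#' @param dG folding free energy (kcal/mol).
#' @param mature_start,mature_end 1-based inclusive mature coordinates
#'   within the window.
#' @param window_length window length in nt.
#' @return list with logical `c1`..`c11`, `pass` (all true), and the
#'   measured quantities (`stem_bp`, `loop_len`, `hairpin_len`,
#'   `max_stem_bulge`, `mature_errors`, `mature_bp`, `mature_in_stem_frac`).
#' @export
hairpin_criteria <- function(pairs, dG, mature_start, mature_end,
                             window_length) {
  if (mature_start < 1 || mature_end > window_length ||
      mature_start > mature_end)
    stop("mature region outside window")
  mature <- seq.int(mature_start, mature_end)
  npair <- nrow(pairs)

  if (npair == 0L) {
    out <- list(c1 = TRUE, c2 = FALSE, c3 = dG <= -15, c4 = FALSE,
                c5 = TRUE, c6 = TRUE, c7 = TRUE, c8 = TRUE,
                c9 = FALSE, c10 = FALSE, c11 = FALSE,
                stem_bp = 0L, loop_len = NA_integer_,
                hairpin_len = 0L, max_stem_bulge = 0L,
                mature_errors = length(mature), mature_bp = 0L,
                mature_in_stem_frac = 0)
    out$pass <- FALSE
    return(out)
  }

  i_out <- pairs[1, 1]; j_out <- pairs[1, 2]
  i_in <- pairs[npair, 1]; j_in <- pairs[npair, 2]
  loop_len <- j_in - i_in - 1L
  hairpin_len <- j_out - i_out + 1L

  # Interruptions between consecutive pairs of the nested run.
  bulge_sizes <- integer(0)     # max unpaired run per interruption
  bulge_mature_err <- integer(0)  # unpaired mature nt per interruption
  bulge_biased <- logical(0)
  bulge_touches_mature <- logical(0)
  if (npair > 1L) {
    for (t in seq_len(npair - 1L)) {
      gl <- pairs[t + 1L, 1] - pairs[t, 1] - 1L
      gr <- pairs[t, 2] - pairs[t + 1L, 2] - 1L
      if (gl + gr == 0L) next
      left_pos <- if (gl > 0) seq.int(pairs[t, 1] + 1L, pairs[t + 1L, 1] - 1L)
                  else integer(0)
      right_pos <- if (gr > 0) seq.int(pairs[t + 1L, 2] + 1L, pairs[t, 2] - 1L)
                   else integer(0)
      bulge_sizes <- c(bulge_sizes, max(gl, gr))
      in_mat <- sum(left_pos %in% mature) + sum(right_pos %in% mature)
      bulge_mature_err <- c(bulge_mature_err, in_mat)
      bulge_biased <- c(bulge_biased, xor(gl == 0L, gr == 0L))
      bulge_touches_mature <- c(bulge_touches_mature, in_mat > 0L)
    }
  }

  paired_pos <- c(pairs[, 1], pairs[, 2])
  stem_pos <- c(seq.int(i_out, i_in), seq.int(j_in, j_out))
  mature_errors <- sum(!(mature %in% paired_pos))
  mature_bp <- sum(pairs[, 1] %in% mature | pairs[, 2] %in% mature)
  mature_in_stem <- sum(mature %in% stem_pos) / length(mature)
  max_stem_bulge <- if (length(bulge_sizes)) max(bulge_sizes) else 0L
  max_mature_bulge <- if (any(bulge_touches_mature))
    max(bulge_sizes[bulge_touches_mature]) else 0L

  out <- list(
    c1 = max_stem_bulge <= 12L,
    c2 = npair >= 16L,
    c3 = dG <= -15,
    c4 = hairpin_len >= 50L,
    c5 = loop_len <= 200L,
    c6 = max_mature_bulge <= 4L,
    c7 = (if (length(bulge_mature_err)) max(bulge_mature_err) else 0L) <= 2L,
    c8 = sum(bulge_biased & bulge_touches_mature) <= 2L,
    c9 = mature_errors <= 4L,
    c10 = mature_bp >= 12L,
    c11 = mature_in_stem > 0.8,
    stem_bp = npair, loop_len = loop_len, hairpin_len = hairpin_len,
    max_stem_bulge = max_stem_bulge, mature_errors = mature_errors,
    mature_bp = mature_bp, mature_in_stem_frac = mature_in_stem)
  out$pass <- all(unlist(out[paste0("c", 1:11)]))
  out
}

#' Fold and evaluate a candidate precursor window
#'
#' Convenience wrapper: fold the window (or use a supplied external
#' structure) and apply [hairpin_criteria()].
#'
#' @inheritParams hairpin_criteria
#' @param window candidate window sequence.
#' @param external optional list/row with `dotbracket` and `dG` from
#'   [read_rnafold()]; bypasses internal folding.
#' @return list combining the folding result and the criteria verdicts.
#' @export
evaluate_hairpin <- function(window, mature_start, mature_end,
                             external = NULL) {
  if (is.null(external)) {
    f <- fold_hairpin(window)
    pairs <- f$pairs
    dG <- f$dG
    db <- f$dotbracket
  } else {
    db <- external$dotbracket
    dG <- external$dG
    pairs <- .pairs_from_dotbracket(db)
  }
  crit <- hairpin_criteria(pairs, dG, mature_start, mature_end,
                           nchar(window))
  c(list(window = window, dotbracket = db, dG = dG, pairs = pairs), crit)
}
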