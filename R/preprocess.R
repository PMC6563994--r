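#' Trim the 3' adapter from a read
#'
#' Finds the best-scoring 3' semi-global adapter match: every start
#' position in the read is tried, the adapter prefix is compared to the
#' read suffix, and candidates need at least `min_overlap` aligned bases
#' with a mismatch rate no larger than `max_mismatch_rate`. The score of a
#' candidate is matches minus mismatches; ties are broken toward the
#' rightmost adapter start, i.e. the longest insert, so a chance internal
#' match cannot truncate genuine miRNA sequence.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (>= 10 nt recommended).
#' @param min_overlap minimum aligned adapter bases (>= 6).
#' @param max_mismatch_rate maximum fraction of mismatching aligned bases.
#' @return character vector of inserts, `NA` where no adapter was found
#'   (including empty reads).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L,
                         max_mismatch_rate = 0.1) {
  stopifnot(nzchar(adapter), min_overlap >= 6L)
  adapter <- .as_dna(adapter)
  a_int <- utf8ToInt(adapter)
  alen <- length(a_int)
  uniq <- unique(reads)
  trim_one <- function(read) {
    n <- nchar(read)
    if (n == 0L) return(NA_character_)
    r_int <- utf8ToInt(.as_dna(read))
    best_score <- -Inf
    best_p <- NA_integer_
    for (p in seq_len(n)) {                # adapter start position
      ov <- min(alen, n - p + 1L)
      if (ov < min_overlap) break
      mism <- sum(r_int[p:(p + ov - 1L)] != a_int[seq_len(ov)])
      if (mism / ov > max_mismatch_rate) next
      score <- (ov - mism) - mism
      if (score >= best_score) {           # >=: rightmost start wins ties
        best_score <- score
        best_p <- p
      }
    }
    if (is.na(best_p)) return(NA_character_)
    substr(read, 1L, best_p - 1L)
  }
  res <- vapply(uniq, trim_one, character(1), USE.NAMES = FALSE)
  res[match(reads, uniq)]
}

#' Length filter for trimmed inserts
#'
#' Keeps inserts whose length lies in the inclusive range
#' `[min_len, max_len]` (default 15-32 nt, the targeted small-RNA size
#' range).
#'
#' @param inserts character vector.
#' @param min_len,max_len inclusive bounds.
#' @return logical vector, `TRUE` = keep.
#' @export
filter_length <- function(inserts, min_len = 15L, max_len = 32L) {
  n <- nchar(inserts)
  !is.na(inserts) & n >= min_len & n <= max_len
}

#' Collapse kept inserts into unique tags
#'
#' One tag per distinct sequence, with one count column per sample.
#'
#' @param inserts_by_sample named list (sample id -> character vector of
#'   kept inserts).
#' @return data.frame with a `sequence` column followed by one integer
#'   count column per sample, ordered by decreasing total count then
#'   sequence.
#' @export
collapse_tags <- function(inserts_by_sample) {
  stopifnot(is.list(inserts_by_sample), !is.null(names(inserts_by_sample)))
  all_seq <- sort(unique(unlist(inserts_by_sample, use.names = FALSE)))
  counts <- vapply(inserts_by_sample, function(x) {
    tab <- table(factor(x, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (length(all_seq) == 1L) counts <- matrix(counts, nrow = 1L,
                                              dimnames = list(NULL, names(inserts_by_sample)))
  df <- data.frame(sequence = all_seq, counts, stringsAsFactors = FALSE,
                   check.names = FALSE)
  total <- rowSums(df[, -1, drop = FALSE])
  df <- df[order(-total, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Percentage layer of the read-accounting report
#'
#' Converts a named vector of bin counts into percentages of a stated
#' denominator, rounded half-up to one decimal (display convention of the
#' published accounting tables).
#'
#' @param counts named numeric vector of bin counts.
#' @param denominator the total the percentages refer to.
#' @return data.frame with `bin`, `count`, `percent` columns.
#' @export
accounting <- function(counts, denominator) {
  if (denominator == 0) {
    warning("zero denominator; percentages reported as 0.0")
    pct <- rep(0, length(counts))
  } else {
    pct <- .round_half_up(100 * counts / denominator, 1L)
  }
  data.frame(bin = names(counts), count = as.numeric(counts), percent = pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

.round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ path.
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  n <- length(lines) / 4L
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  idx <- seq_len(n)
  data.frame(id = sub("^@", "", lines[4L * idx - 3L]),
             sequence = lines[4L * idx - 2L],
             quality = lines[4L * idx],
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Sanger Phred+33)
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

.mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Preprocess per-sample FASTQ files into a unique-tag table
#'
#' Runs the full preprocessing stage: adapter trimming, mean-quality
#' filtering, length filtering and tag collapsing, with the conservation
#' law `raw = removed_no_adapter + removed_length + mappable` asserted on
#' every run. Reads failing the mean-Phred threshold are counted inside
#' `removed_length` as a distinct `low_quality` sub-bin (the size/quality
#' screen of the accounting layout).
#'
#' @param fastq_paths named character vector (sample id -> FASTQ path).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len inclusive insert length bounds.
#' @param min_phred minimum mean base quality (default 30).
#' @param min_overlap,max_mismatch_rate adapter-match stringency, see
#'   [trim_adapter()].
#' @return list with `tags` (see [collapse_tags()]), `report` (counts:
#'   `raw`, `removed_no_adapter`, `removed_length`, `removed_low_quality`,
#'   `mappable`; `length_histogram`; `percent` data.frame from
#'   [accounting()] over raw reads), and `per_sample` raw/mappable counts.
#' @export
preprocess_fastq <- function(fastq_paths, adapter, min_len = 15L,
                             max_len = 32L, min_phred = 30,
                             min_overlap = 6L, max_mismatch_rate = 0.1) {
  stopifnot(!is.null(names(fastq_paths)))
  raw <- 0L; no_adapter <- 0L; bad_len <- 0L; low_q <- 0L
  hist_acc <- integer(0)
  inserts <- list()
  per_sample <- list()
  for (s in names(fastq_paths)) {
    reads <- read_fastq(fastq_paths[[s]])
    raw_s <- nrow(reads)
    raw <- raw + raw_s
    ins <- trim_adapter(reads$sequence, adapter, min_overlap,
                        max_mismatch_rate)
    has_adapter <- !is.na(ins)
    no_adapter <- no_adapter + sum(!has_adapter)
    ok_q <- .mean_phred(reads$quality) >= min_phred
    lowq_s <- has_adapter & !ok_q
    low_q <- low_q + sum(lowq_s)
    candidate <- has_adapter & ok_q
    keep <- candidate & filter_length(ins, min_len, max_len)
    bad_len <- bad_len + sum(candidate & !keep)
    kept <- ins[keep]
    inserts[[s]] <- kept
    per_sample[[s]] <- c(raw = raw_s, mappable = length(kept))
    if (length(kept)) {
      h <- table(nchar(kept))
      hist_acc <- .merge_hist(hist_acc, h)
    }
  }
  tags <- if (any(lengths(inserts) > 0)) collapse_tags(inserts) else
    data.frame(sequence = character(0), stringsAsFactors = FALSE)
  mappable <- sum(lengths(inserts))
  removed_length <- bad_len + low_q
  stopifnot(raw == no_adapter + removed_length + mappable)
  counts <- c(raw = raw, removed_no_adapter = no_adapter,
              removed_length = removed_length, mappable = mappable)
  report <- list(raw = raw, removed_no_adapter = no_adapter,
                 removed_length = removed_length,
                 removed_low_quality = low_q, mappable = mappable,
                 length_histogram = hist_acc,
                 percent = accounting(counts[-1], denominator = raw))
  list(tags = tags, report = report,
       per_sample = do.call(rbind, per_sample))
}

.merge_hist <- function(acc, h) {
  for (nm in names(h)) {
    if (is.null(acc[nm]) || is.na(acc[nm])) acc[nm] <- 0L
    acc[nm] <- acc[nm] + as.integer(h[[nm]])
  }
  acc[order(as.integer(names(acc)))]
}
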