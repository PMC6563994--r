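#' Configuration for the synthetic small-RNA study
#'
#' Builds and validates the configuration of the synthetic-data module.
#' Defaults emulate the study conditions the pipeline assumes: n = 3
#' samples per social-status group, an overdispersed negative-binomial
#' count model, 3'-adapter-ligated reads with high base quality, a small
#' fraction of adapterless reads and contaminant RNA fragments, and 3'
#' isomiR length jitter concentrated on the 19-23 nt mode.
#'
#' @param n_samples_per_group samples per group (>= 2; default 3).
#' @param n_mirna_per_group_label named integer vector, miRNAs to plant per
#'   annotation group label.
#' @param de_fraction fraction of miRNAs that are differentially expressed.
#' @param de_log2fc true absolute log2 fold change of DE miRNAs.
#' @param nb_mean expected reads per miRNA per sample.
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param adapter 3' adapter sequence (>= 10 nt).
#' @param frac_no_adapter fraction of extra reads emitted without adapter.
#' @param frac_contaminant fraction of extra contaminant-derived reads.
#' @param length_jitter named probability vector over 3' offsets -2..2.
#' @param seed integer seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_samples_per_group = 3L,
    n_mirna_per_group_label = c(gp1a = 6L, gp1b = 6L, gp2a = 4L, gp2b = 4L,
                                gp3a = 3L, gp3b = 3L, gp4a = 4L, gp4b = 4L),
    de_fraction = 0.25,
    de_log2fc = 1,
    nb_mean = 200,
    nb_dispersion = 0.1,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    frac_no_adapter = 0.05,
    frac_contaminant = 0.10,
    length_jitter = c("-2" = 0.05, "-1" = 0.15, "0" = 0.60,
                      "1" = 0.15, "2" = 0.05),
    seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_mirna_per_group_label = n_mirna_per_group_label,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              adapter = .as_dna(adapter),
              frac_no_adapter = frac_no_adapter,
              frac_contaminant = frac_contaminant,
              length_jitter = length_jitter, seed = as.integer(seed))
  probs <- c(cfg$de_fraction, cfg$frac_no_adapter, cfg$frac_contaminant)
  if (any(probs < 0 | probs > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$n_samples_per_group < 2L) stop("need >= 2 samples per group")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (nchar(cfg$adapter) < 10L) stop("adapter must be >= 10 nt")
  if (abs(sum(cfg$length_jitter) - 1) > 1e-8 || any(cfg$length_jitter < 0))
    stop("length_jitter must be a probability vector")
  bad <- setdiff(names(cfg$n_mirna_per_group_label),
                 c("gp1a", "gp1b", "gp2a", "gp2b", "gp3a", "gp3b",
                   "gp4a", "gp4b"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  class(cfg) <- "synthetic_config"
  cfg
}

.rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Draw a mature sequence that is not within the matching tolerance of any
# sequence already drawn.
.draw_mature <- function(existing, lens = 20:23) {
  repeat {
    s <- .rand_seq(sample(lens, 1L))
    clash <- any(vapply(existing, function(e) {
      if (abs(nchar(e) - nchar(s)) > 2L) return(FALSE)
      L <- min(nchar(e), nchar(s))
      mism <- which(utf8ToInt(substr(e, 1, L)) != utf8ToInt(substr(s, 1, L)))
      sum(mism <= 16L) <= 1L && sum(mism > 16L) == 0L
    }, logical(1)))
    if (!clash) return(s)
  }
}

# Engineer an 80 nt + mature + 80 nt cassette whose window folds into a
# qualifying hairpin: the (mature + 8 nt) arm stacked against a star arm
# around an 8 nt loop. Two G:U wobbles are planted opposite the mature so
# the star is not an exact reverse complement of the mature (as in real
# precursors, and so the mature has a single exact genomic placement);
# wobbles keep the stem fully paired. Verified by folding before
# acceptance.
.hairpin_cassette <- function(mature) {
  for (try in 1:25) {
    left <- .rand_seq(80L)
    ext <- .rand_seq(8L)
    loop <- .rand_seq(8L)
    arm <- paste0(mature, ext)
    star <- .revcomp(arm)
    # wobble positions: mature G or T bases, one per half where possible
    mlen <- nchar(mature)
    bases <- strsplit(mature, "")[[1]]
    cand <- which(bases %in% c("G", "T"))
    pick <- c(cand[cand <= mlen %/% 2][1], rev(cand[cand > mlen %/% 2])[1])
    pick <- pick[!is.na(pick)]
    if (length(pick) < 1L) next
    for (p in pick) {
      si <- nchar(arm) - p + 1L          # star index opposite arm pos p
      repl <- if (bases[p] == "G") "T" else "G"   # G:U / U:G wobble
      substr(star, si, si) <- repl
    }
    right <- paste0(ext, loop, star, .rand_seq(44L))
    stopifnot(nchar(right) >= 80L)
    right <- substr(right, 1L, 80L)
    window <- paste0(left, mature, right)
    ev <- evaluate_hairpin(window, 81L, 80L + nchar(mature))
    if (ev$pass) return(paste0(left, mature, right))
  }
  stop("failed to engineer a qualifying hairpin cassette")
}

# Cassette whose window cannot qualify: flanks restricted to {A, C} admit
# no flank-flank base pair, capping the achievable stem far below the
# 16 bp criterion.
.nonhairpin_cassette <- function(mature) {
  for (try in 1:25) {
    left <- .rand_seq(80L, c("A", "C"))
    right <- .rand_seq(80L, c("A", "C"))
    window <- paste0(left, mature, right)
    ev <- evaluate_hairpin(window, 81L, 80L + nchar(mature))
    if (!ev$pass) return(paste0(left, mature, right))
  }
  stop("failed to engineer a failing cassette")
}

#' Generate synthetic references and ground truth
#'
#' Builds a reference bundle (genome, known-locus table, specific- and
#' selected-species mature sets, 3'UTRs, GO map, contaminant references)
#' in which every requested miRNA carries planted evidence guaranteeing
#' its group label under the annotation decision tree:
#'
#' * `gp1a`: mature in the specific-species set, planted at a locus listed
#'   in the known-locus table (alternating strand);
#' * `gp1b`: mature in the selected-species set, planted at a novel locus;
#' * `gp2a`/`gp2b`: a selected-species reference differing from the planted
#'   mature by one substitution within the first 16 nt (so the reference
#'   itself does not map), with the mature embedded in a cassette
#'   engineered to pass all 11 hairpin criteria (`gp2a`) or fail at least
#'   one (`gp2b`);
#' * `gp3a`/`gp3b`: selected-species reference, mature absent from the
#'   genome; `gp3a` additionally listed (with its previously reported
#'   mature) in the known-locus table;
#' * `gp4a`/`gp4b`: no database entry, genomic cassette with/without a
#'   qualifying hairpin.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param n_genes number of 3'UTR genes to simulate.
#' @return list with `bundle` (ReferenceBundle) and `truth` (GroundTruth:
#'   `mirnas` data.frame and `targets` data.frame).
#' @export
generate_references <- function(cfg, seed = cfg$seed, n_genes = 20L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  spec <- cfg$n_mirna_per_group_label
  ids_all <- character(0)

  mirnas <- list()
  existing <- character(0)
  for (g in names(spec)) {
    ng <- spec[[g]]
    if (ng == 0L) next
    for (k in seq_len(ng)) {
      m <- .draw_mature(existing)
      existing <- c(existing, m)
      id <- sprintf("%s-mir-%s-%02d",
                    if (g == "gp1a") "dre" else if (g %in% c("gp3a")) "omy"
                    else "fru", sub("gp", "", g), k)
      if (id %in% ids_all) stop("duplicate miRNA ids")
      ids_all <- c(ids_all, id)
      mirnas[[length(mirnas) + 1L]] <- list(id = id, group = g, sequence = m)
    }
  }
  mir <- data.frame(id = vapply(mirnas, `[[`, "", "id"),
                    group = vapply(mirnas, `[[`, "", "group"),
                    sequence = vapply(mirnas, `[[`, "", "sequence"),
                    stringsAsFactors = FALSE)

  # Database variants for gp2: one substitution at position 12.
  variant_of <- function(m) {
    pos <- 12L
    base <- substr(m, pos, pos)
    repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    v <- m
    substr(v, pos, pos) <- repl
    v
  }
  mir$db_seq <- mir$sequence
  is_gp2 <- mir$group %in% c("gp2a", "gp2b")
  mir$db_seq[is_gp2] <- vapply(mir$sequence[is_gp2], variant_of, "")

  # Genome assembly: spacer + per-miRNA cassette (where the group calls
  # for genome presence) + spacer, single contig.
  pieces <- character(0)
  offset <- 0L
  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    start <- offset
    offset <<- offset + nchar(s)
    start
  }
  add_piece(.rand_seq(60L))
  mir$contig <- NA_character_; mir$start <- NA_integer_
  mir$end <- NA_integer_; mir$strand <- NA_character_
  for (r in seq_len(nrow(mir))) {
    g <- mir$group[r]
    m <- mir$sequence[r]
    if (g %in% c("gp1a", "gp1b")) {
      minus <- g == "gp1a" && (r %% 2L == 0L)
      cassette <- if (minus) .revcomp(m) else m
      at <- add_piece(cassette)
      mir$contig[r] <- "chr1"
      mir$start[r] <- at; mir$end[r] <- at + nchar(m)
      mir$strand[r] <- if (minus) "-" else "+"
    } else if (g %in% c("gp2a", "gp4a")) {
      cassette <- .hairpin_cassette(m)
      at <- add_piece(cassette)
      mir$contig[r] <- "chr1"
      mir$start[r] <- at + 80L; mir$end[r] <- at + 80L + nchar(m)
      mir$strand[r] <- "+"
    } else if (g %in% c("gp2b", "gp4b")) {
      cassette <- .nonhairpin_cassette(m)
      at <- add_piece(cassette)
      mir$contig[r] <- "chr1"
      mir$start[r] <- at + 80L; mir$end[r] <- at + 80L + nchar(m)
      mir$strand[r] <- "+"
    }
    add_piece(.rand_seq(60L))
  }
  genome <- c(chr1 = paste(pieces, collapse = ""))

  # Known-locus table: genuine gp1a loci plus previously reported trout
  # matures (gp3a) whose historical coordinates no longer match the
  # assembly (placeholder interval in a spacer region).
  known <- mir[mir$group == "gp1a",
               c("id", "contig", "start", "end", "strand", "sequence")]
  names(known)[6] <- "mature"
  gp3a <- mir[mir$group == "gp3a", , drop = FALSE]
  if (nrow(gp3a)) {
    ph <- data.frame(id = gp3a$id, contig = "chr1",
                     start = seq(0L, by = 25L, length.out = nrow(gp3a)),
                     end = seq(0L, by = 25L, length.out = nrow(gp3a)) + 22L,
                     strand = "+", mature = gp3a$sequence,
                     stringsAsFactors = FALSE)
    known <- rbind(known, ph)
  }
  rownames(known) <- NULL
  stopifnot(all(known$start >= 0), all(known$end <= nchar(genome[["chr1"]])))

  specific <- setNames(mir$db_seq[mir$group == "gp1a"],
                       mir$id[mir$group == "gp1a"])
  sel_groups <- c("gp1b", "gp2a", "gp2b", "gp3a", "gp3b")
  selected <- setNames(mir$db_seq[mir$group %in% sel_groups],
                       mir$id[mir$group %in% sel_groups])

  # Post-assembly evidence checks: planted placements are unique, database
  # variants and gp3 matures are absent from the genome.
  for (r in seq_len(nrow(mir))) {
    n_hits <- nrow(map_genome(mir$sequence[r], genome))
    g <- mir$group[r]
    expected <- if (g %in% c("gp3a", "gp3b")) 0L else 1L
    if (n_hits != expected)
      stop("evidence collision for ", mir$id[r], " (", n_hits, " loci)")
    if (g %in% c("gp2a", "gp2b") &&
        nrow(map_genome(mir$db_seq[r], genome)) != 0L)
      stop("gp2 database variant unexpectedly maps")
  }

  # Fixed 3' extension bases per miRNA: genomic continuation when a locus
  # exists, otherwise a fixed random dinucleotide (so isomiR tags are
  # reproducible).
  mir$ext3 <- vapply(seq_len(nrow(mir)), function(r) {
    if (is.na(mir$start[r])) return(.rand_seq(2L))
    contig <- genome[[mir$contig[r]]]
    if (mir$strand[r] == "+") {
      substr(contig, mir$end[r] + 1L, mir$end[r] + 2L)
    } else {
      .revcomp(substr(contig, mir$start[r] - 1L, mir$start[r]))
    }
  }, character(1))
  stopifnot(all(nchar(mir$ext3) == 2L))

  # DE assignment.
  n_de <- round(cfg$de_fraction * nrow(mir))
  mir$de_status <- "null"
  if (n_de > 0L) {
    de_idx <- sample(nrow(mir), n_de)
    mir$de_status[de_idx] <- rep(c("up_SS", "up_SD"), length.out = n_de)
  }
  mir$true_log2fc <- ifelse(mir$de_status == "up_SS", cfg$de_log2fc,
                            ifelse(mir$de_status == "up_SD",
                                   -cfg$de_log2fc, 0))

  # 3'UTRs with planted perfect-complement target sites.
  genes <- sprintf("gene%02d", seq_len(n_genes))
  utrs <- setNames(vapply(genes, function(g) .rand_seq(300L), ""), genes)
  targets <- data.frame(mirna = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
  host <- mir[mir$group %in% c("gp1a", "gp1b"), , drop = FALSE]
  host_mirs <- host$id[order(host$de_status == "null")]  # DE miRNAs first
  occupied <- setNames(vector("list", n_genes), genes)
  for (id in head(host_mirs, 8L)) {
    m <- mir$sequence[mir$id == id]
    for (g in sample(genes, 2L)) {
      site <- .revcomp(m)
      # keep planted sites disjoint within a gene
      repeat {
        pos <- sample(seq_len(300L - nchar(site) - 1L), 1L)
        iv <- c(pos, pos + nchar(site) - 1L)
        clash <- any(vapply(occupied[[g]], function(o)
          iv[1] <= o[2] && iv[2] >= o[1], logical(1)))
        if (!clash) break
      }
      occupied[[g]] <- c(occupied[[g]], list(iv))
      u <- utrs[[g]]
      substr(u, pos, pos + nchar(site) - 1L) <- site
      utrs[[g]] <- u
      targets <- rbind(targets, data.frame(mirna = id, gene = g,
                                           stringsAsFactors = FALSE))
    }
  }

  # GO map: one term concentrated on the targeted genes, the rest random.
  terms <- sprintf("GO:%07d", 1:15)
  target_genes <- unique(targets$gene)
  go <- lapply(genes, function(g) {
    t <- sample(terms[-1], sample(2:4, 1L))
    if (g %in% target_genes) t <- c(terms[1], t)
    unique(t)
  })
  go_map <- data.frame(
    gene = rep(genes, lengths(go)), term = unlist(go),
    stringsAsFactors = FALSE)

  contaminant_refs <- list(
    mRNA = vapply(1:3, function(i) .rand_seq(100L), ""),
    otherRNA = vapply(1:3, function(i) .rand_seq(100L), ""),
    "repeat" = vapply(1:3, function(i) .rand_seq(100L), ""))
  # contaminant references must not harbour any mature
  for (cls in names(contaminant_refs))
    for (m in mir$sequence)
      stopifnot(!any(grepl(m, contaminant_refs[[cls]], fixed = TRUE)))

  bundle <- list(genome = genome, known_locus_table = known,
                 specific_species_matures = specific,
                 selected_species_matures = selected,
                 utrs = utrs, go_map = go_map,
                 contaminant_refs = contaminant_refs)
  truth <- list(mirnas = mir, targets = targets)
  list(bundle = bundle, truth = truth)
}

#' Simulate per-sample small-RNA FASTQ libraries
#'
#' Draws per-miRNA, per-sample counts from a negative-binomial model (DE
#' miRNAs get their fold change split symmetrically across the two
#' groups), emits each read as the mature (with 3' isomiR jitter) plus the
#' 3' adapter at uniformly high base quality, and adds the configured
#' fractions of adapterless and contaminant reads. A manifest records the
#' true source of every read.
#'
#' @param ref result of [generate_references()] (`bundle` + `truth`).
#' @param cfg a [synthetic_config()].
#' @param outdir directory for the FASTQ files.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `fastq_paths` (named by sample), `manifest`
#'   (data.frame sample/read_id/source/class), `true_counts` (miRNA x
#'   sample matrix), `groups` (named sample -> group vector).
#' @export
simulate_library <- function(ref, cfg, outdir, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mir <- ref$truth$mirnas
  nS <- cfg$n_samples_per_group
  samples <- c(sprintf("SS_%d", seq_len(nS)), sprintf("SD_%d", seq_len(nS)))
  groups <- setNames(rep(c("SS", "SD"), each = nS), samples)
  offs <- as.integer(names(cfg$length_jitter))
  half <- cfg$de_log2fc / 2
  true_counts <- matrix(0L, nrow(mir), length(samples),
                        dimnames = list(mir$id, samples))
  manifest <- list()
  paths <- character(0)
  for (j in seq_along(samples)) {
    s <- samples[j]
    set.seed(seed + 1000L + j)   # fixed per-sample stream offsets
    grp <- groups[[s]]
    mult <- ifelse(mir$de_status == "null", 1,
                   ifelse((mir$de_status == "up_SS") == (grp == "SS"),
                          2^half, 2^-half))
    mu <- cfg$nb_mean * mult
    counts <- rnbinom(nrow(mir), mu = mu, size = 1 / cfg$nb_dispersion)
    true_counts[, j] <- counts
    seqs <- character(0); srcs <- character(0); clss <- character(0)
    for (r in seq_len(nrow(mir))) {
      if (counts[r] == 0L) next
      o <- sample(offs, counts[r], replace = TRUE,
                  prob = cfg$length_jitter)
      m <- mir$sequence[r]
      ins <- vapply(o, function(oo) {
        if (oo < 0L) substr(m, 1L, nchar(m) + oo)
        else if (oo == 0L) m
        else paste0(m, substr(mir$ext3[r], 1L, oo))
      }, character(1))
      seqs <- c(seqs, paste0(ins, cfg$adapter))
      srcs <- c(srcs, rep(mir$id[r], counts[r]))
      clss <- c(clss, rep("mirna", counts[r]))
    }
    n_mat <- length(seqs)
    n_noad <- round(cfg$frac_no_adapter * n_mat)
    if (n_noad > 0L) {
      pick <- sample(nrow(mir), n_noad, replace = TRUE)
      seqs <- c(seqs, mir$sequence[pick])
      srcs <- c(srcs, mir$id[pick])
      clss <- c(clss, rep("no_adapter", n_noad))
    }
    n_cont <- round(cfg$frac_contaminant * n_mat)
    if (n_cont > 0L) {
      classes <- sample(names(ref$bundle$contaminant_refs), n_cont,
                        replace = TRUE)
      frag <- vapply(classes, function(cl) {
        r0 <- sample(ref$bundle$contaminant_refs[[cl]], 1L)
        len <- sample(19:24, 1L)
        at <- sample(nchar(r0) - len + 1L, 1L)
        substr(r0, at, at + len - 1L)
      }, character(1))
      seqs <- c(seqs, paste0(frag, cfg$adapter))
      srcs <- c(srcs, classes)
      clss <- c(clss, rep("contaminant", n_cont))
    }
    ids <- sprintf("%s_read%06d", s, seq_along(seqs))
    reads <- data.frame(id = ids, sequence = seqs,
                        quality = if (length(seqs))
                          strrep("I", nchar(seqs)) else character(0),
                        stringsAsFactors = FALSE)
    path <- file.path(outdir, paste0(s, ".fastq"))
    write_fastq(reads, path)
    paths[s] <- path
    manifest[[s]] <- data.frame(sample = rep(s, length(ids)),
                                read_id = ids, source = srcs,
                                class = clss, stringsAsFactors = FALSE)
  }
  list(fastq_paths = paths, manifest = do.call(rbind, manifest),
       true_counts = true_counts, groups = groups)
}

#' Write ground truth to a TSV file
#'
#' Serializes the miRNA-level ground truth (one row per planted miRNA,
#' with its true target genes collapsed into a comma-separated column) so
#' that [read_truth()] round-trips it losslessly.
#'
#' @param truth `truth` element of [generate_references()].
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  mir <- truth$mirnas
  tg <- vapply(mir$id, function(id) {
    g <- truth$targets$gene[truth$targets$mirna == id]
    paste(sort(g), collapse = ",")
  }, character(1))
  out <- cbind(mir, target_genes = unname(tg))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#'
#' @param path TSV path.
#' @return GroundTruth list (`mirnas`, `targets`).
#' @export
read_truth <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(target_genes = "character"))
  tg <- tab$target_genes
  tab$target_genes <- NULL
  keep <- nzchar(tg) & !is.na(tg)
  targets <- if (any(keep)) {
    genes <- strsplit(tg[keep], ",", fixed = TRUE)
    data.frame(mirna = rep(tab$id[keep], lengths(genes)),
               gene = unlist(genes), stringsAsFactors = FALSE)
  } else data.frame(mirna = character(0), gene = character(0),
                    stringsAsFactors = FALSE)
  list(mirnas = tab, targets = targets)
}

#' Truth-label recovery of an annotation run
#'
#' Matches each annotated tag back to its source miRNA by its (unique)
#' 5' 18-mer and reports the fraction of tags whose assigned label equals
#' the planted group label.
#'
#' @param records data.frame from [annotate_tags()].
#' @param truth GroundTruth.
#' @return list with `recovery` (fraction), `n_matched`, `mismatches`
#'   (data.frame of disagreeing tags).
#' @export
label_recovery <- function(records, truth) {
  mir <- truth$mirnas
  key <- substr(mir$sequence, 1L, 18L)
  idx <- match(substr(records$sequence, 1L, 18L), key)
  matched <- !is.na(idx)
  ok <- records$label[matched] == mir$group[idx[matched]]
  list(recovery = mean(ok), n_matched = sum(matched),
       mismatches = data.frame(
         sequence = records$sequence[matched][!ok],
         assigned = records$label[matched][!ok],
         truth = mir$group[idx[matched]][!ok],
         stringsAsFactors = FALSE))
}
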