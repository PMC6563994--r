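# Database matching, genome placement, flank extraction, contaminant
# screening and the group decision tree.

test_that("exact tag matches its reference with zero mismatches and the
           reference class is carried", {
  db <- list(specific = c("dre-mir-1" = "TAGCTTATCAGACTGGTGTTGG"),
             selected = c("fru-mir-2" = "ACCCGTAGATCCGAACTTGTGG"))
  h <- match_mirbase("TAGCTTATCAGACTGGTGTTGG", db)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "specific")
  expect_equal(h$mismatches, 0L)
})

test_that("two mismatches in the first 16 nt reject the hit; one is kept;
           mismatches beyond position 16 reject", {
  ref <- "TAGCTTATCAGACTGGTGTTGG"
  db <- list(selected = c(r = ref))
  t1 <- ref; substr(t1, 3, 3) <- "C"
  expect_equal(nrow(match_mirbase(t1, db)), 1L)
  t2 <- t1; substr(t2, 9, 9) <- "A"
  expect_equal(nrow(match_mirbase(t2, db)), 0L)
  t3 <- ref; substr(t3, 18, 18) <- "A"
  expect_equal(nrow(match_mirbase(t3, db)), 0L)
  # 3' length tolerance: 2 nt kept, 3 nt rejected
  expect_equal(nrow(match_mirbase(substr(ref, 1, nchar(ref) - 2), db)), 1L)
  expect_equal(nrow(match_mirbase(substr(ref, 1, nchar(ref) - 3), db)), 0L)
})

test_that("hit sets on a random fixture equal the exhaustive
           mismatch-counting oracle", {
  set.seed(51)
  refs <- setNames(vapply(1:12, function(i) rand_dna(22), ""),
                   paste0("ref", 1:12))
  tags <- character(50)
  for (i in 1:50) {
    if (i <= 25) {                     # perturbed copies of references
      base <- refs[[sample(12, 1)]]
      nmut <- sample(0:3, 1)
      for (m in seq_len(nmut)) {
        p <- sample(22, 1)
        substr(base, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5) base <- substr(base, 1, 22 - sample(0:3, 1))
      tags[i] <- base
    } else tags[i] <- rand_dna(sample(19:24, 1))
  }
  for (tg in tags) {
    got <- sort(match_mirbase(tg, list(selected = refs))$ref_id)
    expect_equal(got, sort(oracle_match(tg, refs)), info = tg)
  }
})

test_that("genome placement finds planted loci on both strands in
           deterministic order, and absent sequences return empty", {
  m <- "TAGCTTATCAGACTGGTGTTGG"
  genome <- c(chrA = paste0(rand_dna(50), m, rand_dna(30),
                            troutmir:::.revcomp(m), rand_dna(20)))
  loci <- map_genome(m, genome)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$strand, c("+", "-"))
  expect_equal(loci$start[1], 50L)
  expect_equal(loci$end[1], 50L + nchar(m))
  expect_equal(nrow(map_genome("GGGGGGGGGGGGGGGGGGGG", genome)), 0L)
})

test_that("flank windows truncate at contig ends and minus-strand windows
           equal the reverse complement of the forward extraction", {
  set.seed(52)
  genome <- c(c1 = rand_dna(400))
  locus <- list(contig = "c1", start = 150L, end = 172L, strand = "+")
  fw <- flanks(locus, genome)
  expect_equal(nchar(fw$window), 22L + 160L)
  expect_equal(fw$mature_start, 81L)
  expect_equal(fw$mature_end, 102L)
  expect_false(fw$truncated)
  expect_equal(substr(fw$window, 81, 102),
               substr(genome[["c1"]], 151, 172))
  # minus strand: window is the reverse complement, mature offset mirrored
  rv <- flanks(modifyList(locus, list(strand = "-")), genome)
  expect_equal(rv$window, troutmir:::.revcomp(fw$window))
  expect_equal(rv$mature_start, 81L)
  # contig start: left flank shorter, offset adjusted
  tr <- flanks(list(contig = "c1", start = 10L, end = 32L, strand = "+"),
               genome)
  expect_true(tr$truncated)
  expect_equal(tr$mature_start, 11L)
})

test_that("contaminant screening is exact-substring with fixed precedence", {
  refs <- list(mRNA = c(paste0(rand_dna(30), "ACGTACGTACGTACGTACGT",
                               rand_dna(30))),
               otherRNA = c(paste0("TTTTCCCCGGGGAAAATTTTCCCC",
                                   rand_dna(40))),
               "repeat" = c(paste0(rand_dna(20), "ACGTACGTACGTACGTACGT",
                                   rand_dna(20))))
  expect_equal(contaminant_screen("TTTTCCCCGGGGAAAATTTT", refs), "otherRNA")
  # present in both mRNA and repeat references: precedence gives mRNA
  expect_equal(contaminant_screen("ACGTACGTACGTACGTACGT", refs), "mRNA")
  expect_true(is.na(contaminant_screen("GGGGGGGGGGGGGGGGGGGG", refs)))
})

test_that("decision-tree labels match the independently coded truth table
           over the exhaustively enumerated evidence space", {
  hit_df <- function(on) {
    if (!on) return(data.frame(ref_id = character(0), class = character(0)))
    data.frame(ref_id = "r1", class = "selected", stringsAsFactors = FALSE)
  }
  loci_df <- function(n) {
    data.frame(contig = rep("c", n), start = seq_len(n) * 100,
               end = seq_len(n) * 100 + 22, strand = rep("+", n),
               stringsAsFactors = FALSE)
  }
  combos <- expand.grid(has_hit = c(FALSE, TRUE),
                        gene_maps = c(FALSE, TRUE),
                        n_loci = 0:2,
                        at_known = c(FALSE, TRUE),
                        hairpin_pass = c(FALSE, TRUE),
                        known_trout = c(FALSE, TRUE))
  seen <- character(0)
  for (r in seq_len(nrow(combos))) {
    cb <- combos[r, ]
    got <- classify(list(db_hits = hit_df(cb$has_hit),
                         gene_maps = cb$gene_maps,
                         tag_loci = loci_df(cb$n_loci),
                         at_known = cb$at_known,
                         hairpin_pass = cb$hairpin_pass,
                         known_trout_hit = cb$known_trout))
    want <- oracle_label(cb$has_hit, cb$has_hit && cb$gene_maps, cb$n_loci,
                         cb$at_known, cb$hairpin_pass, cb$known_trout)
    # classify() only consults gene_maps when a hit exists; align oracle
    got2 <- classify(list(db_hits = hit_df(cb$has_hit),
                          gene_maps = cb$has_hit && cb$gene_maps,
                          tag_loci = loci_df(cb$n_loci),
                          at_known = cb$at_known,
                          hairpin_pass = cb$hairpin_pass,
                          known_trout_hit = cb$known_trout))
    expect_equal(got2$label, want)
    seen <- c(seen, want)
  }
  expect_setequal(unique(seen),
                  c("gp1a", "gp1b", "gp2a", "gp2b", "gp3a", "gp3b",
                    "gp4a", "gp4b", "nohit"))
  # gp1c secondary flag: extra loci beyond the known/primary one
  fl <- classify(list(db_hits = hit_df(TRUE), gene_maps = TRUE,
                      tag_loci = loci_df(2), at_known = TRUE,
                      hairpin_pass = FALSE, known_trout_hit = FALSE))
  expect_equal(fl$label, "gp1a")
  expect_true(fl$gp1c)
})

test_that("a database hit with an empty reference id is contradictory", {
  expect_error(classify(list(
    db_hits = data.frame(ref_id = "", class = "selected",
                         stringsAsFactors = FALSE),
    gene_maps = FALSE, tag_loci = data.frame(), at_known = FALSE,
    hairpin_pass = FALSE, known_trout_hit = FALSE)), "contradictory")
})

test_that("annotation of a noise-free simulated library recovers the
           planted group labels and partitions all mappable tags", {
  fx <- small_run()
  rec <- annotate_tags(fx$prep$tags, fx$ref$bundle)
  expect_equal(nrow(rec), nrow(fx$prep$tags))
  expect_true(all(table(rec$sequence) == 1L))
  lr <- label_recovery(rec, fx$ref$truth)
  expect_gte(lr$recovery, 0.95)
  rep <- group_report(rec, fx$prep$tags)
  expect_equal(sum(rep$reads$count), rep$mappable)
})
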