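# Single stem-loop folding and the 11-criterion hairpin filter.

test_that("perfect inverted repeat folds into a fully paired stem whose dG
           is the sum of its stack terms plus the loop penalty", {
  arm <- "GCAGTCAGGTACGTACGATCGATCG"          # 25 nt
  loop <- "AACGTA"
  win <- paste0(arm, loop, troutmir:::.revcomp(arm))
  f <- fold_hairpin(win)
  expect_equal(nrow(f$pairs), 25L)
  # hand-summed stack energies along the helix
  stack <- stack_energy_table()
  rna <- chartr("T", "U", arm)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  b <- strsplit(rna, "")[[1]]
  pairs <- paste0(b, comp[b])
  hand <- sum(vapply(seq_len(24), function(t) stack[pairs[t], pairs[t + 1]],
                     0)) + fold_params()$hairpin
  expect_equal(f$dG, hand, tolerance = 1e-9)
})

test_that("windows without pairing potential return an open structure", {
  f <- fold_hairpin(strrep("A", 60))
  expect_equal(f$dG, 0)
  expect_equal(nrow(f$pairs), 0L)
  expect_equal(f$dotbracket, strrep(".", 60))
})

test_that("internal DP matches the exhaustive folding oracle on random
           short windows", {
  set.seed(421)
  for (rep in 1:30) {
    n <- sample(25:40, 1)
    win <- rand_dna(n)
    expect_equal(fold_hairpin(win)$dG, oracle_fold_dG(win),
                 tolerance = 1e-9, info = win)
  }
})

test_that("each hairpin criterion flips at its published boundary", {
  # c2: 15 vs 16 stem base pairs
  m <- c(3, 24)   # mature inside the stem
  c15 <- hairpin_criteria(stem_pairs(15, 8), -30, 3, 14, 60)
  c16 <- hairpin_criteria(stem_pairs(16, 8), -30, 3, 14, 60)
  expect_false(c15$c2); expect_true(c16$c2)

  # c3: dG -14.5 vs -15
  p <- stem_pairs(20, 8)
  expect_false(hairpin_criteria(p, -14.5, 3, 18, 60)$c3)
  expect_true(hairpin_criteria(p, -15, 3, 18, 60)$c3)

  # c4: hairpin length 49 vs 50 (16 bp stem, loop 17 vs 18)
  expect_false(hairpin_criteria(stem_pairs(16, 17), -30, 2, 15, 70)$c4)
  expect_true(hairpin_criteria(stem_pairs(16, 18), -30, 2, 15, 70)$c4)

  # c5: loop 200 vs 201
  expect_true(hairpin_criteria(stem_pairs(20, 200), -40, 2, 19, 260)$c5)
  expect_false(hairpin_criteria(stem_pairs(20, 201), -40, 2, 19, 261)$c5)

  # c1: one stem bulge of 12 vs 13 nt (outside the mature region)
  mk_bulged <- function(gap) {
    top <- stem_pairs(20, 8)
    # shift outer 5 pairs left by `gap` to open a 5'-side bulge
    top[1:5, "i"] <- top[1:5, "i"]
    top[6:20, "i"] <- top[6:20, "i"] + gap
    top[6:20, "j"] <- top[6:20, "j"]
    top
  }
  b12 <- mk_bulged(12); b13 <- mk_bulged(13)
  expect_true(hairpin_criteria(b12, -30, 40, 48, 80)$c1)
  expect_false(hairpin_criteria(b13, -30, 41, 49, 81)$c1)

  # c6/c7: bulge inside the mature region; the same interruption drives
  # both the bulge-size and the errors-in-one-bulge criteria
  mk_mat_bulge <- function(gap) {
    p <- stem_pairs(20, 8)
    p[11:20, "i"] <- p[11:20, "i"] + gap
    p
  }
  mature_span <- c(5, 26)
  g2 <- mk_mat_bulge(2); g3 <- mk_mat_bulge(3); g5 <- mk_mat_bulge(5)
  expect_true(hairpin_criteria(g2, -30, 5, 26, 80)$c7)
  expect_false(hairpin_criteria(g3, -30, 5, 26, 80)$c7)
  expect_true(hairpin_criteria(g3, -30, 5, 26, 80)$c6)   # bulge 3 <= 4
  expect_false(hairpin_criteria(g5, -30, 5, 26, 80)$c6)  # bulge 5 > 4

  # c8: 2 vs 3 biased one-sided bulges in the mature region
  mk_multi_bulge <- function(k) {
    p <- stem_pairs(20, 8)
    for (t in seq_len(k)) {
      idx <- 4 * t
      p[(idx + 1):20, "i"] <- p[(idx + 1):20, "i"] + 1L
    }
    p
  }
  expect_true(hairpin_criteria(mk_multi_bulge(2), -30, 3, 24, 80)$c8)
  expect_false(hairpin_criteria(mk_multi_bulge(3), -30, 3, 24, 80)$c8)

  # c9: 4 vs 5 unpaired mature positions (spread across two interruptions,
  # mature kept within the 5' stem arm)
  mk_two_bulges <- function(g1, g2) {
    p <- stem_pairs(20, 8)
    p[8:20, "i"] <- p[8:20, "i"] + g1
    p[15:20, "i"] <- p[15:20, "i"] + g2
    p
  }
  expect_true(hairpin_criteria(mk_two_bulges(2, 2), -30, 5, 20, 80)$c9)
  expect_false(hairpin_criteria(mk_two_bulges(3, 2), -30, 5, 20, 80)$c9)

  # c10: 11 vs 12 base pairs in the mature region
  p20 <- stem_pairs(20, 8)
  expect_false(hairpin_criteria(p20, -30, 1, 11, 60)$c10)
  expect_true(hairpin_criteria(p20, -30, 1, 12, 60)$c10)

  # c11: fraction of mature inside the stem, 80% (fail, strict >) vs 90%
  # 20 nt mature partially upstream of the outer stem at position 5
  p18 <- stem_pairs(18, 8, start = 5L)
  expect_false(hairpin_criteria(p18, -30, 1, 20, 60)$c11)  # 16/20 = 80%
  expect_true(hairpin_criteria(p18, -30, 3, 22, 60)$c11)   # 18/20 = 90%
})

test_that("all-pass fixture passes and the verdict is the conjunction", {
  res <- hairpin_criteria(stem_pairs(25, 6), -30, 2, 23, 56)
  expect_true(res$pass)
  expect_true(all(unlist(res[paste0("c", 1:11)])))
  # flipping one criterion (dG) flips the verdict
  res2 <- hairpin_criteria(stem_pairs(25, 6), -10, 2, 23, 56)
  expect_false(res2$c3)
  expect_false(res2$pass)
})

test_that("extending a stem with additional pairs never flips the
           stem-size criterion from true to false", {
  for (np in 16:24) {
    a <- hairpin_criteria(stem_pairs(np, 8), -30, 3, 14, 80)
    b <- hairpin_criteria(stem_pairs(np + 1, 8), -30, 3, 14, 80)
    expect_false(a$c2 && !b$c2)
  }
})

test_that("mature region outside the window is rejected", {
  expect_error(hairpin_criteria(stem_pairs(16, 8), -30, 50, 80, 60),
               "mature region")
})

test_that("RNAfold-dialect files are parsed and multibranch structures
           rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">w1", "GGGAAACCC", "(((...))) ( -7.20)",
               "ACGUACGUACGU", "............ (0.00)"), path)
  tab <- read_rnafold(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$dG, c(-7.2, 0))
  expect_equal(tab$name[1], "w1")
  p <- troutmir:::.pairs_from_dotbracket("(((...)))")
  expect_equal(nrow(p), 3L)
  expect_error(troutmir:::.pairs_from_dotbracket("((..))((..))"),
               "single stem-loop")
  expect_error(troutmir:::.pairs_from_dotbracket("(((..))"), "unbalanced")
})

test_that("an external structure bypasses internal folding in evaluation", {
  win <- paste0(strrep("G", 20), strrep("A", 6), strrep("C", 20))
  ext <- list(dotbracket = paste0(strrep("(", 20), strrep(".", 6),
                                  strrep(")", 20)), dG = -44)
  ev <- evaluate_hairpin(win, 2, 19, external = ext)
  expect_equal(ev$dG, -44)
  expect_equal(ev$stem_bp, 20L)
})
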