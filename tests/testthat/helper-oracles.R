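# Independent oracles used to verify the package's dynamic-programming and
# statistical routines. Each is a separate, deliberately naive formulation
# of the same contract; none shares code with the implementation it checks.

# ---- single stem-loop folding oracle ------------------------------------
# Memoized recursion over closed intervals (Nussinov-style energy
# minimization restricted to one nested run of pairs), using the same
# energy terms as the package model.
oracle_fold_dG <- function(seq, params = troutmir::fold_params()) {
  seq <- chartr("tT", "uU", toupper(seq))
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  stack <- troutmir::stack_energy_table()
  pair_name <- function(a, b) {
    p <- paste0(toupper(a), toupper(b))
    p <- chartr("U", "U", p)
    if (p %in% rownames(stack)) p else NA_character_
  }
  pn <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) pn[i, j] <- pair_name(bases[i], bases[j])
  memo <- matrix(NA_real_, n, n)
  minloop <- params$min_loop
  maxint <- params$max_intr
  Efun <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- Inf
    if (j - i - 1 >= minloop) best <- params$hairpin
    for (k in (i + 1):min(i + 1 + maxint, j - minloop - 1)) {
      if (k > j - minloop - 1) break
      for (l in (j - 1):max(k + minloop + 1, j - 1 - maxint)) {
        if (l < k + minloop + 1) break
        if (is.na(pn[k, l])) next
        inner <- Efun(k, l)
        cost <- if (k == i + 1 && l == j - 1) stack[pn[i, j], pn[k, l]]
                else params$intr_open +
                     params$intr_per_nt * ((k - i - 1) + (j - l - 1))
        if (cost + inner < best) best <- cost + inner
      }
    }
    memo[i, j] <<- best
    best
  }
  dG <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1 < minloop || is.na(pn[i, j])) next
      v <- Efun(i, j)
      if (v < dG) dG <- v
    }
  }
  dG
}

# ---- adapter trimming oracle --------------------------------------------
# Exhaustive shift-and-compare over every adapter start offset.
oracle_trim <- function(read, adapter, min_overlap = 6L,
                        max_mismatch_rate = 0.1) {
  n <- nchar(read)
  if (n == 0L) return(NA_character_)
  rr <- strsplit(read, "")[[1]]
  aa <- strsplit(adapter, "")[[1]]
  best <- NULL
  for (p in seq_len(n)) {
    ov <- min(length(aa), n - p + 1L)
    if (ov < min_overlap) next
    mm <- sum(rr[p:(p + ov - 1L)] != aa[seq_len(ov)])
    if (mm / ov > max_mismatch_rate) next
    sc <- (ov - mm) - mm
    if (is.null(best) || sc > best$sc || (sc == best$sc && p > best$p))
      best <- list(sc = sc, p = p)
  }
  if (is.null(best)) return(NA_character_)
  substr(read, 1L, best$p - 1L)
}

# ---- miRBase matching oracle --------------------------------------------
oracle_match <- function(tag, refs) {
  hits <- character(0)
  for (id in names(refs)) {
    ref <- refs[[id]]
    if (abs(nchar(tag) - nchar(ref)) > 2L) next
    L <- min(nchar(tag), nchar(ref))
    tb <- strsplit(substr(tag, 1, L), "")[[1]]
    rb <- strsplit(substr(ref, 1, L), "")[[1]]
    mm <- which(tb != rb)
    if (sum(mm <= 16) <= 1L && !any(mm > 16)) hits <- c(hits, id)
  }
  hits
}

# ---- duplex alignment oracle --------------------------------------------
# Exhaustive maximization over all monotone chains of aligned residue
# pairs, with explicit affine jump costs; memoized on the chain end.
oracle_duplex_S <- function(mirna, window, scheme = troutmir::scoring_scheme()) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(toupper(mirna), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  M <- length(m); N <- length(w)
  if (M == 0 || N == 0) return(0)
  r <- rev(m)                         # miRNA read 3'->5'
  ps <- function(a, b) {              # pair score, a indexes r
    pos5 <- M - (a - 1)               # 5'-based miRNA position
    x <- r[a]; y <- w[b]
    v <- if (comp[[y]] == x) scheme$match
         else if ((x == "G" && y == "T") || (x == "T" && y == "G"))
           scheme$wobble
         else scheme$mismatch
    if (pos5 >= scheme$seed_start && pos5 <= scheme$seed_end)
      v * scheme$seed_scale else v
  }
  gapcost <- function(len) if (len == 0) 0 else
    scheme$gap_open + (len - 1) * scheme$gap_extend
  memo <- matrix(NA_real_, M, N)
  ext <- function(a, b) {             # best continuation after pair (a,b)
    if (!is.na(memo[a, b])) return(memo[a, b])
    best <- 0                         # stop here
    if (a < M && b < N) {
      for (a2 in (a + 1):M) for (b2 in (b + 1):N) {
        v <- gapcost(a2 - a - 1) + gapcost(b2 - b - 1) + ps(a2, b2) +
          ext(a2, b2)
        if (v > best) best <- v
      }
    }
    memo[a, b] <<- best
    best
  }
  best <- 0
  for (a in seq_len(M)) for (b in seq_len(N)) {
    v <- ps(a, b) + ext(a, b)
    if (v > best) best <- v
  }
  best
}

# ---- Welch t oracle -----------------------------------------------------
oracle_welch <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  list(t = t, df = df, p = p)
}

# ---- hypergeometric tail oracle (direct summation via choose) -----------
oracle_hyper_tail <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# ---- Tukey HSD oracle (studentized range, from first principles) --------
oracle_tukey <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, 0)
  dfres <- sum(ns) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / dfres
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    q <- abs(means[j] - means[i]) /
      sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    out[[paste(names(groups)[j], names(groups)[i], sep = "-")]] <-
      unname(ptukey(q, nmeans = k, df = dfres, lower.tail = FALSE))
  }
  out
}

# ---- average-linkage (UPGMA) merge heights, direct algorithm ------------
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  D <- matrix(Inf, n + (n - 1), n + (n - 1))
  D[1:n, 1:n] <- d
  diag(D) <- Inf
  heights <- numeric(0)
  cur <- n
  alive <- 1:n
  while (length(alive) > 1) {
    sub <- D[alive, alive, drop = FALSE]
    ix <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- alive[ix[1]]; b <- alive[ix[2]]
    heights <- c(heights, D[a, b])
    cur <- cur + 1
    members[[cur]] <- c(members[[a]], members[[b]])
    alive <- c(setdiff(alive, c(a, b)), cur)
    for (o in setdiff(alive, cur)) {
      # average over all inter-cluster leaf distances
      D[cur, o] <- D[o, cur] <-
        mean(d[members[[cur]], members[[o]], drop = FALSE])
    }
  }
  heights
}

# ---- decision-tree truth table, independently coded ---------------------
oracle_label <- function(has_hit, gene_maps, n_loci, at_known,
                         hairpin_pass, known_trout) {
  if (!has_hit) {
    if (n_loci == 0) return("nohit")
    if (hairpin_pass) return("gp4a") else return("gp4b")
  }
  if (gene_maps) {
    if (at_known) return("gp1a") else return("gp1b")
  }
  if (n_loci > 0) {
    if (hairpin_pass) return("gp2a") else return("gp2b")
  }
  if (known_trout) "gp3a" else "gp3b"
}

# ---- pair-matrix builder for criteria fixtures --------------------------
# Perfect nested stem of `npair` pairs starting at `start` with terminal
# loop of `loop` nt; i_t = start+t-1, j_t = start + 2*npair + loop - t.
stem_pairs <- function(npair, loop, start = 1L) {
  t <- seq_len(npair)
  cbind(i = start + t - 1L, j = start + 2L * npair + loop - t)
}

# random DNA sequence
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
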