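# Independent brute-force oracles, deliberately written with different
# machinery than the package (lm(), recursive search, full 64x64 scans).

# every sliding-window regression slope of log2(od - blank) vs time, via lm()
oracle_window_slopes <- function(time_min, od600, window_min = 120,
                                 blank = 0) {
  od <- od600 - blank
  keep <- od > 0
  tt <- time_min[keep]
  yy <- log2(od[keep])
  slopes <- numeric(0)
  for (i in seq_along(tt)) {
    if (tt[i] + window_min > max(tt) + 1e-9) next
    j <- which(tt >= tt[i] & tt <= tt[i] + window_min + 1e-9)
    j <- j[j >= i]
    if (length(j) < 3) next
    slopes <- c(slopes, unname(coef(lm(yy[j] ~ tt[j]))[2]))
  }
  slopes
}

oracle_top_k_rate <- function(time_min, od600, window_min = 120, top_k = 3,
                              blank = 0) {
  s <- sort(oracle_window_slopes(time_min, od600, window_min, blank),
            decreasing = TRUE)
  mean(s[seq_len(min(top_k, length(s)))])
}

# all shortest paths between two genotype labels by recursive DFS over
# single-letter neighbors that reduce the Hamming distance to the goal
oracle_direct_paths <- function(start, end) {
  s <- strsplit(start, "")[[1]]
  e <- strsplit(end, "")[[1]]
  recurse <- function(cur) {
    if (all(cur == e)) return(list(paste0(cur, collapse = "")))
    out <- list()
    for (i in which(cur != e)) {
      nxt <- cur
      nxt[i] <- e[i]
      for (tail in recurse(nxt))
        out[[length(out) + 1L]] <- c(paste0(cur, collapse = ""), tail)
    }
    out
  }
  recurse(s)
}

# minimum codon Hamming distance between amino acids by a full 64x64 scan
oracle_code <- Biostrings::GENETIC_CODE
oracle_codon_chars <- strsplit(names(oracle_code), "")

oracle_pair_dist <- function(i, j) {
  sum(oracle_codon_chars[[i]] != oracle_codon_chars[[j]])
}

oracle_min_aa_distance <- function(aaA, aaB) {
  ia <- which(oracle_code == aaA)
  ib <- which(oracle_code == aaB)
  best <- 3L
  for (i in ia) for (j in ib) best <- min(best, oracle_pair_dist(i, j))
  best
}

oracle_bridges <- function(aaA, aaB) {
  ia <- which(oracle_code == aaA)
  ib <- which(oracle_code == aaB)
  sense <- which(oracle_code != "*")
  hits <- character(0)
  for (z in setdiff(sense, c(ia, ib))) {
    if (oracle_code[z] %in% c(aaA, aaB)) next
    near_a <- any(vapply(ia, function(i) oracle_pair_dist(z, i) == 1, TRUE))
    near_b <- any(vapply(ib, function(i) oracle_pair_dist(z, i) == 1, TRUE))
    if (near_a && near_b) hits <- c(hits, unname(oracle_code[z]))
  }
  sort(unique(hits))
}

# character-by-character identity oracle
oracle_identity <- function(seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  n_match <- 0L
  n_co <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("-", ".") || b[i] %in% c("-", ".")) next
    n_co <- n_co + 1L
    if (a[i] == b[i] && !(a[i] %in% c("X", "B", "Z"))) n_match <- n_match + 1L
  }
  if (n_co == 0L) return(NA_real_)
  100 * n_match / n_co
}

# random complete landscape over L loci with distinct letters per locus
random_landscape <- function(L, seed) {
  withr::with_seed(seed, {
    a1 <- LETTERS[seq_len(L)]
    a2 <- letters_pool <- LETTERS[L + seq_len(L)]
    loci <- do.call(landscape_loci, stats::setNames(
      lapply(seq_len(L), function(i) c(a1[i], a2[i])),
      paste0("p", seq_len(L))))
    labs <- all_genotype_labels(loci)
    build_landscape(stats::setNames(round(runif(length(labs)), 4), labs),
                    loci)
  })
}
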