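tiny_aln <- function() {
  seqs <- c(ref = "M-KV", s1 = "MAKV", s2 = "M-RV", s3 = "--KV")
  clade <- c(ref = "euk", s1 = "euk", s2 = "bac", s3 = "bac")
  labeled_alignment(seqs, clade, "ref")
}

test_that("reference residue numbers map to 0-based columns and round-trip", {
  aln <- tiny_aln()
  expect_identical(ref_position_to_column(aln, 1), 0L)
  expect_identical(ref_position_to_column(aln, 2), 2L) # gap at column 1
  expect_identical(ref_position_to_column(aln, 3), 3L)
  expect_error(ref_position_to_column(aln, 4), "1\\.\\.3")
  gap_lead <- labeled_alignment(c(r = "--MA", s = "AAMA"),
                                c(r = "x", s = "x"), "r")
  expect_identical(ref_position_to_column(gap_lead, 1), 2L)
  expect_identical(column_to_ref_position(gap_lead, 2), 1L)
  expect_error(column_to_ref_position(gap_lead, 0), "gapped")
  # random gapped references agree with a naive scan oracle
  withr::with_seed(7, {
    for (rep in 1:10) {
      chars <- sample(c("A", "C", "D", "-"), 40, replace = TRUE,
                      prob = c(0.3, 0.3, 0.2, 0.2))
      if (all(chars == "-")) chars[1] <- "A"
      aln2 <- labeled_alignment(
        c(r = paste(chars, collapse = ""),
          s = paste(rep("A", 40), collapse = "")),
        c(r = "x", s = "x"), "r")
      nongap <- which(chars != "-")
      for (p in seq_along(nongap)) {
        expect_identical(ref_position_to_column(aln2, p),
                         as.integer(nongap[p] - 1L))
        expect_identical(column_to_ref_position(aln2, nongap[p] - 1L),
                         as.integer(p))
      }
    }
  })
})

test_that("column composition reproduces an archaeal-style 45/12/16 split and counts gaps", {
  dist219 <- list(archaea = c(S = 45 / 73, T = 12 / 73, V = 16 / 73))
  aln <- simulate_alignment(c(archaea = 73), n_columns = 5,
                            columns = list(list(pos = 3, dist = dist219)))
  prof <- column_composition(aln, 3)
  counts <- prof$counts["archaea", ]
  expect_identical(unname(counts[["S"]]), 45L)
  expect_identical(unname(counts[["T"]]), 12L)
  expect_identical(unname(counts[["V"]]), 16L)
  expect_identical(unname(prof$totals[["archaea"]]), 73L)
  # all-gap clade column
  gappy <- labeled_alignment(c(r = "MA", g1 = "M-", g2 = "M-"),
                             c(r = "euk", g1 = "arc", g2 = "arc"), "r")
  prof2 <- column_composition(gappy, 2)
  expect_identical(unname(prof2$counts["arc", "gap"]), 2L)
  # per-clade counts sum to clade totals, and over clades to the whole column
  expect_true(all(rowSums(prof$counts) == as.integer(prof$totals)))
  expect_identical(sum(prof$counts), nrow(aln$mat))
})

test_that("position association recovers a constructed 535/547 co-occurrence", {
  aln <- simulate_alignment(
    c(bacteria = 300, eukaryota = 247, archaea = 72), n_columns = 4,
    columns = list(list(pos = 2, dist = list(bacteria = c(K = 1),
                                             eukaryota = c(K = 1),
                                             archaea = c(S = 1)))),
    coupled = list(posA = 2, stateA = "K", posB = 4, stateB = "E",
                   conditional = 535 / 547))
  assoc <- position_association(aln, 2, "K", 4, "E")
  expect_identical(unname(assoc$counts["yes", "yes"]), 535L)
  expect_identical(assoc$n_stateA, 547L)
  expect_equal(assoc$conditional, 535 / 547, tolerance = 1e-12)
  expect_false(assoc$undefined)
  # transposing the pair transposes the contingency table
  flip <- position_association(aln, 4, "E", 2, "K")
  expect_equal(as.vector(flip$counts), as.vector(t(assoc$counts)))
  # sequence order does not matter
  perm <- withr::with_seed(3, sample(names(aln$sequences)))
  aln2 <- labeled_alignment(aln$sequences[perm], aln$clade, "REF")
  expect_identical(position_association(aln2, 2, "K", 4, "E")$counts,
                   assoc$counts)
  # no carriers of stateA -> undefined flag
  none <- position_association(aln, 2, "W", 4, "E")
  expect_true(none$undefined)
  expect_true(is.na(none$conditional))
})

test_that("independently simulated columns show conditional close to marginal", {
  hits <- withr::with_seed(21, replicate(30, {
    aln <- simulate_alignment(
      c(c1 = 200), n_columns = 2,
      columns = list(
        list(pos = 1, dist = list(c1 = c(K = 0.5, S = 0.5)),
             mode = "stochastic"),
        list(pos = 2, dist = list(c1 = c(E = 0.7, A = 0.3)),
             mode = "stochastic")),
      seed = sample.int(1e6, 1))
    position_association(aln, 1, "K", 2, "E")$conditional
  }))
  expect_equal(mean(hits, na.rm = TRUE), 0.7, tolerance = 0.05)
})

test_that("pairwise identity matches hand counts and the character oracle", {
  aln <- labeled_alignment(c(a = "AC-D", b = "AG-D", c = "AC-D",
                             d = "----"),
                           c(a = "x", b = "x", c = "x", d = "x"), "a")
  expect_equal(pairwise_identity(aln, "a", "c"), 100)
  expect_equal(pairwise_identity(aln, "a", "b"), 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(pairwise_identity(aln, "a", "b"),
               pairwise_identity(aln, "b", "a"))
  expect_warning(ident <- pairwise_identity(aln, "a", "d"), "undefined")
  expect_true(is.na(ident))
  # ambiguity codes never match
  amb <- labeled_alignment(c(p = "XXAA", q = "XXAA"), c(p = "x", q = "x"),
                           "p")
  expect_equal(pairwise_identity(amb, "p", "q"), 50)
  withr::with_seed(11, {
    for (rep in 1:10) {
      s1 <- paste(sample(c("A", "C", "D", "X", "-"), 60, TRUE),
                  collapse = "")
      s2 <- paste(sample(c("A", "C", "D", "X", "-"), 60, TRUE),
                  collapse = "")
      aln2 <- labeled_alignment(c(u = s1, v = s2), c(u = "x", v = "x"), "u")
      got <- suppressWarnings(pairwise_identity(aln2, "u", "v"))
      expect_equal(got, oracle_identity(s1, s2), tolerance = 1e-12)
      expect_true(is.na(got) || got <= 100)
    }
  })
})

test_that("tolerated-set overlap reports exclusives and Jaccard", {
  ov <- tolerated_set_overlap(c("K", "S", "R", "T", "V", "A", "G"),
                              c("S", "T", "V", "R", "A", "L"))
  expect_identical(ov$observed_only, c("G", "K"))
  expect_identical(ov$natural_only, "L")
  expect_identical(ov$intersection, c("A", "R", "S", "T", "V"))
  expect_equal(ov$jaccard, 5 / 8, tolerance = 1e-12)
  expect_equal(tolerated_set_overlap(c("A", "B"), c("B", "A"))$jaccard, 1)
  expect_equal(tolerated_set_overlap("A", "C")$jaccard, 0)
  expect_error(tolerated_set_overlap(character(0), "A"), "non-empty")
})

test_that("labeled alignments round-trip through FASTA plus labels TSV", {
  aln <- simulate_alignment(c(bac = 5, arc = 4), n_columns = 12,
                            columns = list(list(pos = 6,
                                                dist = list(bac = c(K = 1),
                                                            arc = c(S = 1)))))
  fa <- file.path(tempdir(), "aln.fasta")
  tsv <- file.path(tempdir(), "aln_labels.tsv")
  write_labeled_alignment(aln, fa, tsv)
  back <- read_labeled_alignment(fa, tsv, "REF")
  expect_identical(back$sequences, aln$sequences)
  expect_identical(back$clade, aln$clade)
  expect_identical(column_composition(back, 6)$counts,
                   column_composition(aln, 6)$counts)
})
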