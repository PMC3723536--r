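pgk_land <- make_landscape_preset("pgk219")

test_that("landscape construction validates labels, alleles and completeness", {
  loci <- landscape_loci("219:K/S", "239:M/I", "403:E/D")
  fit <- pgk_land$fitness
  land <- build_landscape(fit, loci)
  expect_true(land$complete)
  expect_length(land$fitness, 8)
  incomplete <- build_landscape(fit[-1], loci)
  expect_false(incomplete$complete)
  expect_error(enumerate_direct_paths(incomplete, "KME", "SID"),
               "incomplete")
  expect_error(build_landscape(c(fit, XME = 0.01), loci), "not valid")
  expect_error(build_landscape(stats::setNames(c(fit, 0.01),
                                               c(names(fit), "KME")), loci),
               "duplicate")
  expect_error(build_landscape(stats::setNames(-1, "KME"), loci), ">= 0")
})

test_that("direct path enumeration yields d! paths matching the DFS oracle up to L = 5", {
  expect_length(enumerate_direct_paths(pgk_land, "KME", "SID"), 6)
  p1 <- enumerate_direct_paths(pgk_land, "KME", "SME")
  expect_length(p1, 1)
  expect_equal(p1[[1]], c("KME", "SME"))
  for (L in 3:5) {
    land <- random_landscape(L, seed = L)
    labs <- all_genotype_labels(land$loci)
    start <- labs[1]
    end <- labs[length(labs)] # all-different corners: d = L
    paths <- enumerate_direct_paths(land, start, end)
    expect_length(paths, factorial(L))
    got <- sort(vapply(paths, paste, "", collapse = ">"))
    want <- sort(vapply(oracle_direct_paths(start, end), paste, "",
                        collapse = ">"))
    expect_identical(got, want)
  }
})

test_that("the pgk219 preset reproduces the 0/1/4 accessibility pattern across selection levels", {
  at <- function(theta) accessible_paths(pgk_land, "KME", "SID",
                                         theta = theta)
  expect_identical(at(0.0156)$n_accessible, 0L)
  strict <- at(0.0125)
  expect_identical(strict$n_accessible, 1L)
  expect_equal(strsplit(strict$verdicts$path[strict$verdicts$accessible],
                        ">")[[1]],
               c("KME", "KMD", "KID", "SID")) # 403 first, then 239, then 219
  weak <- at(min(pgk_land$fitness[pgk_land$fitness > 0]) / 2)
  expect_identical(weak$n_accessible, 4L)
  expect_identical(at(0)$n_accessible, 6L)
})

test_that("accessible path sets shrink monotonically with theta and zero-fitness genotypes block", {
  thetas <- sort(withr::with_seed(42, c(0, runif(8, 0, 0.02), 0.0074, 0.013)))
  prev <- NULL
  for (th in thetas) {
    acc <- accessible_paths(pgk_land, "KME", "SID", theta = th)
    ids <- acc$verdicts$path[acc$verdicts$accessible]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
  # every path through the lethal SME genotype is inaccessible for theta > 0
  acc <- accessible_paths(pgk_land, "KME", "SID", theta = 1e-9)
  through_sme <- grepl(">SME>", acc$verdicts$path)
  expect_true(any(through_sme))
  expect_false(any(acc$verdicts$accessible[through_sme]))
  expect_error(accessible_paths(pgk_land, "KME", "SID", theta = -0.1),
               "non-negative")
})

test_that("monotonic accessibility accepts only fitness-non-decreasing paths", {
  loci <- landscape_loci("p1:A/B", "p2:C/D")
  up <- build_landscape(c(AC = 1, BC = 2, AD = 1.5, BD = 3), loci)
  acc <- accessible_paths(up, "AC", "BD", mode = "monotonic")
  expect_identical(acc$n_accessible, 2L)
  valley <- build_landscape(c(AC = 1, BC = 0.5, AD = 1.5, BD = 3), loci)
  acc2 <- accessible_paths(valley, "AC", "BD", mode = "monotonic")
  expect_identical(acc2$n_accessible, 1L)
  expect_identical(acc2$verdicts$first_fail[!acc2$verdicts$accessible], "BC")
})

test_that("locus effects are background-conditional with fold-ratios flagged at zero fitness", {
  # additive synthetic landscape: identical effect on every background
  loci <- landscape_loci("p1:A/B", "p2:C/D", "p3:E/F")
  labs <- all_genotype_labels(loci)
  w <- vapply(strsplit(labs, ""), function(s)
    1 + 0.5 * (s[1] == "B") + 0.25 * (s[2] == "D") + 0.1 * (s[3] == "F"),
    numeric(1))
  add <- build_landscape(stats::setNames(w, labs), loci)
  effs <- c(locus_effect(add, "p1", c(p2 = "C", p3 = "E"))$delta,
            locus_effect(add, "p1", c(p2 = "D", p3 = "E"))$delta,
            locus_effect(add, "p1", c(p2 = "D", p3 = "F"))$delta)
  expect_equal(effs, rep(0.5, 3), tolerance = 1e-12)
  # preset: the 219 K->S swap on the wild-type M/E background is lethal
  eff <- locus_effect(pgk_land, "219", c(`239` = "M", `403` = "E"))
  expect_lt(eff$delta, 0)
  expect_true(eff$fold_undefined)
  expect_true(is.na(eff$fold))
  expect_error(locus_effect(pgk_land, "219", c(`239` = "M")), "non-focal")
})

test_that("epistasis classification matches hand-worked 2x2 cases", {
  loci <- landscape_loci("p1:A/B", "p2:C/D")
  mk <- function(ab, Ab, aB, AB)
    build_landscape(c(AC = ab, BC = Ab, AD = aB, BD = AB), loci)
  cl <- function(land, ...) classify_pairwise_epistasis(land, "p1", "p2", ...)
  add <- cl(mk(1, 2, 3, 4), zero_tol = 1e-9)
  expect_identical(add$classification, "additive")
  expect_equal(add$epsilon, 0)
  rec <- cl(mk(2, 1, 1, 2))
  expect_identical(rec$classification, "reciprocal_sign")
  expect_equal(rec$epsilon, 2)
  mag <- cl(mk(1, 2, 1.5, 2.2))
  expect_identical(mag$classification, "magnitude")
  expect_equal(mag$epsilon, -0.3, tolerance = 1e-12)
  sgn <- cl(mk(1, 2, 3, 2.5)) # p1 effect flips, p2 effect stays positive
  expect_identical(sgn$classification, "sign")
  expect_error(cl(mk(1, 2, 3, 0), scale = "log"), "log-scale")
})

test_that("the Table-1-derived WT/G4-v4 quartet shows sign-reversing 219 effects", {
  loci <- landscape_loci("219:K/S", "bg:W/G") # W = wild type, G = G4-v4
  quart <- build_landscape(
    c(KW = 1 / 63.8, SW = 0, KG = 1 / 79.5, SG = 1 / 73.4), loci)
  call <- classify_pairwise_epistasis(quart, "219", "bg")
  effs <- call$focal_effects$A
  expect_lt(effs[["on_b"]], 0) # K->S lethal on the wild-type background
  expect_gt(effs[["on_B"]], 0) # K->S beneficial on the evolved background
  expect_true(call$classification %in% c("sign", "reciprocal_sign"))
  # both conditional effects reverse here, so the rule yields the
  # reciprocal form of sign epistasis
  expect_identical(call$classification, "reciprocal_sign")
})

test_that("epistasis calls are invariant under locus swap and predictable under allele relabeling", {
  for (seed in 1:10) {
    land <- random_landscape(2, seed = 1000 + seed)
    nm <- land$loci$name
    a <- classify_pairwise_epistasis(land, nm[1], nm[2])
    b <- classify_pairwise_epistasis(land, nm[2], nm[1])
    expect_identical(a$classification, b$classification)
    expect_equal(a$epsilon, b$epsilon, tolerance = 1e-12)
    # relabel alleles of locus 1 (swap allele1/allele2): epsilon flips sign
    loci2 <- do.call(landscape_loci, stats::setNames(
      list(c(land$loci$allele2[1], land$loci$allele1[1]),
           c(land$loci$allele1[2], land$loci$allele2[2])), nm))
    land2 <- build_landscape(land$fitness, loci2)
    a2 <- classify_pairwise_epistasis(land2, nm[1], nm[2])
    expect_equal(a2$epsilon, -a$epsilon, tolerance = 1e-12)
    both <- c(a$classification, a2$classification)
    expect_identical(both[1], both[2])
  }
})

test_that("epistasis_table covers every pair and background of the preset", {
  tab <- epistasis_table(pgk_land)
  expect_equal(nrow(tab), 3 * 2) # 3 pairs x 2 backgrounds of the third locus
  ser_bg <- tab[tab$locusA == "239" & tab$locusB == "403" &
                  tab$background == "S", ]
  expect_equal(ser_bg$epsilon,
               0.0130 - 0.0074 - 0.0074 + 0, tolerance = 1e-12)
  expect_lt(ser_bg$epsilon, 0) # negative epistasis on the serine background
})

test_that("landscape TSV tables round-trip", {
  path <- file.path(tempdir(), "cube.tsv")
  write.table(data.frame(genotype_label = names(pgk_land$fitness),
                         fitness = unname(pgk_land$fitness),
                         sd = 0.0005),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  land <- read_landscape_table(path, pgk_land$loci)
  expect_true(land$complete)
  expect_equal(land$fitness, pgk_land$fitness)
  expect_equal(unname(land$sd["KME"]), 0.0005)
})
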