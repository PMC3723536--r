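#' Define the biallelic loci of a fitness landscape
#'
#' Loci are named residue positions with exactly two single-letter allele
#' states; genotypes are labeled by joining one letter per locus in locus
#' order (e.g. `"KME"` for K219 / M239 / E403). Accepts either named
#' two-letter vectors (`landscape_loci("219" = c("K","S"))`) or compact
#' strings (`landscape_loci("219:K/S", "239:M/I")`).
#'
#' @param ... Locus definitions (see above). Multi-allelic positions are out
#'   of scope here; they are handled at the codon and alignment level.
#' @return A data.frame of class `landscape_loci` with columns `name`,
#'   `allele1`, `allele2`.
#' @export
landscape_loci <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1]]) && is.null(names(args)) &&
      all(grepl(":", args[[1]])))
    args <- as.list(args[[1]])
  parse_one <- function(x, nm) {
    if (is.character(x) && length(x) == 1L && grepl(":", x)) {
      parts <- strsplit(x, "[:/]")[[1]]
      if (length(parts) != 3L)
        stop(sprintf("cannot parse locus spec '%s' (want 'name:A/B')", x))
      return(c(parts[1], toupper(parts[2]), toupper(parts[3])))
    }
    if (is.null(nm) || !nzchar(nm))
      stop("allele-vector locus definitions must be named")
    if (length(x) != 2L)
      stop(sprintf("locus '%s' must have exactly two alleles", nm))
    c(nm, toupper(as.character(x[1])), toupper(as.character(x[2])))
  }
  nms <- names(args)
  rows <- lapply(seq_along(args), function(i)
    parse_one(args[[i]], if (is.null(nms)) NULL else nms[i]))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("name", "allele1", "allele2")
  if (any(nchar(df$allele1) != 1L) || any(nchar(df$allele2) != 1L))
    stop("alleles must be single letters")
  if (any(df$allele1 == df$allele2))
    stop("the two alleles of a locus must be distinct")
  if (anyDuplicated(df$name))
    stop("locus names must be unique")
  class(df) <- c("landscape_loci", "data.frame")
  df
}

.split_label <- function(label) strsplit(label, "")[[1]]

.check_label <- function(states, loci) {
  if (length(states) != nrow(loci))
    stop(sprintf("genotype label '%s' has %d letters but there are %d loci",
                 paste0(states, collapse = ""), length(states), nrow(loci)))
  for (i in seq_len(nrow(loci))) {
    if (!(states[i] %in% c(loci$allele1[i], loci$allele2[i])))
      stop(sprintf("allele '%s' is not valid at locus %s (alleles %s/%s)",
                   states[i], loci$name[i], loci$allele1[i], loci$allele2[i]))
  }
  invisible(states)
}

#' All genotype labels of a locus set
#'
#' @param loci A [landscape_loci()] definition.
#' @return Character vector of the 2^L genotype labels, sorted.
#' @export
all_genotype_labels <- function(loci) {
  alleles <- lapply(seq_len(nrow(loci)),
                    function(i) c(loci$allele1[i], loci$allele2[i]))
  grid <- do.call(expand.grid, c(alleles, stringsAsFactors = FALSE))
  sort(do.call(paste0, grid))
}

#' Build a multi-locus genotype-fitness landscape
#'
#' Maps genotype labels to growth-rate fitness W (min^-1); W = 0 encodes
#' "no growth"/non-viable. The landscape is marked complete when all 2^L
#' genotypes are present; path operations require completeness.
#'
#' @param fitness Either a named numeric vector (names = genotype labels)
#'   or a data.frame with columns `genotype_label`, `fitness` and optional
#'   `sd` (per-genotype replicate standard deviation).
#' @param loci A [landscape_loci()] definition.
#' @param sd Optional named numeric vector of replicate SDs (ignored when
#'   `fitness` is a data.frame carrying its own `sd` column).
#' @return An object of class `fitness_landscape` with fields `loci`,
#'   `fitness`, `sd`, `complete`.
#' @examples
#' loci <- landscape_loci("219:K/S", "239:M/I", "403:E/D")
#' land <- make_landscape_preset("pgk219")
#' land$complete
#' @export
build_landscape <- function(fitness, loci, sd = NULL) {
  if (!inherits(loci, "landscape_loci"))
    stop("`loci` must come from landscape_loci()")
  if (is.data.frame(fitness)) {
    if (!all(c("genotype_label", "fitness") %in% names(fitness)))
      stop("data.frame input needs columns `genotype_label` and `fitness`")
    if ("sd" %in% names(fitness))
      sd <- stats::setNames(as.numeric(fitness$sd), fitness$genotype_label)
    fitness <- stats::setNames(as.numeric(fitness$fitness),
                               fitness$genotype_label)
  }
  if (is.null(names(fitness)) || any(!nzchar(names(fitness))))
    stop("`fitness` must be named by genotype labels")
  if (anyDuplicated(names(fitness)))
    stop("duplicate genotype labels in fitness table")
  if (any(!is.finite(fitness)) || any(fitness < 0))
    stop("fitness values must be finite and >= 0 (0 encodes no growth)")
  for (lab in names(fitness)) .check_label(.split_label(lab), loci)
  labs <- all_genotype_labels(loci)
  complete <- setequal(names(fitness), labs)
  ordered <- fitness[intersect(labs, names(fitness))]
  if (!is.null(sd)) sd <- sd[names(ordered)]
  structure(
    list(loci = loci, fitness = ordered, sd = sd, complete = complete),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("<fitness_landscape> %d loci (%s), %d/%d genotypes%s\n",
              nrow(x$loci), paste(x$loci$name, collapse = ", "),
              length(x$fitness), 2^nrow(x$loci),
              if (x$complete) ", complete" else ", INCOMPLETE"))
  print(x$fitness)
  invisible(x)
}

#' Read a genotype-fitness table
#'
#' TSV with columns `genotype_label`, `fitness` and optional `sd`.
#'
#' @param path File path.
#' @param loci A [landscape_loci()] definition.
#' @return A [build_landscape()] result.
#' @export
read_landscape_table <- function(path, loci) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  build_landscape(df, loci)
}

.landscape_w <- function(land, label) {
  w <- land$fitness[label]
  if (anyNA(w))
    stop(sprintf("genotype(s) missing from landscape: %s",
                 paste(label[is.na(w)], collapse = ", ")))
  unname(w)
}

# lexicographic permutations of an integer vector (ascending input =>
# lexicographic output); used for deterministic path ordering
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- .perms(v[-i])
    for (p in rest) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Enumerate all direct mutational trajectories between two genotypes
#'
#' All shortest paths from `start` to `end` on the genotype hypercube, each
#' step flipping exactly one of the d differing loci; there are d! such
#' paths, returned in deterministic lexicographic order of the locus-flip
#' order. Paths with back-mutations are not enumerated.
#'
#' @param landscape A complete [build_landscape()] object.
#' @param start,end Genotype labels (must differ).
#' @return A list of character vectors (genotype label sequences of length
#'   d + 1), of class `genotype_paths`.
#' @examples
#' enumerate_direct_paths(make_landscape_preset("pgk219"), "KME", "SID")
#' @export
enumerate_direct_paths <- function(landscape, start, end) {
  if (!inherits(landscape, "fitness_landscape"))
    stop("`landscape` must be a fitness_landscape")
  if (!landscape$complete)
    stop("landscape is incomplete; path enumeration needs all 2^L genotypes")
  s <- .check_label(.split_label(start), landscape$loci)
  e <- .check_label(.split_label(end), landscape$loci)
  diff_loci <- which(s != e)
  if (length(diff_loci) == 0L)
    stop("`start` and `end` are the same genotype")
  paths <- lapply(.perms(diff_loci), function(ord) {
    g <- s
    out <- character(length(ord) + 1L)
    out[1] <- start
    for (k in seq_along(ord)) {
      g[ord[k]] <- e[ord[k]]
      out[k + 1L] <- paste0(g, collapse = "")
    }
    out
  })
  structure(paths, class = "genotype_paths", start = start, end = end)
}

#' @export
print.genotype_paths <- function(x, ...) {
  cat(sprintf("<genotype_paths> %s -> %s: %d direct paths\n",
              attr(x, "start"), attr(x, "end"), length(x)))
  for (p in x) cat(" ", paste(p, collapse = " > "), "\n")
  invisible(x)
}

#' Accessibility of direct mutational trajectories under selection
#'
#' Classifies every direct path from `start` to `end` as accessible or not.
#' In `"threshold"` mode a path is accessible iff every genotype after the
#' start (all intermediates and the endpoint) has fitness W >= `theta` —
#' the start is the currently viable state and is not tested. In
#' `"monotonic"` mode a path is accessible iff W is non-decreasing along
#' it. The first failing genotype of each rejected path is reported.
#'
#' @param landscape A complete [build_landscape()] object.
#' @param start,end Genotype labels.
#' @param mode `"threshold"` or `"monotonic"`.
#' @param theta Minimum viable fitness (min^-1) for threshold mode;
#'   must be non-negative.
#' @return An object of class `accessible_paths`: list with `paths`
#'   (the [enumerate_direct_paths()] result), `verdicts` (data.frame with
#'   `path_id`, `path`, `accessible`, `first_fail`), `n_accessible`,
#'   `mode`, `theta`.
#' @examples
#' land <- make_landscape_preset("pgk219")
#' accessible_paths(land, "KME", "SID", theta = 0.0125)$n_accessible # 1
#' @export
accessible_paths <- function(landscape, start, end,
                             mode = c("threshold", "monotonic"), theta = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("`theta` must be a single non-negative number")
  paths <- enumerate_direct_paths(landscape, start, end)
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    w <- .landscape_w(landscape, p)
    if (mode == "threshold") {
      bad <- which(w[-1] < theta) + 1L
    } else {
      bad <- which(diff(w) < 0) + 1L
    }
    data.frame(path_id = i,
               path = paste(p, collapse = ">"),
               accessible = length(bad) == 0L,
               first_fail = if (length(bad)) p[min(bad)] else NA_character_,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  structure(
    list(paths = paths, verdicts = verdicts,
         n_accessible = sum(verdicts$accessible),
         mode = mode, theta = theta),
    class = "accessible_paths"
  )
}

#' @export
print.accessible_paths <- function(x, ...) {
  cat(sprintf("<accessible_paths> mode %s, theta %.4g: %d of %d paths accessible\n",
              x$mode, x$theta, x$n_accessible, nrow(x$verdicts)))
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

.background_genotype <- function(loci, focal_idx, background) {
  other <- loci$name[-focal_idx]
  if (!setequal(names(background), other))
    stop(sprintf("`background` must fix exactly the non-focal loci: %s",
                 paste(other, collapse = ", ")))
  states <- character(nrow(loci))
  for (i in seq_len(nrow(loci)))
    if (!(i %in% focal_idx)) states[i] <- toupper(background[[loci$name[i]]])
  states
}

#' Background-conditional effect of a single locus
#'
#' Fitness difference W(allele2) - W(allele1) at the focal locus, with all
#' other loci fixed to `background`. The fold-ratio W2/W1 is reported when
#' both fitnesses are positive, and flagged undefined otherwise.
#'
#' @param landscape A [build_landscape()] object.
#' @param locus Focal locus name.
#' @param background Named character vector fixing every other locus.
#' @return List of class `locus_effect`: `delta`, `fold` (or `NA`),
#'   `genotypes`, `fitness`.
#' @export
locus_effect <- function(landscape, locus, background) {
  loci <- landscape$loci
  idx <- match(locus, loci$name)
  if (is.na(idx)) stop(sprintf("unknown locus '%s'", locus))
  states <- .background_genotype(loci, idx, background)
  g1 <- states; g1[idx] <- loci$allele1[idx]
  g2 <- states; g2[idx] <- loci$allele2[idx]
  l1 <- paste0(g1, collapse = ""); l2 <- paste0(g2, collapse = "")
  w1 <- .landscape_w(landscape, l1); w2 <- .landscape_w(landscape, l2)
  structure(
    list(delta = w2 - w1,
         fold = if (w1 > 0 && w2 > 0) w2 / w1 else NA_real_,
         fold_undefined = !(w1 > 0 && w2 > 0),
         genotypes = c(l1, l2), fitness = c(w1, w2), locus = locus),
    class = "locus_effect"
  )
}

#' Classify pairwise epistasis between two loci
#'
#' On the additive growth-rate scale (default), the interaction is
#' epsilon = W(AB) - W(Ab) - W(aB) + W(ab), where lowercase denotes each
#' locus's first allele and the remaining loci are fixed to `background`.
#' Classification follows the standard scheme: `additive` when
#' |epsilon| <= `zero_tol`; otherwise `sign` when exactly one locus's
#' background-conditional effect changes sign across the other's
#' backgrounds, `reciprocal_sign` when both do, and `magnitude` otherwise.
#' Effects with absolute value <= `zero_tol` are treated as zero.
#'
#' A multiplicative (log) scale is available via `scale = "log"`; zero
#' fitness (no growth) is excluded from log-scale analysis.
#'
#' @param landscape A [build_landscape()] object.
#' @param locusA,locusB Names of the two focal loci.
#' @param background Named character vector fixing all remaining loci
#'   (omit for a 2-locus landscape).
#' @param zero_tol Tolerance below which a fitness difference counts as
#'   zero. Defaults to the largest replicate SD among the four genotypes
#'   when the landscape carries SDs, else 0.
#' @param scale `"additive"` (growth rate) or `"log"` (natural log rate).
#' @return An object of class `epistasis_call`: `classification`,
#'   `epsilon`, `focal_effects` (background-conditional effects of each
#'   locus), `genotypes`, `fitness`, `scale`, `zero_tol`.
#' @examples
#' loci <- landscape_loci("p1:A/B", "p2:C/D")
#' land <- build_landscape(c(AC = 2, BC = 1, AD = 1, BD = 2), loci)
#' classify_pairwise_epistasis(land, "p1", "p2")$classification # reciprocal_sign
#' @export
classify_pairwise_epistasis <- function(landscape, locusA, locusB,
                                        background = NULL, zero_tol = NULL,
                                        scale = c("additive", "log")) {
  scale <- match.arg(scale)
  loci <- landscape$loci
  ia <- match(locusA, loci$name); ib <- match(locusB, loci$name)
  if (is.na(ia) || is.na(ib)) stop("unknown locus name")
  if (ia == ib) stop("`locusA` and `locusB` must differ")
  if (is.null(background)) background <- stats::setNames(character(0), character(0))
  states <- .background_genotype(loci, c(ia, ib), background)
  lab <- function(sa, sb) {
    g <- states; g[ia] <- sa; g[ib] <- sb
    paste0(g, collapse = "")
  }
  g_ab <- lab(loci$allele1[ia], loci$allele1[ib])
  g_Ab <- lab(loci$allele2[ia], loci$allele1[ib])
  g_aB <- lab(loci$allele1[ia], loci$allele2[ib])
  g_AB <- lab(loci$allele2[ia], loci$allele2[ib])
  labs <- c(ab = g_ab, Ab = g_Ab, aB = g_aB, AB = g_AB)
  w <- .landscape_w(landscape, labs)
  names(w) <- names(labs)
  if (is.null(zero_tol)) {
    zero_tol <- 0
    if (!is.null(landscape$sd)) {
      sds <- landscape$sd[labs]
      if (!all(is.na(sds))) zero_tol <- max(sds, na.rm = TRUE)
    }
  }
  f <- w
  if (scale == "log") {
    if (any(w <= 0))
      stop("zero fitness is excluded from log-scale epistasis analysis")
    f <- log(w)
  }
  eps <- f[["AB"]] - f[["Ab"]] - f[["aB"]] + f[["ab"]]
  clip <- function(x) if (abs(x) <= zero_tol) 0 else x
  eA <- c(on_b = clip(f[["Ab"]] - f[["ab"]]), on_B = clip(f[["AB"]] - f[["aB"]]))
  eB <- c(on_a = clip(f[["aB"]] - f[["ab"]]), on_A = clip(f[["AB"]] - f[["Ab"]]))
  flipA <- eA[1] * eA[2] < 0
  flipB <- eB[1] * eB[2] < 0
  classification <-
    if (abs(eps) <= zero_tol) "additive"
    else if (flipA && flipB) "reciprocal_sign"
    else if (flipA || flipB) "sign"
    else "magnitude"
  structure(
    list(classification = classification,
         epsilon = unname(eps),
         focal_effects = list(A = eA, B = eB),
         genotypes = labs, fitness = w,
         scale = scale, zero_tol = zero_tol,
         loci = c(locusA, locusB)),
    class = "epistasis_call"
  )
}

#' @export
print.epistasis_call <- function(x, ...) {
  cat(sprintf("<epistasis_call> %s x %s: %s (epsilon = %.4g, %s scale, tol %.3g)\n",
              x$loci[1], x$loci[2], x$classification, x$epsilon, x$scale,
              x$zero_tol))
  invisible(x)
}

#' Epistasis calls for every locus pair and background
#'
#' Runs [classify_pairwise_epistasis()] for all locus pairs of a complete
#' landscape across all backgrounds of the remaining loci.
#'
#' @inheritParams classify_pairwise_epistasis
#' @return A data.frame with one row per (pair, background) combination.
#' @export
epistasis_table <- function(landscape, zero_tol = NULL,
                            scale = c("additive", "log")) {
  scale <- match.arg(scale)
  if (!landscape$complete) stop("epistasis_table needs a complete landscape")
  loci <- landscape$loci
  L <- nrow(loci)
  rows <- list()
  for (ia in seq_len(L - 1)) for (ib in (ia + 1):L) {
    other <- setdiff(seq_len(L), c(ia, ib))
    bgs <- if (length(other)) {
      alleles <- lapply(other, function(i) c(loci$allele1[i], loci$allele2[i]))
      grid <- do.call(expand.grid, c(alleles, stringsAsFactors = FALSE))
      lapply(seq_len(nrow(grid)), function(r)
        stats::setNames(as.character(grid[r, ]), loci$name[other]))
    } else list(NULL)
    for (bg in bgs) {
      call <- classify_pairwise_epistasis(landscape, loci$name[ia],
                                          loci$name[ib], background = bg,
                                          zero_tol = zero_tol, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        locusA = loci$name[ia], locusB = loci$name[ib],
        background = if (is.null(bg)) "" else paste0(bg, collapse = ""),
        classification = call$classification, epsilon = call$epsilon,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
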