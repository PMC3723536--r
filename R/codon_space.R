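#' The standard genetic code
#'
#' Named character vector mapping the 64 DNA codons (T alphabet, uppercase)
#' to one-letter amino acids, with `"*"` for stop; taken from
#' `Biostrings::GENETIC_CODE`.
#'
#' @return Named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
}

#' Load an alternative genetic code from a codon-table file
#'
#' TSV with two columns, `codon` and `amino_acid` (one-letter, `*` for
#' stop). The table must cover all 64 codons and all 20 amino acids plus
#' stop.
#'
#' @param path File path.
#' @return Named character vector (codon -> amino acid).
#' @export
read_genetic_code <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "amino_acid") %in% names(df)))
    stop("codon table needs columns `codon` and `amino_acid`")
  code <- stats::setNames(toupper(df$amino_acid),
                          chartr("U", "T", toupper(df$codon)))
  .validate_code(code)
  code
}

.validate_code <- function(code) {
  if (length(code) != 64L || anyDuplicated(names(code)))
    stop("a genetic code must assign exactly the 64 codons")
  if (!all(grepl("^[ACGT]{3}$", names(code))))
    stop("codons must be 3-letter DNA strings (A/C/G/T)")
  aas <- setdiff(unique(code), "*")
  if (length(aas) != 20L || !("*" %in% code))
    stop("a genetic code must encode 20 amino acids and stop")
  invisible(code)
}

# normalize an amino-acid argument to one-letter uppercase;
# accepts one-letter or three-letter (Lys, Ser, ...) codes
.aa1 <- function(aa, allow_stop = FALSE) {
  aa <- as.character(aa)
  if (length(aa) != 1L) stop("one amino acid at a time")
  if (nchar(aa) == 3L) {
    three <- Biostrings::AMINO_ACID_CODE # names: one-letter
    hit <- names(three)[tolower(three) == tolower(aa)]
    if (length(hit) == 1L) return(hit)
    stop(sprintf("unknown three-letter amino-acid code '%s'", aa))
  }
  aa <- toupper(aa)
  if (aa == "*") {
    if (allow_stop) return(aa)
    stop("stop is not a valid amino acid here")
  }
  if (!(aa %in% names(Biostrings::AMINO_ACID_CODE)) ||
      !(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    stop(sprintf("'%s' is not a standard amino acid", aa))
  aa
}

.codons_for <- function(aa, code) names(code)[code == aa]

# Hamming distance between two 3-letter codons
.codon_dist <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

# pairwise Hamming distances between two codon sets, via position matrices
.codon_dist_matrix <- function(codons1, codons2) {
  m1 <- do.call(rbind, strsplit(codons1, ""))
  m2 <- do.call(rbind, strsplit(codons2, ""))
  out <- matrix(0L, nrow = length(codons1), ncol = length(codons2),
                dimnames = list(codons1, codons2))
  for (p in 1:3)
    out <- out + outer(m1[, p], m2[, p], "!=")
  out
}

#' Expand a degenerate (IUPAC) codon
#'
#' Expands a 3-symbol IUPAC nucleotide pattern (e.g. `"NNS"`, the
#' saturation-mutagenesis library design covering all 20 amino acids with
#' a single stop codon) into its concrete codons, and tallies the encoded
#' amino acids and stop codons under the given genetic code.
#'
#' @param pattern 3 IUPAC nucleotide symbols (U is accepted and read as T).
#' @param code Genetic code (default [standard_genetic_code()]).
#' @return An object of class `degenerate_expansion`: `pattern`, `codons`,
#'   `amino_acid_counts` (table, stops excluded), `stop_count`, `n_codons`.
#' @examples
#' ex <- expand_degenerate("NNS")
#' ex$n_codons    # 32
#' ex$stop_count  # 1
#' @export
expand_degenerate <- function(pattern, code = standard_genetic_code()) {
  .validate_code(code)
  pattern <- chartr("U", "T", toupper(as.character(pattern)))
  if (nchar(pattern) != 3L) stop("a codon pattern has exactly 3 symbols")
  syms <- strsplit(pattern, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(syms, names(map))
  if (length(bad))
    stop(sprintf("non-IUPAC nucleotide symbol(s): %s",
                 paste(bad, collapse = ", ")))
  sets <- strsplit(unname(map[syms]), "")
  codons <- character(0)
  for (n1 in sets[[1]]) for (n2 in sets[[2]]) for (n3 in sets[[3]])
    codons <- c(codons, paste0(n1, n2, n3))
  aas <- code[codons]
  structure(
    list(pattern = pattern,
         codons = codons,
         amino_acid_counts = table(factor(aas[aas != "*"])),
         stop_count = sum(aas == "*"),
         n_codons = length(codons)),
    class = "degenerate_expansion"
  )
}

#' @export
print.degenerate_expansion <- function(x, ...) {
  cat(sprintf("<degenerate_expansion> %s: %d codons, %d amino acids, %d stop codon(s)\n",
              x$pattern, x$n_codons, length(x$amino_acid_counts), x$stop_count))
  print(x$amino_acid_counts)
  invisible(x)
}

#' Minimum nucleotide distance between two amino acids
#'
#' Minimum Hamming distance over all codon pairs of the two amino acids
#' (0..3). A value of 2 for lysine/serine is why that exchange cannot occur
#' by a single nucleotide substitution.
#'
#' @param aaA,aaB Amino acids (one- or three-letter codes; stop rejected).
#' @param code Genetic code.
#' @return Integer in 0..3.
#' @examples
#' min_nucleotide_distance("Lys", "Ser") # 2
#' @export
min_nucleotide_distance <- function(aaA, aaB, code = standard_genetic_code()) {
  .validate_code(code)
  a <- .aa1(aaA); b <- .aa1(aaB)
  d <- .codon_dist_matrix(.codons_for(a, code), .codons_for(b, code))
  as.integer(min(d))
}

#' Minimum nucleotide distance from a codon to an amino acid
#'
#' Minimum Hamming distance from a concrete sense codon to any codon of
#' the target amino acid. The TCT serine codon, for instance, needs all
#' three bases changed to encode lysine — the anti-reversion rationale of
#' designing a library around TCT.
#'
#' @param codon Concrete sense codon (DNA, U accepted).
#' @param aa Target amino acid.
#' @param code Genetic code.
#' @return Integer in 0..3.
#' @examples
#' codon_to_amino_distance("TCT", "Lys") # 3
#' @export
codon_to_amino_distance <- function(codon, aa, code = standard_genetic_code()) {
  .validate_code(code)
  codon <- chartr("U", "T", toupper(as.character(codon)))
  if (!(codon %in% names(code)))
    stop(sprintf("'%s' is not a valid codon", codon))
  if (code[[codon]] == "*")
    stop("input codon is a stop codon, not a sense codon")
  a <- .aa1(aa)
  d <- .codon_dist_matrix(codon, .codons_for(a, code))
  as.integer(min(d))
}

#' Bridging amino acids between two amino acids
#'
#' An amino acid Z bridges A and B when Z has a sense codon one nucleotide
#' substitution away from some codon of A and one substitution away from
#' some codon of B, enabling a two-step codon path A -> Z -> B. For
#' lysine/serine the bridges are arginine, threonine and asparagine. Every
#' witness path (cA -> cZ -> cB) is reported. Stop codons may not serve as
#' intermediates unless `include_stop_intermediates = TRUE` (a non-
#' biological relaxation for analysis). Pairs that are already one
#' substitution apart still report their bridges, with `direct_adjacent`
#' set.
#'
#' @param aaA,aaB Distinct amino acids.
#' @param code Genetic code.
#' @param include_stop_intermediates Allow stop codons as intermediates.
#' @return An object of class `bridge_report`: `amino_pair`,
#'   `intermediates` (sorted one-letter codes), `witness_paths`
#'   (data.frame `from_codon`, `via_codon`, `to_codon`, `intermediate`),
#'   `direct_adjacent`.
#' @examples
#' bridging_amino_acids("Lys", "Ser")$intermediates # "N" "R" "T"
#' @export
bridging_amino_acids <- function(aaA, aaB, code = standard_genetic_code(),
                                 include_stop_intermediates = FALSE) {
  .validate_code(code)
  a <- .aa1(aaA); b <- .aa1(aaB)
  if (a == b) {
    warning("identical amino acids: no bridging intermediates by convention")
    return(structure(
      list(amino_pair = c(a, b), intermediates = character(0),
           witness_paths = data.frame(from_codon = character(0),
                                      via_codon = character(0),
                                      to_codon = character(0),
                                      intermediate = character(0),
                                      stringsAsFactors = FALSE),
           direct_adjacent = NA),
      class = "bridge_report"))
  }
  ca <- .codons_for(a, code)
  cb <- .codons_for(b, code)
  cand_aas <- setdiff(unique(code), c(a, b))
  if (!include_stop_intermediates) cand_aas <- setdiff(cand_aas, "*")
  paths <- list()
  for (z in cand_aas) {
    cz <- .codons_for(z, code)
    da <- .codon_dist_matrix(cz, ca)
    db <- .codon_dist_matrix(cz, cb)
    for (i in seq_along(cz)) {
      froms <- ca[da[i, ] == 1L]
      tos <- cb[db[i, ] == 1L]
      if (length(froms) && length(tos)) {
        grid <- expand.grid(from_codon = froms, to_codon = tos,
                            stringsAsFactors = FALSE)
        grid$via_codon <- cz[i]
        grid$intermediate <- z
        paths[[length(paths) + 1L]] <- grid[, c("from_codon", "via_codon",
                                                "to_codon", "intermediate")]
      }
    }
  }
  witness <- if (length(paths)) do.call(rbind, paths) else
    data.frame(from_codon = character(0), via_codon = character(0),
               to_codon = character(0), intermediate = character(0),
               stringsAsFactors = FALSE)
  witness <- witness[order(witness$intermediate, witness$via_codon,
                           witness$from_codon, witness$to_codon), ]
  rownames(witness) <- NULL
  structure(
    list(amino_pair = c(a, b),
         intermediates = sort(unique(witness$intermediate)),
         witness_paths = witness,
         direct_adjacent = min_nucleotide_distance(a, b, code) == 1L),
    class = "bridge_report"
  )
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("<bridge_report> %s <-> %s: intermediates {%s}%s, %d witness paths\n",
              x$amino_pair[1], x$amino_pair[2],
              paste(x$intermediates, collapse = ", "),
              if (isTRUE(x$direct_adjacent)) " [directly adjacent]" else "",
              nrow(x$witness_paths)))
  invisible(x)
}
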