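.GAP_CHARS <- c("-", ".")

#' Clade-labeled protein multiple sequence alignment
#'
#' Equal-length gapped amino-acid sequences with a per-sequence clade label
#' (e.g. bacteria / eukaryota / archaea) and a designated reference
#' sequence used for residue numbering. Residue numbers are 1-based over
#' the non-gap residues of the reference (the human-PGK convention);
#' alignment columns are 0-based in every output.
#'
#' @param sequences Named character vector of aligned sequences, or a
#'   `Biostrings::AAStringSet`.
#' @param clade Named character vector of clade labels covering every
#'   sequence id.
#' @param reference_id Id of the reference sequence (must have at least one
#'   non-gap residue).
#' @return An object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(sequences, clade, reference_id) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence ids")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("all sequences must have the same aligned length")
  ids <- names(sequences)
  if (!all(ids %in% names(clade)))
    stop("`clade` must label every sequence id")
  if (!(reference_id %in% ids))
    stop(sprintf("reference id '%s' not found in alignment", reference_id))
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- ids
  if (all(mat[reference_id, ] %in% .GAP_CHARS))
    stop("reference sequence has no non-gap residues")
  structure(
    list(sequences = sequences,
         clade = as.character(clade[ids]) |> stats::setNames(ids),
         reference_id = reference_id,
         mat = mat),
    class = "labeled_alignment"
  )
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("<labeled_alignment> %d sequences x %d columns, reference '%s'\n",
              nrow(x$mat), ncol(x$mat), x$reference_id))
  print(table(x$clade))
  invisible(x)
}

#' Read an aligned FASTA plus a clade-label sidecar table
#'
#' Clade labels come from a sidecar TSV (columns `id`, `clade`) rather
#' than from FASTA headers, whose formats vary.
#'
#' @param fasta_path Aligned protein FASTA.
#' @param labels_path TSV with columns `id` and `clade`.
#' @param reference_id Reference sequence id for residue numbering.
#' @return A [labeled_alignment()].
#' @export
read_labeled_alignment <- function(fasta_path, labels_path, reference_id) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "clade") %in% names(lab)))
    stop("labels table needs columns `id` and `clade`")
  labeled_alignment(seqs, stats::setNames(lab$clade, lab$id), reference_id)
}

#' Write a labeled alignment as FASTA + labels TSV
#'
#' @param aln A [labeled_alignment()].
#' @param fasta_path,labels_path Output paths.
#' @return `aln`, invisibly.
#' @export
write_labeled_alignment <- function(aln, fasta_path, labels_path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$sequences),
                              fasta_path)
  utils::write.table(
    data.frame(id = names(aln$clade), clade = unname(aln$clade)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(aln)
}

#' Map a reference residue number to an alignment column
#'
#' `ref_pos` is 1-based over the non-gap residues of the reference
#' sequence; the returned column index is 0-based.
#'
#' @param aln A [labeled_alignment()].
#' @param ref_pos 1-based residue index on the reference.
#' @return 0-based alignment column (integer).
#' @export
ref_position_to_column <- function(aln, ref_pos) {
  ref <- aln$mat[aln$reference_id, ]
  nongap <- which(!(ref %in% .GAP_CHARS))
  if (!is.numeric(ref_pos) || length(ref_pos) != 1L ||
      ref_pos < 1 || ref_pos > length(nongap) || ref_pos != round(ref_pos))
    stop(sprintf("reference position must be an integer in 1..%d",
                 length(nongap)))
  as.integer(nongap[ref_pos] - 1L)
}

#' Map a 0-based alignment column back to a reference residue number
#'
#' Inverse of [ref_position_to_column()]; errors when the reference is
#' gapped at that column.
#'
#' @param aln A [labeled_alignment()].
#' @param column 0-based alignment column.
#' @return 1-based reference residue index (integer).
#' @export
column_to_ref_position <- function(aln, column) {
  ref <- aln$mat[aln$reference_id, ]
  if (!is.numeric(column) || length(column) != 1L ||
      column < 0 || column >= length(ref) || column != round(column))
    stop(sprintf("column must be an integer in 0..%d", length(ref) - 1L))
  if (ref[column + 1L] %in% .GAP_CHARS)
    stop("reference is gapped at this column; no residue number exists")
  as.integer(sum(!(ref[seq_len(column + 1L)] %in% .GAP_CHARS)))
}

#' Per-clade amino-acid composition of an alignment column
#'
#' Counts every residue (gaps as their own `"gap"` category) at the column
#' mapped from a reference residue number, split by clade.
#'
#' @param aln A [labeled_alignment()].
#' @param ref_pos 1-based reference residue index.
#' @return An object of class `column_profile`: `ref_position`, `column`
#'   (0-based), `counts` (clade x residue contingency table), `totals`
#'   (per-clade sequence counts).
#' @export
column_composition <- function(aln, ref_pos) {
  col0 <- ref_position_to_column(aln, ref_pos)
  res <- aln$mat[, col0 + 1L]
  res[res %in% .GAP_CHARS] <- "gap"
  structure(
    list(ref_position = as.integer(ref_pos),
         column = col0,
         counts = table(clade = aln$clade, residue = res),
         totals = table(aln$clade)),
    class = "column_profile"
  )
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> reference position %d (0-based column %d)\n",
              x$ref_position, x$column))
  print(x$counts)
  invisible(x)
}

#' Association between states at two alignment positions
#'
#' 2x2 contingency of (stateA at posA) x (stateB at posB) over sequences
#' that are non-gapped at both columns, plus the conditional fraction
#' P(stateB at posB | stateA at posA) — the statistic behind observations
#' such as "535/547 lysine-219 carriers have glutamate at 403".
#'
#' @param aln A [labeled_alignment()].
#' @param posA,posB 1-based reference residue indices.
#' @param stateA,stateB Residues whose co-occurrence is tabulated.
#' @return An object of class `association_table`: `counts` (2x2),
#'   `conditional`, `n_stateA`, `n_total`, `undefined` (no stateA
#'   carriers), `positions`, `states`.
#' @export
position_association <- function(aln, posA, stateA, posB, stateB) {
  colA <- ref_position_to_column(aln, posA) + 1L
  colB <- ref_position_to_column(aln, posB) + 1L
  a_col <- aln$mat[, colA]
  b_col <- aln$mat[, colB]
  keep <- !(a_col %in% .GAP_CHARS) & !(b_col %in% .GAP_CHARS)
  a <- a_col[keep] == toupper(stateA)
  b <- b_col[keep] == toupper(stateB)
  counts <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(stateA = c("yes", "no"),
                                   stateB = c("yes", "no")))
  nA <- sum(a)
  structure(
    list(counts = counts,
         conditional = if (nA > 0) sum(a & b) / nA else NA_real_,
         n_stateA = nA,
         n_total = sum(keep),
         undefined = nA == 0,
         positions = c(posA = posA, posB = posB),
         states = c(stateA = toupper(stateA), stateB = toupper(stateB))),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %s@%d x %s@%d over %d co-aligned sequences\n",
              x$states[1], x$positions[1], x$states[2], x$positions[2],
              x$n_total))
  print(x$counts)
  if (x$undefined) cat("conditional: undefined (no stateA carriers)\n")
  else cat(sprintf("P(%s@%d | %s@%d) = %d/%d = %.4f\n",
                   x$states[2], x$positions[2], x$states[1], x$positions[1],
                   x$counts[1, 1], x$n_stateA, x$conditional))
  invisible(x)
}

#' Percent identity between two aligned sequences
#'
#' Matching non-gap positions divided by the chosen denominator, times
#' 100. The default `"mutual"` denominator counts only columns where both
#' sequences are non-gapped; `"alignment"` uses the full alignment length
#' and `"shorter"` the shorter ungapped sequence length. Ambiguity codes
#' (X, B, Z) form their own category and never count as matches.
#'
#' @param aln A [labeled_alignment()].
#' @param idA,idB Sequence ids.
#' @param denominator One of `"mutual"`, `"alignment"`, `"shorter"`.
#' @return Percent identity (numeric); `NA` with a warning when the
#'   denominator is zero (no co-aligned columns).
#' @export
pairwise_identity <- function(aln, idA, idB,
                              denominator = c("mutual", "alignment",
                                              "shorter")) {
  denominator <- match.arg(denominator)
  for (id in c(idA, idB))
    if (!(id %in% rownames(aln$mat)))
      stop(sprintf("sequence id '%s' not found", id))
  x <- aln$mat[idA, ]
  y <- aln$mat[idB, ]
  gx <- x %in% .GAP_CHARS
  gy <- y %in% .GAP_CHARS
  co <- !gx & !gy
  matches <- co & (x == y) & !(x %in% c("X", "B", "Z"))
  den <- switch(denominator,
                mutual = sum(co),
                alignment = length(x),
                shorter = min(sum(!gx), sum(!gy)))
  if (den == 0) {
    warning("no co-aligned columns; identity undefined")
    return(NA_real_)
  }
  100 * sum(matches) / den
}

#' Overlap between an observed and a natural tolerated amino-acid set
#'
#' Exact set algebra between the amino acids tolerated at a position in a
#' selection experiment and those observed in natural sequences:
#' intersection, each side's exclusives, and the Jaccard index.
#'
#' @param observed,natural Non-empty character vectors of amino acids.
#' @param notes Optional free-text annotations carried in the report.
#' @return An object of class `set_overlap`: `intersection`,
#'   `observed_only`, `natural_only`, `jaccard`, `notes`.
#' @export
tolerated_set_overlap <- function(observed, natural, notes = NULL) {
  if (length(observed) == 0L || length(natural) == 0L)
    stop("both sets must be non-empty")
  observed <- unique(toupper(observed))
  natural <- unique(toupper(natural))
  inter <- sort(intersect(observed, natural))
  un <- union(observed, natural)
  structure(
    list(intersection = inter,
         observed_only = sort(setdiff(observed, natural)),
         natural_only = sort(setdiff(natural, observed)),
         jaccard = length(inter) / length(un),
         notes = notes),
    class = "set_overlap"
  )
}

#' @export
print.set_overlap <- function(x, ...) {
  cat(sprintf("<set_overlap> shared {%s}; observed-only {%s}; natural-only {%s}; Jaccard %.3f\n",
              paste(x$intersection, collapse = ","),
              paste(x$observed_only, collapse = ","),
              paste(x$natural_only, collapse = ","), x$jaccard))
  if (!is.null(x$notes)) cat("notes:", x$notes, "\n")
  invisible(x)
}
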