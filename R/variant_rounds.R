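#' Parse a variant-round table
#'
#' Reads a TSV of evolved clones: one row per variant with its selection
#' round, substitution list, paired Ser-219/Lys-219 doubling times
#' (minutes; `ND` = no growth) and optional catalytic efficiencies
#' (mM^-1 s^-1). Substitutions are semicolon-separated `M239I`-style
#' tokens; an optional parallel `frequencies` column carries the printed
#' per-round occurrence of each substitution as a fraction, or
#' `singleton` for mutations seen only once.
#'
#' Expected columns: `variant_id`, `substitutions`, and optionally
#' `round` (parsed from a `G<round>-` id prefix when absent),
#' `frequencies`, `growth_doubling_ser`, `growth_doubling_lys`,
#' `efficiency_ser`, `efficiency_lys`.
#'
#' @param path Path to the TSV.
#' @return An object of class `variant_table`: list with `records` (one
#'   row per variant: `variant_id`, `round`, doubling times as numeric
#'   with `nd_ser`/`nd_lys` no-growth flags, efficiencies) and
#'   `substitutions` (long table: `variant_id`, `ref`, `pos`, `alt`,
#'   `substitution`, `printed_freq`, `singleton`).
#' @examples
#' vt <- parse_variant_table(
#'   system.file("extdata", "table1_variants.tsv", package = "pgkevo"))
#' nrow(vt$records) # 6
#' @export
parse_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = character(0))
  if (nrow(df) == 0L || !("variant_id" %in% names(df))) {
    if (!("variant_id" %in% names(df)))
      stop("variant table needs a `variant_id` column")
    return(.empty_variant_table())
  }
  get_col <- function(nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_character_, nrow(df))
  rounds <- get_col("round")
  parse_round <- function(id, r) {
    if (!is.na(r) && nzchar(r)) return(as.integer(r))
    m <- regmatches(id, regexec("^G([0-9]+)-", id))[[1]]
    if (length(m) == 2L) return(as.integer(m[2]))
    0L # wild type / unannotated baseline
  }
  nd <- function(x) !is.na(x) & toupper(trimws(x)) == "ND"
  num <- function(x) suppressWarnings(as.numeric(ifelse(nd(x) | !nzchar(trimws(x)),
                                                        NA, x)))
  records <- data.frame(
    variant_id = df$variant_id,
    round = mapply(parse_round, df$variant_id, rounds, USE.NAMES = FALSE),
    growth_doubling_ser = num(get_col("growth_doubling_ser")),
    nd_ser = nd(get_col("growth_doubling_ser")),
    growth_doubling_lys = num(get_col("growth_doubling_lys")),
    nd_lys = nd(get_col("growth_doubling_lys")),
    efficiency_ser = num(get_col("efficiency_ser")),
    efficiency_lys = num(get_col("efficiency_lys")),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  subs_rows <- list()
  freqs_col <- get_col("frequencies")
  for (i in seq_len(nrow(df))) {
    raw <- df$substitutions[i]
    toks <- if (is.na(raw)) character(0) else
      Filter(nzchar, strsplit(gsub("\\s", "", raw), ";")[[1]])
    if (length(toks) == 0L) next
    ftoks <- if (!is.na(freqs_col[i]) && nzchar(freqs_col[i]))
      Filter(nzchar, strsplit(gsub("\\s", "", freqs_col[i]), ";")[[1]]) else
      rep(NA_character_, length(toks))
    if (length(ftoks) != length(toks))
      stop(sprintf("row %d: %d substitutions but %d frequency entries",
                   i, length(toks), length(ftoks)))
    for (k in seq_along(toks)) {
      m <- regmatches(toks[k], regexec("^([A-Z])([0-9]+)([A-Z])$", toks[k]))[[1]]
      if (length(m) != 4L)
        stop(sprintf("malformed substitution '%s' in row %d", toks[k], i))
      pos <- as.integer(m[3])
      if (pos < 1L)
        stop(sprintf("non-positive position in substitution '%s' (row %d)",
                     toks[k], i))
      singleton <- !is.na(ftoks[k]) && tolower(ftoks[k]) == "singleton"
      pf <- if (singleton || is.na(ftoks[k])) NA_real_ else
        suppressWarnings(as.numeric(ftoks[k]))
      subs_rows[[length(subs_rows) + 1L]] <- data.frame(
        variant_id = df$variant_id[i], ref = m[2], pos = pos, alt = m[4],
        substitution = toks[k], printed_freq = pf, singleton = singleton,
        stringsAsFactors = FALSE)
    }
  }
  subs <- if (length(subs_rows)) do.call(rbind, subs_rows) else
    .empty_substitutions()
  structure(list(records = records, substitutions = subs),
            class = "variant_table")
}

.empty_substitutions <- function() {
  data.frame(variant_id = character(0), ref = character(0),
             pos = integer(0), alt = character(0),
             substitution = character(0), printed_freq = numeric(0),
             singleton = logical(0), stringsAsFactors = FALSE)
}

.empty_variant_table <- function() {
  structure(list(
    records = data.frame(variant_id = character(0), round = integer(0),
                         growth_doubling_ser = numeric(0), nd_ser = logical(0),
                         growth_doubling_lys = numeric(0), nd_lys = logical(0),
                         efficiency_ser = numeric(0),
                         efficiency_lys = numeric(0), stringsAsFactors = FALSE),
    substitutions = .empty_substitutions()),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants, %d substitution annotations, rounds %s\n",
              nrow(x$records), nrow(x$substitutions),
              paste(sort(unique(x$records$round)), collapse = ",")))
  invisible(x)
}

#' Serialize a variant table back to TSV
#'
#' Inverse of [parse_variant_table()] (parse -> write -> parse is the
#' identity on the packaged fixtures).
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `vt`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  rec <- vt$records
  fmt_growth <- function(v, ndflag) ifelse(ndflag, "ND",
                                           ifelse(is.na(v), "", format(v)))
  sub_str <- function(id) {
    s <- vt$substitutions[vt$substitutions$variant_id == id, ]
    paste(s$substitution, collapse = ";")
  }
  freq_str <- function(id) {
    s <- vt$substitutions[vt$substitutions$variant_id == id, ]
    if (nrow(s) == 0L) return("")
    paste(ifelse(s$singleton, "singleton",
                 ifelse(is.na(s$printed_freq), "", format(s$printed_freq))),
          collapse = ";")
  }
  out <- data.frame(
    variant_id = rec$variant_id,
    round = rec$round,
    substitutions = vapply(rec$variant_id, sub_str, ""),
    frequencies = vapply(rec$variant_id, freq_str, ""),
    growth_doubling_ser = fmt_growth(rec$growth_doubling_ser, rec$nd_ser),
    growth_doubling_lys = fmt_growth(rec$growth_doubling_lys, rec$nd_lys),
    efficiency_ser = ifelse(is.na(rec$efficiency_ser), "",
                            format(rec$efficiency_ser)),
    efficiency_lys = ifelse(is.na(rec$efficiency_lys), "",
                            format(rec$efficiency_lys)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vt)
}

#' Per-round substitution frequencies
#'
#' For tables carrying printed per-round percentages (the representative-
#' variant annotation style), those printed values are reported as the
#' round's frequencies; otherwise frequencies are computed as the fraction
#' of the round's variants carrying each substitution.
#'
#' @param vt A `variant_table`.
#' @param round Selection round (integer present in the table).
#' @return An object of class `round_summary`: `round`, `n_variants`,
#'   `freq` (data.frame `substitution`, `frequency`, `singleton`).
#' @export
mutation_frequencies <- function(vt, round) {
  rec <- vt$records[vt$records$round == round, ]
  if (nrow(rec) == 0L)
    stop(sprintf("no variants in round %s", round))
  subs <- vt$substitutions[vt$substitutions$variant_id %in% rec$variant_id, ]
  has_printed <- any(!is.na(subs$printed_freq)) || any(subs$singleton)
  if (has_printed) {
    keep <- !duplicated(subs$substitution)
    freq <- data.frame(substitution = subs$substitution[keep],
                       frequency = subs$printed_freq[keep],
                       singleton = subs$singleton[keep],
                       stringsAsFactors = FALSE)
  } else {
    all_subs <- sort(unique(subs$substitution))
    carrier_frac <- vapply(all_subs, function(s) {
      carriers <- unique(subs$variant_id[subs$substitution == s])
      length(carriers) / nrow(rec)
    }, numeric(1))
    n_carriers <- vapply(all_subs, function(s)
      length(unique(subs$variant_id[subs$substitution == s])), integer(1))
    freq <- data.frame(substitution = all_subs,
                       frequency = unname(carrier_frac),
                       singleton = n_carriers == 1L,
                       stringsAsFactors = FALSE)
  }
  rownames(freq) <- NULL
  structure(list(round = round, n_variants = nrow(rec), freq = freq),
            class = "round_summary")
}

#' @export
print.round_summary <- function(x, ...) {
  cat(sprintf("<round_summary> round %s, %d variants\n", x$round,
              x$n_variants))
  print(x$freq, row.names = FALSE)
  invisible(x)
}

#' Substitutions at or above a fixation threshold
#'
#' The near-complete-fixation criterion: substitutions whose per-round
#' frequency is at least `threshold` (default 0.90). Singleton-marked
#' substitutions (no printed frequency) are never called fixed.
#'
#' @param summary A [mutation_frequencies()] result.
#' @param threshold Fraction in (0, 1].
#' @return Sorted character vector of fixed substitutions.
#' @examples
#' vt <- parse_variant_table(
#'   system.file("extdata", "table1_variants.tsv", package = "pgkevo"))
#' fixed_mutations(mutation_frequencies(vt, 7)) # E403D, M239I
#' @export
fixed_mutations <- function(summary, threshold = 0.90) {
  if (!inherits(summary, "round_summary"))
    stop("`summary` must come from mutation_frequencies()")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  f <- summary$freq
  sort(f$substitution[!is.na(f$frequency) & f$frequency >= threshold])
}

#' Paired Ser-219 / Lys-219 growth trend across rounds
#'
#' Converts the paired doubling times of every variant to growth rates
#' (no growth = rate 0, via [rate_from_doubling()]), tabulates the
#' Ser/Lys rate ratio, and summarizes monotonicity of each series with
#' round as a Kendall rank correlation.
#'
#' @param vt A `variant_table` with growth values.
#' @return An object of class `trajectory_trend`: `table` (per-variant
#'   `round`, `ser_rate`, `lys_rate`, `ratio`), `kendall_ser`,
#'   `kendall_lys`.
#' @export
trajectory_trend <- function(vt) {
  rec <- vt$records
  conv <- function(doubling, ndflag)
    ifelse(!ndflag & is.na(doubling), NA_real_,
           rate_from_doubling(ifelse(ndflag, NA, doubling)))
  tab <- data.frame(
    variant_id = rec$variant_id,
    round = rec$round,
    ser_rate = conv(rec$growth_doubling_ser, rec$nd_ser),
    lys_rate = conv(rec$growth_doubling_lys, rec$nd_lys),
    stringsAsFactors = FALSE)
  tab$ratio <- ifelse(tab$lys_rate > 0, tab$ser_rate / tab$lys_rate, NA_real_)
  tau <- function(y) {
    ok <- !is.na(y) & !is.na(tab$round)
    if (sum(ok) < 2L || stats::sd(y[ok]) == 0 || stats::sd(tab$round[ok]) == 0)
      return(NA_real_)
    suppressWarnings(stats::cor(tab$round[ok], y[ok], method = "kendall"))
  }
  structure(
    list(table = tab,
         kendall_ser = tau(tab$ser_rate),
         kendall_lys = tau(tab$lys_rate)),
    class = "trajectory_trend"
  )
}

#' @export
print.trajectory_trend <- function(x, ...) {
  cat(sprintf("<trajectory_trend> %d variants; Kendall tau (Ser rate vs round) = %.3f, (Lys) = %.3f\n",
              nrow(x$table), x$kendall_ser, x$kendall_lys))
  print(x$table, row.names = FALSE)
  invisible(x)
}
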