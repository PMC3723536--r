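#' Plate-reader growth curve for a single well
#'
#' Container for one well's OD600 time series. Times are minutes since
#' inoculation and must be strictly increasing; readings must be positive.
#' An optional `blank` (media-only optical density) is stored and subtracted
#' at estimation time, not here, so the raw readings remain inspectable.
#'
#' @param time_min Numeric vector of measurement times, in minutes, strictly
#'   increasing.
#' @param od600 Numeric vector of OD600 readings, positive, same length as
#'   `time_min`.
#' @param well_id Character label for the well.
#' @param blank Optical-density offset to subtract before log transformation
#'   (default 0).
#' @return An object of class `growth_curve`.
#' @seealso [estimate_growth_rate()], [simulate_growth_curve()]
#' @examples
#' t <- seq(0, 720, by = 20)
#' gc <- growth_curve(t, 0.02 * 2^(t / 63.8), well_id = "A1")
#' estimate_growth_rate(gc)
#' @export
growth_curve <- function(time_min, od600, well_id = "well", blank = 0) {
  if (!is.numeric(time_min) || !is.numeric(od600))
    stop("`time_min` and `od600` must be numeric")
  if (length(time_min) != length(od600))
    stop("`time_min` and `od600` must have the same length")
  if (length(time_min) < 2L)
    stop("a growth curve needs at least 2 points")
  if (anyNA(time_min) || anyNA(od600) ||
      any(!is.finite(time_min)) || any(!is.finite(od600)))
    stop("growth curve contains non-finite values")
  if (any(diff(time_min) <= 0))
    stop("`time_min` must be strictly increasing")
  if (any(od600 <= 0))
    stop("`od600` readings must be positive")
  if (!is.numeric(blank) || length(blank) != 1L || blank < 0)
    stop("`blank` must be a single non-negative number")
  structure(
    list(time_min = as.numeric(time_min), od600 = as.numeric(od600),
         well_id = as.character(well_id), blank = as.numeric(blank)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well '%s': %d points, t = %g..%g min, OD = %.3g..%.3g\n",
              x$well_id, length(x$time_min), min(x$time_min), max(x$time_min),
              min(x$od600), max(x$od600)))
  invisible(x)
}

# OLS slope without the lm() overhead; x and y are equal-length numerics.
.ols_slope <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Estimate the exponential growth rate of a plate-reader curve
#'
#' Sliding-window estimator used for selection-plate growth phenotyping:
#' log2(OD600 - blank) is regressed on time (ordinary least squares) in every
#' window of span `window_min` minutes that starts at a retained data point
#' and contains at least 3 points; the mean of the `top_k` largest window
#' slopes is reported as the growth rate (in log2-OD units per minute, so
#' its reciprocal is the doubling time in minutes). Points that are
#' non-positive after blank subtraction are dropped before windowing. Ties
#' among slopes are broken by earliest window start, for determinism.
#'
#' A curve whose best windows have a non-positive slope yields a typed
#' "no growth" result (`rate = 0`, undefined doubling time), not an error,
#' so that non-viable genotypes can be encoded as fitness 0 downstream.
#'
#' @param curve A [growth_curve()].
#' @param window_min Window span in minutes (default 120, i.e. 7 points at
#'   the standard 20-min sampling interval).
#' @param top_k Number of largest window slopes to average (default 3).
#' @return An object of class `growth_rate_estimate` with fields `rate`
#'   (min^-1, log2 scale), `doubling_time_min` (`1/rate`, `NA` for no
#'   growth), `window_slopes`, `window_starts`, `top_k_used`, `no_growth`
#'   and `well_id`.
#' @examples
#' t <- seq(0, 720, by = 20)
#' est <- estimate_growth_rate(growth_curve(t, 0.02 * 2^(t / 63.8)))
#' est$doubling_time_min # 63.8
#' @export
estimate_growth_rate <- function(curve, window_min = 120, top_k = 3) {
  if (!inherits(curve, "growth_curve"))
    stop("`curve` must be a growth_curve")
  if (!is.numeric(window_min) || length(window_min) != 1L || window_min <= 0)
    stop("`window_min` must be a single positive number")
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("`top_k` must be a positive integer")
  od <- curve$od600 - curve$blank
  keep <- od > 0
  tt <- curve$time_min[keep]
  yy <- log2(od[keep])
  if (length(tt) < 3L)
    stop("too few usable points after blank subtraction (need >= 3)")
  n <- length(tt)
  slopes <- numeric(0)
  starts <- numeric(0)
  for (i in seq_len(n)) {
    # a window must span the full window_min inside the sampled range;
    # its points are those with time in [t_i, t_i + window], contiguous
    if (tt[i] + window_min > tt[n] + 1e-9) break
    upper <- findInterval(tt[i] + window_min + 1e-9, tt)
    if (upper - i + 1L < 3L) next
    j <- i:upper
    slopes <- c(slopes, .ols_slope(tt[j], yy[j]))
    starts <- c(starts, tt[i])
  }
  if (length(slopes) == 0L)
    stop("no window of span `window_min` contains >= 3 points")
  ord <- order(-slopes, starts)
  k <- min(as.integer(top_k), length(slopes))
  rate_raw <- mean(slopes[ord[seq_len(k)]])
  no_growth <- !(rate_raw > 0)
  structure(
    list(rate = if (no_growth) 0 else rate_raw,
         doubling_time_min = if (no_growth) NA_real_ else 1 / rate_raw,
         window_slopes = slopes,
         window_starts = starts,
         top_k_used = k,
         no_growth = no_growth,
         well_id = curve$well_id),
    class = "growth_rate_estimate"
  )
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  if (x$no_growth) {
    cat(sprintf("<growth_rate_estimate> well '%s': no growth (%d windows)\n",
                x$well_id, length(x$window_slopes)))
  } else {
    cat(sprintf(
      "<growth_rate_estimate> well '%s': rate %.5g min^-1, doubling %.4g min (top %d of %d windows)\n",
      x$well_id, x$rate, x$doubling_time_min, x$top_k_used,
      length(x$window_slopes)))
  }
  invisible(x)
}

#' Growth rate relative to a reference strain
#'
#' Ratio of two estimated growth rates (e.g. a variant against wild type),
#' the normalization used when comparing strains as the inverse of the
#' shortest doubling time. A "no growth" estimate yields 0.
#'
#' @param estimate,reference [estimate_growth_rate()] results; the reference
#'   must show growth.
#' @return A single number, `estimate$rate / reference$rate`.
#' @export
relative_growth_rate <- function(estimate, reference) {
  if (!inherits(estimate, "growth_rate_estimate") ||
      !inherits(reference, "growth_rate_estimate"))
    stop("both arguments must be growth_rate_estimate objects")
  if (reference$no_growth || reference$rate <= 0)
    stop("reference shows no growth; relative rate undefined")
  if (estimate$no_growth) return(0)
  estimate$rate / reference$rate
}

#' Convert between doubling time and growth rate
#'
#' Single source of truth for the reciprocal relation used throughout the
#' package: rate (log2-OD per minute) = 1 / doubling time (minutes).
#' `NA` doubling times (no growth) convert to rate 0; rate 0 converts to
#' `NA` doubling time.
#'
#' @param doubling_min Doubling time(s) in minutes.
#' @param rate Growth rate(s) in min^-1.
#' @return Numeric vector.
#' @export
rate_from_doubling <- function(doubling_min) {
  out <- ifelse(is.na(doubling_min), 0, 1 / doubling_min)
  as.numeric(out)
}

#' @rdname rate_from_doubling
#' @export
doubling_from_rate <- function(rate) {
  out <- ifelse(is.na(rate) | rate <= 0, NA_real_, 1 / rate)
  as.numeric(out)
}

#' Initial-rate series for catalytic-efficiency estimation
#'
#' Michaelis-Menten initial rates v0 measured at low substrate
#' concentrations, in the linear regime where v0 ~ (kcat/KM) [E]0 [S]0.
#'
#' @param substrate_conc Initial substrate concentrations `[S]0`, mM,
#'   non-negative.
#' @param initial_rate Initial rates v0, mM s^-1, non-negative, same length.
#' @param enzyme_conc Enzyme concentration `[E]0`, mM, positive scalar.
#' @return An object of class `initial_rate_series`.
#' @export
initial_rate_series <- function(substrate_conc, initial_rate, enzyme_conc) {
  if (!is.numeric(substrate_conc) || !is.numeric(initial_rate))
    stop("`substrate_conc` and `initial_rate` must be numeric")
  if (length(substrate_conc) != length(initial_rate))
    stop("`substrate_conc` and `initial_rate` must have the same length")
  if (any(substrate_conc < 0) || any(initial_rate < 0))
    stop("concentrations and rates must be non-negative")
  if (!is.numeric(enzyme_conc) || length(enzyme_conc) != 1L ||
      enzyme_conc <= 0)
    stop("`enzyme_conc` must be a single positive number")
  structure(
    list(substrate_conc = as.numeric(substrate_conc),
         initial_rate = as.numeric(initial_rate),
         enzyme_conc = as.numeric(enzyme_conc)),
    class = "initial_rate_series"
  )
}

#' Catalytic efficiency (kcat/KM) from linear-regime initial rates
#'
#' Fits v0 = slope * `[S]0` through the origin by least squares (v0 = 0 at
#' `[S]0` = 0 is physically forced) and returns slope / `[E]0`, the
#' catalytic efficiency in mM^-1 s^-1. A negative fitted slope is flagged
#' rather than silently returned.
#'
#' @param series An [initial_rate_series()] with at least two distinct
#'   substrate concentrations.
#' @return An object of class `catalytic_efficiency` with fields
#'   `efficiency` (mM^-1 s^-1), `slope` (s^-1), `enzyme_conc` and
#'   `negative_slope`.
#' @examples
#' s <- c(0.05, 0.1, 0.2, 0.4)
#' catalytic_efficiency(initial_rate_series(s, 5.496e-3 * s, 8e-6))
#' @export
catalytic_efficiency <- function(series) {
  if (!inherits(series, "initial_rate_series"))
    stop("`series` must be an initial_rate_series")
  s <- series$substrate_conc
  v <- series$initial_rate
  if (length(unique(s[s > 0])) < 2L && length(unique(s)) < 2L)
    stop("need >= 2 distinct substrate concentrations")
  denom <- sum(s * s)
  if (denom == 0)
    stop("all substrate concentrations are zero")
  slope <- sum(s * v) / denom
  structure(
    list(efficiency = slope / series$enzyme_conc,
         slope = slope,
         enzyme_conc = series$enzyme_conc,
         negative_slope = slope < 0),
    class = "catalytic_efficiency"
  )
}

#' @export
print.catalytic_efficiency <- function(x, ...) {
  cat(sprintf("<catalytic_efficiency> kcat/KM = %.4g mM^-1 s^-1 (slope %.4g s^-1, [E]0 %.3g mM)%s\n",
              x$efficiency, x$slope, x$enzyme_conc,
              if (x$negative_slope) " [negative slope]" else ""))
  invisible(x)
}

#' Read a plate-reader table into growth curves
#'
#' Accepts either wide format (first column `time_min`, one column per
#' well) or long format (columns `well`, `time_min`, `od600`). Separator
#' is inferred from the file extension (`.csv` comma, otherwise tab).
#'
#' @param path Path to a TSV/CSV file.
#' @param blank Blank OD passed to every [growth_curve()].
#' @return A named list of `growth_curve` objects.
#' @export
read_plate <- function(path, blank = 0) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("well", "time_min", "od600") %in% names(df))) {
    out <- lapply(split(df, df$well), function(d) {
      d <- d[order(d$time_min), ]
      growth_curve(d$time_min, d$od600, well_id = d$well[1], blank = blank)
    })
    return(out[order(names(out))])
  }
  if (names(df)[1] != "time_min")
    stop("wide plate tables must have `time_min` as their first column")
  wells <- names(df)[-1]
  out <- lapply(wells, function(w)
    growth_curve(df$time_min, df[[w]], well_id = w, blank = blank))
  names(out) <- wells
  out
}

#' Estimate growth rates for every well of a plate table
#'
#' Convenience wrapper around [read_plate()] and [estimate_growth_rate()].
#'
#' @inheritParams read_plate
#' @inheritParams estimate_growth_rate
#' @param out Optional path; when given, the summary table is written as TSV.
#' @return A data.frame with columns `well_id`, `rate_per_min`,
#'   `doubling_time_min`, `n_windows`, `flag` (`"ok"` or `"no_growth"`).
#' @export
estimate_plate <- function(path, window_min = 120, top_k = 3, blank = 0,
                           out = NULL) {
  curves <- read_plate(path, blank = blank)
  rows <- lapply(curves, function(cv) {
    est <- estimate_growth_rate(cv, window_min = window_min, top_k = top_k)
    data.frame(well_id = est$well_id,
               rate_per_min = est$rate,
               doubling_time_min = est$doubling_time_min,
               n_windows = length(est$window_slopes),
               flag = if (est$no_growth) "no_growth" else "ok",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
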