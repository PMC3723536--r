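# Seeded generators for growth curves, fitness landscapes, clade-structured
# alignments and directed-evolution round simulations. All are
# bit-reproducible given a seed (withr::with_seed scopes the RNG state).

.with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a plate-reader growth curve
#'
#' Lag / exponential / saturating OD600 trajectory sampled at fixed
#' intervals from a standard inoculation density, with optional
#' multiplicative log-normal noise (plate readers err multiplicatively).
#' The deterministic kernel is flat at `initial_od` during the lag, then
#' logistic with the prescribed doubling time and carrying capacity
#' (`carrying_capacity_od = Inf` gives a pure exponential, which the
#' estimator recovers exactly).
#'
#' @param doubling_time_min Exponential-phase doubling time, minutes.
#' @param duration_min Total duration, minutes (default 720).
#' @param lag_min Lag duration, minutes (default 0).
#' @param initial_od Inoculation OD600 (default 0.02).
#' @param carrying_capacity_od Saturation OD (default 1.5; `Inf` for pure
#'   exponential growth).
#' @param noise_sd Log-scale SD of multiplicative noise (default 0).
#' @param additive_noise_sd SD of additive OD noise (default 0; the
#'   multiplicative model is the realistic one).
#' @param sample_interval_min Sampling interval, minutes (default 20).
#' @param seed Optional integer seed; identical seeds give identical
#'   curves.
#' @param well_id Label for the simulated well.
#' @return A [growth_curve()].
#' @examples
#' gc <- simulate_growth_curve(63.8, carrying_capacity_od = Inf)
#' estimate_growth_rate(gc)$doubling_time_min # 63.8
#' @export
simulate_growth_curve <- function(doubling_time_min, duration_min = 720,
                                  lag_min = 0, initial_od = 0.02,
                                  carrying_capacity_od = 1.5,
                                  noise_sd = 0, additive_noise_sd = 0,
                                  sample_interval_min = 20, seed = NULL,
                                  well_id = "sim") {
  stopifnot(doubling_time_min > 0, duration_min > 0, lag_min >= 0,
            initial_od > 0, carrying_capacity_od > initial_od,
            noise_sd >= 0, additive_noise_sd >= 0, sample_interval_min > 0)
  if (duration_min < 120)
    warning("duration shorter than one 2-h regression window")
  t <- seq(0, duration_min, by = sample_interval_min)
  te <- pmax(0, t - lag_min)
  mu <- log(2) / doubling_time_min
  od <- if (is.finite(carrying_capacity_od)) {
    K <- carrying_capacity_od
    K / (1 + (K / initial_od - 1) * exp(-mu * te))
  } else {
    initial_od * exp(mu * te)
  }
  od <- .with_opt_seed(seed, {
    out <- od
    if (noise_sd > 0)
      out <- out * exp(stats::rnorm(length(out), 0, noise_sd))
    if (additive_noise_sd > 0)
      out <- pmax(out + stats::rnorm(length(out), 0, additive_noise_sd),
                  .Machine$double.eps)
    out
  })
  growth_curve(t, od, well_id = well_id)
}

#' Packaged fitness-landscape presets
#'
#' `"pgk219"` is a complete 3-locus hypercube over positions 219 (K/S),
#' 239 (M/I) and 403 (E/D), shaped after the PGK lysine/serine divergence
#' system. Three values are literature-anchored: the wild-type KME rate
#' (0.0156 min^-1), the non-viable K219S genotype SME (0), and the
#' triple-exchange genotype SID (0.0130 min^-1). The remaining five values
#' (KIE = 0.0115, KMD = 0.0145, SIE = 0.0074, SMD = 0.0074, KID = 0.0126)
#' are synthetic, chosen so that the qualitative accessibility pattern of
#' the system is reproduced: no direct K-to-S route survives wild-type-level
#' selection, exactly one route (403, then 239, then 219) survives a
#' 0.0125 min^-1 threshold, and four routes survive weak selection. This
#' preset must not be presented as measured data; the per-genotype
#' `synthetic` flag records which members are invented.
#'
#' @param name Preset name; currently only `"pgk219"`.
#' @return A complete [build_landscape()] object with extra fields
#'   `preset`, `synthetic` (named logical: TRUE where the value is
#'   invented rather than anchored).
#' @export
make_landscape_preset <- function(name = "pgk219") {
  name <- match.arg(name)
  loci <- landscape_loci("219:K/S", "239:M/I", "403:E/D")
  fitness <- c(KME = 0.0156, KMD = 0.0145, KIE = 0.0115, KID = 0.0126,
               SME = 0,      SMD = 0.0074, SIE = 0.0074, SID = 0.0130)
  land <- build_landscape(fitness, loci)
  land$preset <- name
  land$synthetic <- stats::setNames(
    !(names(land$fitness) %in% c("KME", "SME", "SID")), names(land$fitness))
  land
}

# largest-remainder apportionment of n items to probabilities p
.apportion <- function(p, n) {
  q <- p * n
  base <- floor(q)
  need <- n - sum(base)
  if (need > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Simulate a clade-structured labeled alignment
#'
#' Generates an alignment whose specified columns have prescribed
#' per-clade residue compositions, optionally with one coupled column pair
#' of prescribed conditional association. An ungapped reference sequence
#' (all `background` residues) is appended under clade `"reference"`, so
#' reference residue number p maps to 1-based alignment column p (0-based
#' column p - 1).
#'
#' In `"deterministic"` mode column counts follow the distribution exactly
#' (largest-remainder apportionment); in `"stochastic"` mode residues are
#' sampled, matching the distribution in expectation.
#'
#' @param clades Named integer vector of clade sizes.
#' @param n_columns Alignment length.
#' @param columns List of column specs, each a list with `pos` (1-based
#'   column), `dist` (named list: clade -> named probability vector
#'   summing to 1), and optional `mode` (`"deterministic"` default, or
#'   `"stochastic"`).
#' @param coupled Optional coupled-pair spec: list with `posA`, `stateA`,
#'   `posB`, `stateB`, `conditional` (target P(stateB at posB | stateA at
#'   posA)), optional `else_state` (default `background`) and `mode`.
#'   The coupled pair owns column `posB`.
#' @param background Fill residue for unspecified cells (default "A").
#' @param reference_id Id of the appended reference row (default "REF").
#' @param seed Optional integer seed.
#' @return A [labeled_alignment()].
#' @export
simulate_alignment <- function(clades, n_columns, columns = list(),
                               coupled = NULL, background = "A",
                               reference_id = "REF", seed = NULL) {
  stopifnot(length(clades) >= 1, all(clades >= 1), n_columns >= 1)
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("`clades` must be a named vector of sizes")
  .with_opt_seed(seed, {
    ids <- unlist(lapply(names(clades), function(cl)
      sprintf("%s_%03d", cl, seq_len(clades[[cl]]))))
    clade_of <- stats::setNames(
      rep(names(clades), times = unname(clades)), ids)
    mat <- matrix(background, nrow = length(ids), ncol = n_columns,
                  dimnames = list(ids, NULL))
    for (spec in columns) {
      pos <- spec$pos
      if (pos < 1 || pos > n_columns) stop("column spec out of range")
      mode <- if (is.null(spec$mode)) "deterministic" else spec$mode
      for (cl in names(spec$dist)) {
        p <- spec$dist[[cl]]
        if (abs(sum(p) - 1) > 1e-8)
          stop(sprintf("distribution for clade '%s' at column %d does not sum to 1",
                       cl, pos))
        rows <- which(clade_of == cl)
        res <- if (mode == "deterministic") {
          counts <- .apportion(p, length(rows))
          rep(names(counts), times = counts)
        } else {
          sample(names(p), length(rows), replace = TRUE, prob = p)
        }
        mat[rows, pos] <- res
      }
    }
    if (!is.null(coupled)) {
      mode <- if (is.null(coupled$mode)) "deterministic" else coupled$mode
      else_state <- if (is.null(coupled$else_state)) background else
        coupled$else_state
      carriers <- which(mat[, coupled$posA] == coupled$stateA)
      mat[, coupled$posB] <- else_state
      if (length(carriers)) {
        if (mode == "deterministic") {
          k <- round(coupled$conditional * length(carriers))
          mat[carriers[seq_len(k)], coupled$posB] <- coupled$stateB
        } else {
          hit <- stats::runif(length(carriers)) < coupled$conditional
          mat[carriers[hit], coupled$posB] <- coupled$stateB
        }
      }
    }
    seqs <- apply(mat, 1, paste0, collapse = "")
    seqs[reference_id] <- paste(rep(background, n_columns), collapse = "")
    clade_of[reference_id] <- "reference"
    labeled_alignment(seqs, clade_of, reference_id)
  })
}

#' Simulate rounds of mutagenesis and viability selection
#'
#' Emulates directed evolution over the biallelic loci of a fitness
#' landscape: each round every clone receives a Poisson(`lambda`) number
#' of uniformly chosen locus flips (the per-gene mutation load of
#' error-prone PCR), clones whose genotype fitness falls below the round's
#' viability threshold are removed (plate selection is grow/not-grow
#' truncation, not fitness-proportional reproduction; an optional
#' growth-rate-weighted resampling is provided), and survivors are
#' resampled with replacement back to the population size. Derived-allele
#' (second allele) frequencies are tallied per locus after each round.
#'
#' Extinction (no survivors) is a typed result, not an error.
#'
#' @param landscape A complete [build_landscape()] object; its loci are
#'   the mutable sites.
#' @param start Starting genotype label.
#' @param rounds Number of selection rounds (default 7).
#' @param population Clones per round (default 1000).
#' @param lambda Poisson mean mutations per gene per round (default 2.5).
#' @param viability_theta Minimum viable fitness; scalar, or one value per
#'   round for a selection ramp (default 0).
#' @param weight_by_fitness Resample survivors proportionally to growth
#'   rate instead of uniformly (default FALSE).
#' @param seed Optional integer seed.
#' @return An object of class `evo_sim`: `freq` (data.frame `round`,
#'   `substitution`, `frequency` of the derived allele after selection),
#'   `mean_mutations` (pre-selection mean flips per clone per round),
#'   `round_genotypes` (per-round genotype-label count tables after
#'   resampling), `extinct`, `extinct_round`, plus the simulation
#'   parameters.
#' @examples
#' sim <- simulate_directed_evolution(make_landscape_preset("pgk219"),
#'                                    "KME", rounds = 3, population = 200,
#'                                    seed = 1)
#' head(sim$freq)
#' @export
simulate_directed_evolution <- function(landscape, start, rounds = 7,
                                        population = 1000, lambda = 2.5,
                                        viability_theta = 0,
                                        weight_by_fitness = FALSE,
                                        seed = NULL) {
  if (!inherits(landscape, "fitness_landscape") || !landscape$complete)
    stop("`landscape` must be a complete fitness_landscape")
  stopifnot(rounds >= 1, population >= 1, lambda >= 0)
  loci <- landscape$loci
  L <- nrow(loci)
  .check_label(.split_label(start), loci)
  theta <- rep_len(viability_theta, rounds)
  sub_names <- paste0(loci$allele1, loci$name, loci$allele2)
  start_idx <- as.integer(
    .split_label(start) == loci$allele2) + 1L
  labels_of <- function(state) {
    # state: population x L matrix of allele indices (1 or 2)
    chars <- matrix("", nrow(state), L)
    for (j in seq_len(L))
      chars[, j] <- ifelse(state[, j] == 1L, loci$allele1[j], loci$allele2[j])
    do.call(paste0, asplit(chars, 2))
  }
  run_sim <- function() {
    state <- matrix(rep(start_idx, each = population), nrow = population)
    freq_rows <- list()
    mean_mut <- numeric(0)
    round_genotypes <- list()
    finish <- function(extinct, extinct_round) {
      structure(
        list(freq = if (length(freq_rows)) do.call(rbind, freq_rows) else
               NULL,
             mean_mutations = mean_mut,
             round_genotypes = round_genotypes,
             extinct = extinct, extinct_round = extinct_round,
             loci = loci, start = start, rounds = rounds,
             population = population, lambda = lambda, theta = theta),
        class = "evo_sim")
    }
    for (r in seq_len(rounds)) {
      k <- stats::rpois(population, lambda)
      mean_mut[r] <- mean(k)
      for (i in which(k > 0)) {
        for (j in sample.int(L, k[i], replace = TRUE))
          state[i, j] <- 3L - state[i, j]
      }
      w <- .landscape_w(landscape, labels_of(state))
      surv <- which(w >= theta[r])
      if (length(surv) == 0L)
        return(finish(TRUE, r))
      prob <- NULL
      if (weight_by_fitness && any(w[surv] > 0)) prob <- w[surv]
      idx <- surv[sample.int(length(surv), population, replace = TRUE,
                             prob = prob)]
      state <- state[idx, , drop = FALSE]
      derived <- colMeans(state == 2L)
      freq_rows[[r]] <- data.frame(round = r, substitution = sub_names,
                                   frequency = unname(derived),
                                   stringsAsFactors = FALSE)
      round_genotypes[[r]] <- table(labels_of(state))
    }
    finish(FALSE, NA_integer_)
  }
  .with_opt_seed(seed, run_sim())
}

#' @export
print.evo_sim <- function(x, ...) {
  if (x$extinct) {
    cat(sprintf("<evo_sim> EXTINCT at round %d (population %d, lambda %.2g)\n",
                x$extinct_round, x$population, x$lambda))
  } else {
    cat(sprintf("<evo_sim> %d rounds, population %d, lambda %.2g, start %s\n",
                x$rounds, x$population, x$lambda, x$start))
    last <- x$freq[x$freq$round == max(x$freq$round), ]
    cat("final derived-allele frequencies:\n")
    print(last, row.names = FALSE)
  }
  invisible(x)
}

#' Convert one simulated round into variant records
#'
#' Expands the genotype counts of a [simulate_directed_evolution()] round
#' into a `variant_table` (one record per clone, substitutions relative to
#' each locus's first allele), so that [mutation_frequencies()] can be
#' applied to simulated data exactly as to transcribed tables.
#'
#' @param sim An `evo_sim` result.
#' @param round Round number.
#' @return A `variant_table`.
#' @export
evo_round_records <- function(sim, round) {
  if (!inherits(sim, "evo_sim")) stop("`sim` must be an evo_sim")
  if (round < 1 || round > length(sim$round_genotypes))
    stop("round out of range")
  tab <- sim$round_genotypes[[round]]
  loci <- sim$loci
  sub_names <- paste0(loci$allele1, loci$name, loci$allele2)
  vt <- .empty_variant_table()
  recs <- list(); subs <- list()
  clone <- 0L
  for (lab in names(tab)) {
    states <- .split_label(lab)
    derived <- which(states == loci$allele2)
    for (n in seq_len(tab[[lab]])) {
      clone <- clone + 1L
      id <- sprintf("R%d-c%04d", round, clone)
      recs[[clone]] <- data.frame(
        variant_id = id, round = as.integer(round),
        growth_doubling_ser = NA_real_, nd_ser = FALSE,
        growth_doubling_lys = NA_real_, nd_lys = FALSE,
        efficiency_ser = NA_real_, efficiency_lys = NA_real_,
        stringsAsFactors = FALSE)
      if (length(derived))
        subs[[length(subs) + 1L]] <- data.frame(
          variant_id = id, ref = loci$allele1[derived],
          pos = suppressWarnings(as.integer(loci$name[derived])),
          alt = loci$allele2[derived],
          substitution = sub_names[derived],
          printed_freq = NA_real_, singleton = FALSE,
          stringsAsFactors = FALSE)
    }
  }
  vt$records <- do.call(rbind, recs)
  if (length(subs)) vt$substitutions <- do.call(rbind, subs)
  vt
}
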