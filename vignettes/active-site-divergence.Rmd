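---
title: "Quantifying divergence at an essential active-site position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying divergence at an essential active-site position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgkevo)
```

## The scientific problem

Phosphoglycerate kinase (PGK) carries a lysine at position 219 in every
known bacterial and eukaryotic sequence; archaeal PGKs instead carry
serine, threonine and a handful of other residues, and never lysine.
Swapping the residue in either direction in a contemporary sequence
abolishes function, yet the exchange evidently happened in the deep past.
`pgkevo` packages the quantitative machinery needed to study this kind of
divergence-and-incompatibility question: estimating growth-rate fitness
from plate-reader curves, building complete genotype-fitness hypercubes
and asking which mutational trajectories selection permits, classifying
pairwise epistasis, analysing the genetic code's single-substitution
network, profiling alignment columns by clade, and following substitution
frequencies across rounds of directed evolution. Seeded generators
emulate each data type so that the full pipeline runs, and is tested,
without any external download.

## Growth-rate estimation

Fitness here is a growth rate in min^-1 on the log2 scale, so that the
doubling time is exactly its reciprocal. The estimator mirrors the
selection-plate protocol: regress log2(OD600 − blank) on time by ordinary
least squares in every window of 2 hours (`window_min = 120`; 7 points at
the standard 20-minute sampling interval) that starts at a retained data
point, then average the 3 largest window slopes (`top_k = 3`).

Numerical choices worth stating:

* A window must span the full `window_min` inside the sampled range.
  Truncated windows at the end of a series contain as few as 3 points,
  carry roughly four times the slope noise, and would dominate the top-k
  selection for no biological reason.
* Points that are non-positive after blank subtraction are dropped before
  windowing; logs of non-positive values are undefined.
* Ties among window slopes break by earliest window start, so results are
  deterministic.
* A curve whose best windows have non-positive slope returns a typed
  "no growth" result (rate 0, doubling time undefined) rather than an
  error, because downstream landscape construction encodes non-viable
  genotypes as fitness 0.

```{r growth}
t <- seq(0, 720, by = 20)
est <- estimate_growth_rate(growth_curve(t, 0.02 * 2^(t / 63.8)))
c(rate = est$rate, doubling = est$doubling_time_min)
```

Because the top-k slopes are the largest order statistics of many
correlated window regressions, the estimator carries a small upward rate
bias under measurement noise. At a multiplicative log-normal noise SD of
0.02 per reading (a realistic plate-reader figure), the median recovered
doubling time over 200 simulated replicates sits about 2.5% below the
generating value. This is a property of any maximum-selection estimator,
is shared by the laboratory protocol the estimator reproduces, and should
be kept in mind when comparing absolute rates across instruments; rate
*ratios* between strains measured identically are unaffected to first
order.

Catalytic efficiency (kcat/KM) is estimated from the low-substrate linear
regime as the least-squares slope of initial rate versus substrate
concentration, forced through the origin (v0 must vanish at zero
substrate), divided by the enzyme concentration. Full Michaelis–Menten
fitting is deliberately out of scope: the enzyme's substrate-activation
kinetics make KM and kcat individually ill-defined, while the linear-regime
slope remains meaningful.

## Fitness landscapes and trajectory accessibility

A `fitness_landscape` maps all 2^L genotypes over L biallelic loci to
growth rates; W = 0 encodes no growth. `enumerate_direct_paths()` lists
all d! shortest trajectories between two genotypes (back-mutations are
not considered — the laboratory trajectories of interest are direct).
`accessible_paths()` offers two selection models, because "accessible"
is used in both senses in the literature:

* **threshold** — every genotype after the start must have W ≥ θ. The
  start is exempt: it is the currently viable state. θ is the minimum
  viable growth rate on the selection medium.
* **monotonic** — fitness must be non-decreasing along the path, the
  strong-selection weak-mutation reading.

The packaged `"pgk219"` preset is a 3-locus cube over positions 219
(K/S), 239 (M/I) and 403 (E/D). Three of its eight values are anchored to
published measurements (wild-type KME = 0.0156 min^-1; the non-viable
K219S genotype SME = 0; the triple exchange SID = 0.0130 min^-1); the
other five are **synthetic**, chosen once so the cube reproduces the
qualitative selection pattern of the system and flagged per-genotype in
`$synthetic`. The preset must not be mistaken for measured data.

```{r landscape}
land <- make_landscape_preset("pgk219")
vapply(c(weak = min(land$fitness[land$fitness > 0]) / 2,
         stringent = 0.0125, wildtype = 0.0156),
       function(th) accessible_paths(land, "KME", "SID",
                                     theta = th)$n_accessible,
       integer(1))
```

Under weak selection four routes survive (all that avoid the lethal SME
corner), a stringent 0.0125 min^-1 threshold leaves the single route that
changes 403 first, then 239, then 219, and wild-type-level selection
closes every route — a fitness landscape with two peaks separated by
valleys.

### Epistasis classification

For loci A and B on a fixed background, the interaction is computed on
the additive growth-rate scale, ε = W(AB) − W(Ab) − W(aB) + W(ab), and
classified by the standard sign-epistasis scheme: *additive* when
|ε| ≤ `zero_tol`; otherwise *sign* when exactly one locus's conditional
effect changes sign across the other's backgrounds, *reciprocal_sign*
when both do, and *magnitude* otherwise. Design choices:

* The additive rate scale is the default because near-additivity in this
  system is described on rates; a log (multiplicative) scale is available,
  with zero-fitness genotypes excluded there.
* `zero_tol` defaults to the largest replicate SD among the four genotypes
  when the landscape carries SDs, else 0 — a difference smaller than
  measurement error should not flip a classification.
* The classifier is symmetric in its two loci, and allele relabelling
  flips ε's sign without changing the class (both properties are tested).

On the quartet built from the measured wild-type and round-4-variant
doubling times, the 219 swap is deleterious on the wild-type background
and beneficial on the evolved one, and the background swap likewise
reverses sign, so the rule returns `reciprocal_sign` — the reciprocal
form of sign epistasis, matching the two-peak geometry above.

## Codon-network analytics

The genetic code and IUPAC degeneracy map come from Biostrings; the
analyses on top are exhaustive scans, cheap at 64 codons. Degenerate-codon
expansion reproduces the NNS saturation-library design (32 codons, all 20
amino acids, exactly one stop); `codon_to_amino_distance("TCT", "K") = 3`
is the anti-reversion rationale for building a serine library on TCT; and
`bridging_amino_acids()` finds every amino acid with a sense codon one
substitution from each of two others. Lysine and serine are two
substitutions apart, with arginine, threonine and asparagine as the only
bridges — the codon-level reason an intermediate residue must have
existed at position 219. Stop codons are excluded as intermediates by
default (a nonsense codon is not a viable protein), with a documented
flag to relax this for analysis.

## Alignment columns by clade

`labeled_alignment` keeps clade labels in a sidecar table rather than
parsing FASTA headers, whose formats vary. Residue numbering is 1-based
over the non-gap residues of the reference sequence (the human-PGK
convention); alignment columns are 0-based and labelled as such in every
output. Pairwise identity defaults to the mutual-coverage denominator
(columns where both sequences are non-gapped), with alignment-length and
shorter-sequence denominators available by flag since conventions differ;
ambiguity codes (X, B, Z) never count as matches. Association between two
columns is a 2×2 contingency over sequences non-gapped at both, plus the
conditional fraction; conditional probabilities are reported as exact
fractions, never re-rounded.

## Synthetic data: what it emulates and what it does not

Generators are seeded (`withr::with_seed`) and bit-reproducible; the RNG
is R's default Mersenne-Twister as recorded by the session.

* `simulate_growth_curve()` — lag, exponential and logistic-saturation
  phases from OD 0.02 sampled every 20 minutes, defaults matching the
  plate protocol (720 min duration; carrying capacity 1.5 OD, a typical
  96-well ceiling; `Inf` gives the pure exponential used for exactness
  tests). Noise is multiplicative log-normal (natural-log SD), the
  plate-reader error model; an additive option exists. It does not model
  diauxic shifts, condensation artefacts or well-edge effects, so passing
  tests say nothing about curves with those pathologies.
* `simulate_alignment()` — per-clade column compositions, deterministic
  (largest-remainder apportionment, exact counts) or stochastic (exact in
  expectation), plus one coupled column pair with a target conditional.
  It generates independent columns otherwise: no phylogenetic
  autocorrelation, so it cannot exercise tree-aware statistics.
* `simulate_directed_evolution()` — per round, Poisson(λ = 2.5 by
  default, the measured per-gene error-prone PCR load) uniform locus
  flips, viability truncation at θ (plate selection is grow/not-grow, not
  fitness-proportional; a growth-rate-weighted resampling option is
  provided), survivors resampled to constant population size. Extinction
  is a typed result. The mutation model is locus-level, not a
  nucleotide-level error-prone PCR spectrum, and round-2-style DNA
  shuffling is not modelled — the simulator exists to exercise the
  frequency/fixation analytics, not to re-create mutagenesis chemistry.

Simulation sizes used in the test suite (200-replicate noise studies,
populations of a few hundred over a handful of rounds, 100-seed
association studies) were chosen as the smallest designs whose Monte
Carlo error is well below the effects being tested.

## Variant-round tables

The packaged `table1_variants.tsv` fixture transcribes the
representative-variant table of the directed-evolution experiment: one
variant per round with its substitutions, printed per-round occurrence
percentages, and paired Ser-219/Lys-219 doubling times and efficiencies.
The printed percentages are stored as round-level frequencies as given —
they are not recomputed from the full set of sequenced clones, which is
not machine-readable. Substitutions seen only once carry a `singleton`
marker and are never called fixed. "ND" growth parses to the same
no-growth encoding (rate 0) used by the landscape module, and the
doubling-time-to-rate conversion is the single shared
`rate_from_doubling()`. The fixation criterion (`fixed_mutations()`,
threshold 0.90) recovers exactly the M239I + E403D pair; the Kendall
concordance of Ser-219 rate with round (0.87 on the fixture) summarizes
the rising trend without overclaiming strict monotonicity, which the data
do not show.

## Interfaces

The exported functions, the packaged fixtures and this vignette are the
package's interface; analyses are a few lines of R (see the README's
worked example), so no shell wrapper is shipped. Readers and writers for
the standard formats (plate TSV/CSV wide or long, landscape TSV, aligned
FASTA + labels TSV, variant TSV, codon-table TSV) are provided so the
modules interoperate with external tools.

## Known limitations

* The growth-rate estimator's maximum-selection bias discussed above.
* Only biallelic loci in landscapes; multi-allelic variation lives at the
  codon and alignment levels.
* Direct (shortest) trajectories only; no fixation-probability weighting
  or higher-order epistasis decomposition.
* The alignment generator's columns are mutually independent apart from
  the one coupled pair, so richer covariation cannot be simulated.
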