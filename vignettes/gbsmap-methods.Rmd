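---
title: "Models and methods behind gbsmap"
author: "gbsmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbsmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gbsmap` rebuilds, as reusable and tested R code, the full analysis chain
needed to turn raw genotyping-by-sequencing (GBS) calls from a biparental
recombinant inbred line (RIL) population into a high-density genetic map
and QTL scan. This vignette documents the models, the tunable parameters,
the numerical choices, and the places where the design was genuinely
open — together with what the synthetic validation does and does not
demonstrate.

## The population model

All genetics in the package assume a biparental population inbred by
single-seed descent (SSD): an F1 (fully heterozygous) is selfed
`generation − 1` times, keeping one offspring per line per round. Calls
are coded by parental origin: 0 = homozygous parent A, 1 = heterozygous,
2 = homozygous parent B, `NA` = missing. Parent A is the first declared
parent; the 0/2 orientation of every marker is anchored to that
declaration (markers read from allele-level files whose parents are both
missing are carried as *unoriented* until `infer_parental_genotypes()`
phases them against the nearest oriented marker).

The simulator (`simulate_population()`) draws, per chromosome and
meiosis, a Poisson number of crossovers with mean equal to the genetic
length in Morgans, placed uniformly in genetic distance — i.e. **no
crossover interference**. Interference affects the spacing of double
crossovers but not expected junction counts, and the map estimators
downstream operate on adjacent-interval fractions of order 0.05 cM where
the Haldane/Kosambi distinction is far below the acceptance tolerances;
we therefore kept the simplest kernel. A per-chromosome *recombination
landscape* (piecewise rate multipliers over physical position,
normalized to average 1) maps physical to genetic coordinates,
producing suppressed pericentromeric recombination and hot chromosome
ends; the default profile multiplies the background by 2.2 in the outer
8%, 1.4 in the next 22%, and 0.25 in the central 40% of each
chromosome. The default genome is a 12-chromosome, 1,088-cM / 353-Mb
melon-like genome.

Two selfing-theory identities are used as free validation: residual
heterozygosity at F_t is exactly `2^-(t-1)` per locus, and junction
density per haplotype approaches 2 per Morgan as t grows. The test suite
checks both, plus a brute-force oracle comparison of junction counts.

## GBS artifacts and what they emulate

`inject_artifacts()` corrupts the true matrix in the order errors →
missingness → misallocation → inversion → parental missingness:

* **Missingness** is beta-distributed per site (`mean = 0.445`,
  `shape1 = 0.35` by default) rather than uniform. This mirrors the
  site-depth dispersion of reduced-representation libraries and is what
  makes a minority of sites fully observed — the anchor pool. With
  uniform missingness at 44.5% essentially no marker would be
  zero-missing across 109 lines and the anchor-based QC stages would be
  untestable; with the default dispersion about 6% of markers qualify,
  matching the order observed in real GBS panels.
* **Errors** flip a call with probability 0.002; an erroneous homozygote
  becomes the opposite homozygote (70%) or a het (30%), producing the
  isolated spurious double recombinants the sliding window targets.
* **Misallocated markers** (54 by default) receive a false chromosome
  and position, sampled with weight `1/(mult + 0.05)^2` so they
  originate preferentially from low-recombination windows, while their
  genotype columns stay truthful.
* **An inverted block** (28 consecutive markers starting at ~30.5 Mb of
  chromosome 1 by default) has its reported positions reflected, so the
  reported order of the block is reversed.
* **Parents** lose 30% of their calls (70% call rate); markers whose
  parents are both missing have their coding randomly swapped half the
  time and are flagged unoriented, which is exactly the situation
  `infer_parental_genotypes()` must repair.
* **Segregation distortion** is a breeding-time process, so it lives in
  the meiosis kernel rather than in the observation layer: gametic
  viability selection at one locus (chromosome 6 by default) in every
  selfing generation. The selection coefficient is found by bisection on
  the exact single-locus genotype recursion so that the favored allele
  reaches a target frequency (0.83) at the final generation;
  `simulate_gbs_dataset()` wires the calibration automatically. A
  10,000-line independent simulation verifies the calibration in the
  tests.

The simulator does **not** emulate read depths or genotype likelihoods,
allele-specific error biases, duplicated/repetitive-region collapse
(misallocation is positional only), residual parental heterozygosity, or
segregating structural variation beyond the single inverted block.
Passing tests on this synthetic data therefore demonstrate correctness
of the algorithms under the stated statistical structure, not robustness
to every pathology of real libraries.

## QC stages

**Anchors and grouping.** Anchors are markers with zero missing data in
all RILs and both parents, biallelic, with opposite homozygous parents.
Pairwise linkage uses only doubly homozygous lines (hets are
non-informative in a RIL and the backcross-likelihood LOD,
`k log10(2R) + (n−k) log10(2(1−R))`, is a *test statistic* here, not a
distance — no riself correction is applied inside it). Groups are
single-linkage components at LOD > 10. Misallocation flags any marker
whose group differs from its physical chromosome's majority group.

**De novo ordering** is seriation by objective — minimize the sum of
adjacent recombination fractions. Groups of ≤ 12 markers are solved
exactly by a Held–Karp dynamic program; larger groups use
nearest-neighbour chaining from several starts plus full 2-opt
refinement. The orientation is normalized so the first marker has the
smaller physical position. Inversion detection compares the reference
and de novo orders after aligning their global orientation (sign of the
rank correlation) and reports maximal runs that step backwards by one; a
run spanning the whole set is classed "orientation", not "inversion".
The run rule is this package's own construction: exact contiguity is
only guaranteed when adjacent markers are statistically resolvable, so
the validation uses marker spacings (~2 cM at n = 400 lines) where they
are.

**Fisher filter.** Each non-anchor marker is tested against its nearest
four anchors by physical distance (two per side; ties toward the smaller
position; chromosome ends use the anchors available; anchor-less
chromosomes pass untested with a warning). The 2×2 tables count
parent-coded homozygous calls over lines non-missing and homozygous at
both markers — hets are excluded for the same informativeness reason as
above. The two-sided p-value is computed directly from the
hypergeometric mass (`stats::dhyper`, summing probabilities ≤ the
observed table's within relative tolerance 1e−7); an exhaustive sweep
against independent enumeration for every table with n ≤ 30, and spot
checks against `stats::fisher.test`, pin the implementation down. A
marker is dropped when *any* of its tests has p > 0.05 — independence
from even one nearby anchor marks an error-prone locus.

**Sliding window.** Scores are computed on the original matrix and
removals applied afterwards — a deliberate single-pass design so the
output is deterministic and order-independent (no cascade of removals
into re-scored windows). The window is 25 markers, threshold 0.8, and
the 12 markers at each chromosome end are structurally uncorrectable.
A planted-error experiment in the tests requires ≥ 95% removal of
isolated flips with < 0.5% collateral damage.

## HMM imputation

The imputer is a three-state chain per line and chromosome. Transitions
over an interval of d cM use the switch probability `q = 2r/(1+2r)` with
`r = kosambi_inv(d)` between the homozygous states; the full 3×3 kernel
is the reversible "redraw from the stationary distribution" form
`T = (1−ρ)I + ρ 1πᵀ` with `π = ((1−h)/2, h, (1−h)/2)` and `ρ = q/π_B`,
so the homozygote-to-homozygote element is exactly q and the het state
is entered in proportion to the residual-het level h (default
`2^-6 = 0.0156`, the F7 expectation). Emissions are symmetric with
error rate ε (default 0.005); missing cells emit 1 in every state.
Distances come from the genetic map when one exists, otherwise from
physical positions at a configurable 3 cM/Mb. Posteriors are computed by
scaled forward–backward, vectorized across lines; an exhaustive
path-enumeration oracle on short chromosomes verifies them to 1e−6.
Missing cells are filled when the argmax posterior reaches τ = 0.95;
observed calls are never overwritten (error correction is the sliding
window's job, mirroring the reference workflow's division of labour).
Lines with fewer than two observed calls on a chromosome are skipped and
reported.

The contract for imputation quality is the masking experiment
(`evaluate_imputation()`): mask 5% of observed homozygous calls,
re-impute, report accuracy among called cells and the non-imputed
fraction, over 10 replicates.

## Map estimation: the generation-aware correction

The classic `riself` conversion `r = R/(2(1−R))` assumes the population
is fully inbred. At F7 this is measurably wrong once one conditions on
the lines actually informative for mapping (doubly homozygous at both
markers): a junction created in a late selfing generation is
disproportionately still heterozygous and hence invisible, so the
observed recombinant fraction for tight linkage is only ≈ 0.905 of its
F∞ value. We verified this with an exact 16-state two-locus selfing
recursion (`ril_observed_R()`), and the ~9.5% map-length deficit it
predicts is exactly what F∞-corrected maps of simulated F7 populations
show. `build_map()` therefore inverts the *generation-specific* relation
(monotone interpolation on an r-grid of the exact recursion;
`generation = Inf` recovers the classic formula). With this estimator,
simulated F7 populations on the default genome return the generating
1,088-cM total within sampling noise (±2–3% at 109 lines). The
`riself_correct()` function itself is retained for the pairwise-LOD,
HMM and dosage computations, where the F∞ scale is the conventional
modeling approximation and only relative distances matter.

Interval counting skips *missing* cells: a transition is judged between
consecutive non-missing calls when both are homozygous, attributed to
the interval after the earlier call. This matters after imputation,
whose leftover missing cells sit almost exclusively where a breakpoint's
position is ambiguous — a strict adjacent-pair count would silently drop
about half of all junctions and halve the map. Heterozygous calls, by
contrast, *break* a pair rather than being skipped: residual-het tracts
are junction-enriched, and the finite-generation R(r) relation
conditions on homozygosity, so skipping hets would inflate the map by
several percent. On complete matrices the rule reduces exactly to
strict adjacent-pair counting.

Breakpoints are transitions between successive non-missing homozygous
calls; bins are maximal runs of markers with no direct-adjacent
breakpoint in any line (a breakpoint whose position is undetermined
because of missing/het calls between the flanks does not split a bin).
Bin consensus genotypes are strict per-line majorities, ties going
missing. Windowed recombination rates regress cM on Mb by OLS per 1-Mb
window (≥ 3 markers required); the reported unit is cM/Mb, which is why
the genetic coordinate is the response even though the source workflow's
prose inverts the phrasing.

## CIM

Haley–Knott regression on the expected allele dosage
`x = P(B|flanks) − P(A|flanks) ∈ [−1, 1]`, computed from the nearest
informative flanking bins with RIL-scale switch probabilities. The scan
grid is the union of a 1-cM lattice and the bin positions themselves (as
in standard scan implementations), so a genotyped bin scores exactly.
Cofactors (2–5) are chosen by forward RSS selection — the selection rule
is this package's own, as only the count is conventional — with
deterministic first-index tie-breaks, and are excluded within 10 cM of
the test position. `LOD = (n/2) log10(RSS_red/RSS_full)`; a perfect fit
is capped (default 100) with a warning, and ties at the cap resolve
toward the largest PVE. Permutation thresholds shuffle the phenotype and
*reselect cofactors inside every permutation* so the permuted null stays
exchangeable; the threshold is the empirical (1−α) quantile (type-1, so
α = 1 degenerates to the minimum). Bayes credible intervals accumulate
normalized `10^LOD` mass outward from the peak on the scan grid, growing
toward the heavier side. Additive effects are the partial regression
coefficient on x at the peak (half the parental-class difference); PVE
is `100(1 − RSS_full/RSS_red)` at the peak. Phenotypes are treated as
continuous even for ordinal-scored traits.

The type-I calibration test (200 null phenotypes, 100 permutations each)
checks the rejection rate is within 0.04 of α = 0.05, and a planted
30%-PVE QTL at n = 109 must be localized within 5 cM in ≥ 90% of 20
populations.

## Problem sizes and reproducibility

The default test run simulates populations from 40–400 lines and
200–23,000 markers; the two full-scale checks (masking accuracy and
map-length recovery at 109 × ~23,000) run in well under a minute each on
one CPU, and the whole suite in about two minutes. Every stochastic
component takes an explicit seed and restores the caller's RNG state;
fixed seeds give bit-identical matrices, summaries and thresholds.
`scripts/acceptance.R` recomputes the two headline quantities from
scratch from a single command-line seed.

The spec'd command-line surface is intentionally the R API plus that
one script: the package's audience drives analyses from R, as with the
established linkage-mapping packages this one is styled after.

## Known limitations

* The inversion-detection run rule needs adjacent markers to be
  statistically resolvable; at very tight spacings equal-cost local
  swaps fragment runs.
* The de novo ordering objective is the adjacent-fraction sum, not a
  full multipoint likelihood; beyond 12 markers the optimizer is a
  heuristic (exact on every tested small instance).
* Parental genomes are assumed fully inbred; the parent rows carry
  missingness but never heterozygosity.
* The HMM's het state is a stationary mixture component, not a model of
  het-tract length; it suffices for calling but not for segmenting
  residual heterozygous blocks.
* CIM fits a single-QTL model with cofactors; linked-QTL deconvolution
  and epistasis are out of scope.
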