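---
title: "SHAPE-directed modeling of RNA structure ensembles: methods and design"
author: "shapeEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SHAPE-directed modeling of RNA structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeEnsemble)
```

## The problem

Chemical probing by SHAPE reports, per nucleotide, a normalized reactivity
that correlates with backbone flexibility: unpaired nucleotides tend to be
reactive, paired ones less so. When an RNA populates several conformations
at equilibrium — riboswitches are the canonical case — the measured
reactivity is a population-weighted average across those conformations, and
interpreting it under a single-structure assumption misreads the data: a
nucleotide with reactivity 0.75 may be unpaired, weakly paired, or paired
in half the molecules and unpaired in the rest. This package models the
experiment generatively. It asks: what ensemble of secondary structures,
weighted by the thermodynamic model and gently restrained by the probing
data, best explains the measured profile — and what distinct conformations
with what populations does that ensemble contain?

## The procedure

The pipeline (`foldEnsemble()`) runs exactly once, in this order:

1. **Unrestrained partition function.** McCaskill-style dynamic programming
   over all pseudoknot-free structures under the nearest-neighbor model.
2. **Boltzmann sample,** 10 000 structures by stochastic traceback.
3. **Reactivity estimation.** Each nucleotide in each sampled structure is
   classified as unpaired, helix end, or helix interior; `Rcalc` is the
   ensemble average of the class reactivities.
4. **Restraint.** Per nucleotide,
   $\Delta G_{bonus,i} = C \ln\left[(Rexp_i + Offset)/(Rcalc_i + Offset)\right]$,
   added to the free energy of every base-pair stack containing nucleotide
   *i*; the partition function is recomputed under these bonuses.
5. **Single-structure mode:** maximum expected accuracy (MEA) structure
   from the restrained pair probabilities; or
6. **Restrained sample** of 1000 structures,
7. **clustering** by base-pair distance with automatic choice of the number
   of clusters, and
8. **centroids with populations** (cluster fractions), plus the Shannon
   entropy of base pairing.

The restraint is deliberately mild and self-correcting: where the ensemble
already explains the measurement the bonus is zero; an over-reactive
nucleotide (measured > estimated) is destabilized in its pairings, an
under-reactive one stabilized. One pass is enforced by construction — there
is no iteration option. Re-estimating `Rcalc` from the restrained ensemble
and restraining again chases the probing noise away from the thermodynamic
prior and demonstrably degrades single-structure accuracy, so the package
does not expose a second pass.

## The energy model

The folding engine uses a simplified nearest-neighbor model: stacking free
energies for all 36 ordered combinations of canonical pairs (AU, UA, GC,
CG, GU, UG), tabulated hairpin and internal/bulge loop penalties with
logarithmic extrapolation beyond the table, and a linear multibranch model
(offset + per-branch + per-unpaired). All values live in an editable flat
parameter file (`inst/extdata/nn_params.txt`) loaded by `loadParams()`;
the shipped values have realistic magnitudes (stacks −0.2 to −3.4
kcal/mol, hairpin initiation ~5–6 kcal/mol) but are not any published
parameter set. Dangling ends, coaxial stacking and temperature-dependent
enthalpy decomposition are omitted; they are extension points, not inputs
the algorithm depends on. Because the parameter set is simplified,
benchmark-level agreement with published accuracies on natural RNAs is not
expected — the algorithmic behavior (restraint direction, ensemble
recovery, clustering) is what the package demonstrates and tests.

A *stack* is a pair of nested pairs (i,j) and (i+1,j−1) both present. The
pseudo-free-energy bonus of a nucleotide is added once per stack that
contains it, so helix-interior nucleotides (two stacks) receive it twice
and helix-end nucleotides once. The loop-decomposition evaluator
(`structureEnergy()`) and the DP engine implement this rule independently;
the test suite checks them against each other through exhaustive
enumeration.

## Reactivity distributions

Three class-conditional distributions drive both reactivity estimation and
the forward simulator. Empirically, all three classes peak at reactivity
zero and overlap heavily; the unpaired class skews far to the right, helix
ends slightly right of helix interiors. The defaults are gamma
distributions chosen to reproduce that shape:

| class          | shape | scale | mean |
|----------------|-------|-------|------|
| unpaired       | 1.0   | 0.80  | 0.80 |
| helix end      | 0.8   | 0.35  | 0.28 |
| helix interior | 0.6   | 0.25  | 0.15 |

With shape ≤ 1 the density is maximal at zero with a heavy right tail, on
the 0–2.5 scale of normalized reactivities. The class means are the only
moments the deterministic (`"expectation"`) estimation mode consumes; the
full distributions matter for the `"montecarlo"` mode and the simulator.
Users with fitted empirical histograms can substitute parameters via
`reactivityDistributions()`. The validity contract enforces
mean(unpaired) > mean(helix end) ≥ mean(helix interior).

A nucleotide is *helix interior* only when both flanking pairs
(i−1,j+1) and (i+1,j−1) exist; everything else paired is *helix end*. An
isolated pair is therefore two helix-end nucleotides, and a 1-nt bulge
interrupts interior status — the strict flanking-pair rule, applied
uniformly.

## Restraint parameters and numerical choices

* `C = 0.5` kcal/mol and `Offset = 1.1` are the defaults, the optimum of
  the 15 × 15 calibration grid (0.1–1.5 in steps of 0.1, 225
  combinations) re-runnable via `gridSearch()`/`jackknifeCalibration()`.
* Normalized reactivities can be negative; `Offset` keeps the log argument
  positive for values down to −1.1. Below that (possible under unusual
  normalizations) both numerator and denominator are floored at
  `epsilon = 1e-4` rather than erroring; the floor is configurable.
* Missing measurements (−999 in SHAPE files) receive bonus 0: no restraint
  is exactly the thermodynamic prior, the same treatment as a perfectly
  matching estimate. They are never interpolated.
* Boltzmann sums are accumulated in extended (long double) precision,
  which keeps the unscaled partition function in range for sequences to
  several hundred nucleotides.
* Stochastic traceback enumerates decomposition terms in a fixed
  lexicographic order, one uniform deviate per decision, through R's RNG —
  `set.seed()` makes samples exactly reproducible, and the pipeline
  records its seeds (reactivity sample: `seed`; cluster sample:
  `seed + 1`; fresh independent samples per step).
* MEA uses pair weight γ = 1 by default (exposed in `foldConfig()`); ties
  in the DP resolve toward the unpaired/first-candidate branch, so results
  are deterministic.
* The minimum hairpin size is 3 enclosed nucleotides, enforced both by the
  engine and by `SecondaryStructure` validity.

## Clustering and the number of conformations

Structures are embedded as binary base-pair indicator vectors; the
base-pair distance (symmetric difference, the field's standard metric)
equals squared Euclidean distance in that embedding. Partitions are
computed by k-medoids (`cluster::pam`, deterministic) on the distance
matrix for each candidate k in 2..kMax (default 10), and k is chosen by
the Calinski-Harabasz index CH(k) = [B(k)/(k−1)]/[W(k)/(n−k)].

Two guards make this robust for discrete ensembles:

* **Micro-cluster guard.** A Boltzmann sample of a short RNA repeats a few
  structures many times. Peeling off a handful of duplicated rare
  structures drives the within-cluster dispersion W toward zero and CH
  toward infinity, so unguarded CH maximization always prefers many tiny
  clusters. Candidate partitions containing a cluster below
  `minClusterFrac` (default 2% of the sample, matching the population
  reporting floor) are therefore rejected during k selection. Populations
  below ~2% are not interpretable conformations at n = 1000 anyway.
* **Homogeneity fallback.** With fewer than two distinct structures, total
  dispersion near zero, or every candidate partition rejected, one cluster
  is reported (CH is undefined at k = 1).

Centroids contain exactly the pairs at within-cluster frequency > 0.5
(strict). Marginally, two conflicting pairs can both clear 0.5; conflicts
are resolved by descending frequency, then lexicographic order, dropping
later offenders, and the centroid is validated as a legal structure.
Duplicates in the sample are kept throughout — they carry the population
weight. `mergeEquivalentClusters()` maps centroids onto known reference
structures at a configurable accuracy threshold (default 80%,
geometric mean of sensitivity and PPV with slipped-pair tolerance),
summing populations of clusters that predict the same reference; ties go
to the first reference in order and are messaged.

## The synthetic-data generator

`simulateShape()` is the forward model used by every end-to-end test: the
observed reactivity of a nucleotide is the population-weighted mean of the
reactivity it would exhibit in each conformation of a known mixture. Per
replicate, one value is drawn from the class distribution of the
nucleotide in each structure; 50 replicates are averaged by default,
giving per-nucleotide noise of a few hundredths — comparable to a
well-averaged probing experiment while still stochastic. The designed
23-nt bistable fixture (`bistableExample()`) places two mutually exclusive
5-pair hairpins of similar stability 10 base pairs apart, so the
unrestrained model predicts a near-even mixture and the restraint must
move it.

What the simulator emulates: population averaging (the central physics),
class-dependent reactivity overlap, missing-data masks, reproducible
noise. What it does not: sequence-dependent adduct chemistry, primer
extension drop-off and normalization artifacts, tertiary-contact
protections, and correlated noise along the backbone. Passing the
recovery tests therefore shows the algorithm inverts its own generative
model at realistic noise — it does not certify accuracy on real probing
data under a full thermodynamic parameter set.

## Problem sizes in the test suite

The checks run at desk scale, chosen so the whole suite completes in well
under a minute: exhaustive-enumeration cross-checks on ≥ 20 random
sequences of 9–14 nt (thousands of structures each at most); sampler
goodness-of-fit with 50 000 draws on a 12-nt toy; the bistable recovery at
the full default sample sizes (10 000 / 1000) on the 23-nt fixture;
planted-partition clustering at n = 1000 with groups of 500/300/200.
Calibration tests use reduced grids and sample sizes of a few hundred,
since the full 225-point grid re-folds the dataset at every point.

## Known limitations

* Pseudoknots are outside the structure space, in the partition function
  and everywhere downstream.
* The simplified parameter set trades benchmark fidelity for a
  self-contained, editable model; swap in richer tables via the parameter
  file to approach published nearest-neighbor behavior.
* Three structural classes cannot represent, e.g., flexible non-canonical
  pairs; the class machinery is written so additional states are a
  contained extension.
* The restraint functional form is a calibrated heuristic; alternative
  forms are deliberately not implemented.
* `estimateRcalc()` estimates tend toward class means, so extreme measured
  reactivities can never be matched exactly and generate standing
  restraints; this is inherent to the three-state description.
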