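# shapeEnsemble

SHAPE-directed modeling of RNA secondary-structure **ensembles**: from one
sequence and a per-nucleotide SHAPE reactivity profile, predict the distinct
conformations an RNA populates at equilibrium and their populations.

Most SHAPE-directed structure prediction assumes the RNA folds into a single
structure. Riboswitches, mRNAs and many regulatory RNAs do not: the measured
reactivity of a nucleotide is a population-weighted average over every
conformation in solution, and no single structure needs to be consistent with
it. This package treats the probing experiment that way. It is aimed at
computational RNA biologists who have normalized SHAPE reactivities for a
sequence of interest (riboswitch leaders, bistable elements, structured
UTRs) and want conformations with populations rather than one structure.

## Method

1. Compute the partition function over all pseudoknot-free secondary
   structures under a nearest-neighbor thermodynamic model, and draw a
   Boltzmann sample of 10 000 structures.
2. Estimate the reactivity each nucleotide would show given that ensemble
   (`Rcalc`). Every nucleotide in every sampled structure belongs to one of
   three structural classes — unpaired, paired at a helix end, paired in a
   helix interior — each with its own reactivity distribution; the estimate
   is the ensemble average.
3. Convert the mismatch between measurement and estimate into a
   per-nucleotide pseudo-free energy,

   ΔG<sub>bonus,i</sub> = C · ln[(Rexp<sub>i</sub> + Offset) / (Rcalc<sub>i</sub> + Offset)]

   with C = 0.5 kcal/mol and Offset = 1.1 (calibrated by grid search).
   The bonus is added to the free energy of every base-pair stack the
   nucleotide participates in, so helix-interior nucleotides receive it
   twice and helix-end nucleotides once. Nucleotides whose estimate already
   matches the experiment, or with no data, are not restrained.
4. Recompute the partition function with the restraints — one pass only —
   sample 1000 structures, cluster them by base-pair distance with the
   number of clusters chosen by the Calinski-Harabasz index, and report each
   cluster's centroid structure (pairs at within-cluster frequency > 0.5)
   with its population. Ensemble diversity is summarized by the Shannon
   entropy of base pairing, S = −Σ P<sub>ij</sub> log₁₀ P<sub>ij</sub> / N.

A single-structure mode stops after step 4 and returns the maximum expected
accuracy structure. A forward simulator generates SHAPE profiles from known
structure mixtures for validation, and calibration utilities rerun the
C/Offset grid search with jackknife validation.

## Worked example

A designed 23-nt bistable switch can fold its central segment against
either the 5' or the 3' repeat. Simulate a SHAPE profile for a 70/30
mixture of the two hairpins, then recover the ensemble:

```r
library(shapeEnsemble)
fx <- bistableExample()
dotBracket(fx$structures$A)   # "(((((....))))).........."
prof <- simulateShape(list(list(structure = fx$structures$A, population = 0.7),
                           list(structure = fx$structures$B, population = 0.3)),
                      seed = 11)
model <- foldEnsemble(fx$seq, prof, foldConfig(seed = 5))
model
#> EnsembleModel: 2 conformations, Shannon entropy 0.0501
#>   [1] population 0.793  (((((....))))).........
#>   [2] population 0.207  .........(((((....)))))
```

Both generating hairpins are recovered exactly (geometric-mean accuracy
1.0) and the 79/21 population estimate is within 0.31 kcal/mol — about half
of kT at 310 K — of the true 70/30 free-energy balance. Without the SHAPE
profile (`foldEnsemble(fx$seq, NULL, ...)`) the thermodynamic model alone
puts the mixture near 54/46.

A thin command-line front end with `fold`, `simulate`, `evaluate` and
`calibrate` subcommands is installed at
`inst/scripts/shape-ensemble.R`.

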