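#' @useDynLib shapeEnsemble, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Minimum number of unpaired-index distance enforced between the two
## partners of any base pair (j - i > MIN_HAIRPIN); the canonical steric
## limit of three enclosed nucleotides.
MIN_HAIRPIN <- 3L

#' SecondaryStructure: one pseudoknot-free conformation
#'
#' A single RNA secondary structure: a sequence length and a set of base
#' pairs (i, j) with i < j, 1-based. Structures are the unit that is
#' sampled from the Boltzmann ensemble, clustered, and scored. Validity
#' enforces that every index occurs in at most one pair, that pairs are
#' nested (no pseudoknots) and that every pair encloses at least three
#' nucleotides.
#'
#' @slot seqLength integer, number of nucleotides.
#' @slot pairs two-column integer matrix of base pairs, i < j, 1-based.
#' @export
setClass("SecondaryStructure",
         representation(seqLength = "integer", pairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  n <- object@seqLength
  p <- object@pairs
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("seqLength must be a single positive integer")
  if (!is.integer(p) || ncol(p) != 2L)
    return("pairs must be a two-column integer matrix")
  if (nrow(p) == 0L) return(TRUE)
  if (any(is.na(p)) || any(p < 1L) || any(p > n))
    return("pair indices out of range")
  if (any(p[, 1L] >= p[, 2L]))
    return("pairs must satisfy i < j")
  idx <- as.vector(p)
  if (anyDuplicated(idx))
    return("a nucleotide occurs in more than one pair")
  if (any(p[, 2L] - p[, 1L] <= MIN_HAIRPIN))
    return(sprintf("a pair encloses fewer than %d nucleotides", MIN_HAIRPIN))
  ## pseudoknot check: sort by i, every enclosed pair must close before j
  o <- order(p[, 1L])
  pi <- p[o, 1L]; pj <- p[o, 2L]
  if (nrow(p) > 1L) {
    for (a in seq_len(nrow(p) - 1L)) {
      b <- (a + 1L):nrow(p)
      cross <- pi[b] < pj[a] & pj[b] > pj[a]
      if (any(cross))
        return("structure contains a pseudoknot (crossing pairs)")
    }
  }
  TRUE
})

#' ReactivityProfile: per-nucleotide SHAPE reactivities
#'
#' Normalized SHAPE reactivities, one value per nucleotide; values may be
#' negative. Missing measurements are stored as \code{NA} and excluded
#' from all downstream statistics (they receive a zero pseudo-free-energy
#' restraint).
#'
#' @slot values numeric vector; \code{NA} marks missing data.
#' @export
setClass("ReactivityProfile", representation(values = "numeric"))

setValidity("ReactivityProfile", function(object) {
  v <- object@values
  if (length(v) < 1L) return("profile must have at least one position")
  if (any(is.infinite(v))) return("reactivities must be finite or NA")
  TRUE
})

#' PairProbabilityMatrix: base-pair probabilities
#'
#' Upper-triangular matrix of base-pair probabilities P[i, j] from a
#' (possibly restrained) partition function or from ensemble frequencies.
#' For each nucleotide the total pairing probability is at most 1; the
#' remainder is its unpaired probability.
#'
#' @slot probs square numeric matrix, entries in the upper triangle.
#' @export
setClass("PairProbabilityMatrix", representation(probs = "matrix"))

setValidity("PairProbabilityMatrix", function(object) {
  P <- object@probs
  if (!is.numeric(P) || nrow(P) != ncol(P))
    return("probs must be a square numeric matrix")
  if (any(P[lower.tri(P, diag = TRUE)] != 0))
    return("probs must be strictly upper triangular")
  tol <- 1e-9
  if (any(P < -tol) || any(P > 1 + tol))
    return("probabilities must lie in [0, 1]")
  tot <- rowSums(P) + colSums(P)
  if (any(tot > 1 + 1e-6))
    return("per-nucleotide total pairing probability exceeds 1")
  TRUE
})

#' StructureEnsemble: a Boltzmann sample of structures
#'
#' An ordered list of (possibly repeated) \linkS4class{SecondaryStructure}
#' objects drawn from the Boltzmann distribution, together with the RNG
#' seed used and whether the sample came from the unrestrained or the
#' SHAPE-restrained partition function.
#'
#' @slot structures list of \linkS4class{SecondaryStructure}.
#' @slot seed integer seed used for the draw (NA if not recorded).
#' @slot source character, \code{"unrestrained"} or \code{"restrained"}.
#' @export
setClass("StructureEnsemble",
         representation(structures = "list", seed = "integer",
                        source = "character"))

setValidity("StructureEnsemble", function(object) {
  ss <- object@structures
  if (length(ss) < 1L) return("ensemble must contain at least one structure")
  if (!all(vapply(ss, is, logical(1L), "SecondaryStructure")))
    return("all elements must be SecondaryStructure objects")
  lens <- vapply(ss, function(s) s@seqLength, integer(1L))
  if (length(unique(lens)) != 1L)
    return("all structures must share one sequence length")
  if (!object@source %in% c("unrestrained", "restrained"))
    return("source must be 'unrestrained' or 'restrained'")
  TRUE
})

#' ClusterResult: partition of a structure sample
#'
#' Cluster labels for every sampled structure, the chosen number of
#' clusters k, and the Calinski-Harabasz score of each candidate k.
#'
#' @slot assignments integer cluster label (1..k) per structure.
#' @slot k integer, chosen number of clusters.
#' @slot chScores named numeric, CH index per candidate k (NA at k = 1).
#' @slot distanceMetric character, name of the structure distance used.
#' @export
setClass("ClusterResult",
         representation(assignments = "integer", k = "integer",
                        chScores = "numeric", distanceMetric = "character"))

setValidity("ClusterResult", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  a <- object@assignments
  if (any(is.na(a)) || any(a < 1L) || any(a > object@k))
    return("assignments must lie in 1..k")
  TRUE
})

#' EnsembleModel: conformations with populations
#'
#' The final output of the ensemble pipeline: centroid structures, one per
#' conformation, with the population (cluster fraction), the within-cluster
#' pair-probability matrix of each conformation, and the Shannon entropy of
#' base pairing (log base 10, per nucleotide) of the restrained ensemble.
#'
#' @slot centroids list of \linkS4class{SecondaryStructure}, one per cluster.
#' @slot populations numeric fractions, > 0, summing to 1.
#' @slot clusterPairProbs list of \linkS4class{PairProbabilityMatrix}.
#' @slot shannonEntropy numeric, per-nucleotide base-10 pairing entropy.
#' @slot chScores numeric, CH curve from cluster-number selection.
#' @slot lowPopulation logical flag per conformation (below the reporting
#'   floor, default 2\% of the sample).
#' @export
setClass("EnsembleModel",
         representation(centroids = "list", populations = "numeric",
                        clusterPairProbs = "list", shannonEntropy = "numeric",
                        chScores = "numeric", lowPopulation = "logical"))

setValidity("EnsembleModel", function(object) {
  k <- length(object@centroids)
  if (k < 1L) return("at least one conformation required")
  if (length(object@populations) != k ||
      length(object@clusterPairProbs) != k ||
      length(object@lowPopulation) != k)
    return("centroids, populations, clusterPairProbs, lowPopulation must align")
  if (any(object@populations <= 0))
    return("populations must be positive")
  if (abs(sum(object@populations) - 1) > 1e-9)
    return("populations must sum to 1")
  if (object@shannonEntropy < 0)
    return("Shannon entropy must be non-negative")
  TRUE
})

#' ThermoConstants: gas constant and temperature
#'
#' Physical constants of the folding engine: the gas constant R in
#' kcal/(mol K), the absolute temperature T in K (default 310.15), and the
#' derived thermal energy kT = R*T in kcal/mol.
#'
#' @slot R numeric, kcal/(mol K).
#' @slot T numeric, K.
#' @slot kT numeric, kcal/mol, equal to R*T.
#' @export
setClass("ThermoConstants",
         representation(R = "numeric", T = "numeric", kT = "numeric"))

setValidity("ThermoConstants", function(object) {
  if (object@T <= 0) return("temperature must be positive")
  if (abs(object@kT - object@R * object@T) >
      1e-12 * max(1, abs(object@kT)))
    return("kT must equal R * T")
  TRUE
})

#' NearestNeighborParams: thermodynamic parameter set
#'
#' A simplified nearest-neighbor model: stacking free energies for the 36
#' combinations of adjacent canonical pairs, size-dependent hairpin and
#' internal/bulge loop penalties (tabulated with logarithmic extrapolation
#' beyond the table), and a linear multibranch-loop model
#' (offset + perBranch * branches + perUnpaired * unpaired nucleotides).
#'
#' @slot stack 6x6 numeric matrix, kcal/mol; rows = outer pair, columns =
#'   inner pair, in the order AU, UA, GC, CG, GU, UG.
#' @slot hairpin numeric, penalties for loop sizes
#'   \code{MIN_HAIRPIN..length(hairpin)+MIN_HAIRPIN-1}, kcal/mol.
#' @slot hairpinExt numeric, coefficient of the log extrapolation.
#' @slot internal numeric, penalties for total internal/bulge loop sizes
#'   1..length(internal), kcal/mol.
#' @slot internalExt numeric, coefficient of the log extrapolation.
#' @slot multibranch numeric length 3: offset, per-branch, per-unpaired.
#' @slot minHairpin integer, minimum enclosed nucleotides (>= 3).
#' @export
setClass("NearestNeighborParams",
         representation(stack = "matrix", hairpin = "numeric",
                        hairpinExt = "numeric", internal = "numeric",
                        internalExt = "numeric", multibranch = "numeric",
                        minHairpin = "integer"))

PAIR_CODES <- c("AU", "UA", "GC", "CG", "GU", "UG")

setValidity("NearestNeighborParams", function(object) {
  if (!identical(dim(object@stack), c(6L, 6L)))
    return("stack must be a 6x6 matrix over the canonical pair codes")
  if (!identical(rownames(object@stack), PAIR_CODES) ||
      !identical(colnames(object@stack), PAIR_CODES))
    return("stack dimnames must be AU, UA, GC, CG, GU, UG")
  if (any(!is.finite(object@stack))) return("non-finite stack energy")
  if (length(object@hairpin) < 1L || any(!is.finite(object@hairpin)))
    return("hairpin table must be non-empty and finite")
  if (length(object@internal) < 1L || any(!is.finite(object@internal)))
    return("internal table must be non-empty and finite")
  if (length(object@multibranch) != 3L || any(!is.finite(object@multibranch)))
    return("multibranch must be three finite coefficients")
  if (object@minHairpin < 3L) return("minHairpin must be >= 3")
  TRUE
})

#' RestraintParams: pseudo-free-energy restraint parameters
#'
#' The energy scale C (kcal/mol), the unitless Offset accommodating
#' negative normalized reactivities, and a positivity floor epsilon for the
#' log argument. Defaults C = 0.5, Offset = 1.1 are the calibrated optimum
#' of the grid search.
#'
#' @slot C numeric, kcal/mol, > 0.
#' @slot Offset numeric, unitless, > 0.
#' @slot epsilon numeric floor applied to (reactivity + Offset), > 0.
#' @export
setClass("RestraintParams",
         representation(C = "numeric", Offset = "numeric",
                        epsilon = "numeric"))

setValidity("RestraintParams", function(object) {
  if (object@C <= 0) return("C must be positive")
  if (object@Offset <= 0) return("Offset must be positive")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' ReactivityDistributions: class-conditional SHAPE distributions
#'
#' Three parametric reactivity distributions, one per structural context
#' (unpaired, paired at a helix end, paired in a helix interior). Each is a
#' gamma distribution given as c(shape, scale); the gamma family with
#' shape <= 1 peaks at zero with a right tail, matching the empirical shape
#' of normalized SHAPE reactivity histograms. The class means must satisfy
#' mean(unpaired) > mean(helixEnd) >= mean(helixInterior).
#'
#' @slot unpaired numeric c(shape, scale).
#' @slot helixEnd numeric c(shape, scale).
#' @slot helixInterior numeric c(shape, scale).
#' @export
setClass("ReactivityDistributions",
         representation(unpaired = "numeric", helixEnd = "numeric",
                        helixInterior = "numeric"))

setValidity("ReactivityDistributions", function(object) {
  for (nm in c("unpaired", "helixEnd", "helixInterior")) {
    p <- slot(object, nm)
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0))
      return(sprintf("%s must be c(shape, scale), both positive", nm))
  }
  m <- c(prod(object@unpaired), prod(object@helixEnd),
         prod(object@helixInterior))
  if (!(m[1L] > m[2L] && m[2L] >= m[3L]))
    return("class means must satisfy unpaired > helixEnd >= helixInterior")
  TRUE
})
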