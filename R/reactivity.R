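#' Default reactivity distributions
#'
#' Class-conditional distributions of normalized SHAPE reactivity for the
#' three structural contexts. Each is a gamma distribution c(shape, scale);
#' with shape <= 1 the density peaks at 0 with a right tail. Defaults give
#' class means 0.80 (unpaired), 0.28 (helix end) and 0.15 (helix interior),
#' reproducing the qualitative ordering of empirical SHAPE histograms:
#' all three classes peak near zero, but the unpaired class skews far
#' towards high reactivities and helix ends skew slightly higher than
#' helix interiors.
#'
#' @param unpaired,helixEnd,helixInterior numeric c(shape, scale).
#' @return a \linkS4class{ReactivityDistributions}.
#' @export
reactivityDistributions <- function(unpaired = c(1.0, 0.80),
                                    helixEnd = c(0.8, 0.35),
                                    helixInterior = c(0.6, 0.25)) {
  new("ReactivityDistributions", unpaired = unpaired, helixEnd = helixEnd,
      helixInterior = helixInterior)
}

#' @describeIn reactivityDistributions mean reactivity of each class,
#'   named numeric (unpaired, helixEnd, helixInterior).
#' @param x a \code{ReactivityDistributions}.
#' @export
setMethod("classMeans", "ReactivityDistributions", function(x) {
  c(unpaired = prod(x@unpaired), helixEnd = prod(x@helixEnd),
    helixInterior = prod(x@helixInterior))
})

#' Draw reactivities from a class distribution
#'
#' @param dists a \linkS4class{ReactivityDistributions}.
#' @param class "unpaired", "helixEnd" or "helixInterior".
#' @param n number of draws.
#' @return numeric vector of reactivities.
#' @export
drawReactivity <- function(dists, class, n = 1L) {
  p <- slot(dists, match.arg(class,
                             c("unpaired", "helixEnd", "helixInterior")))
  stats::rgamma(n, shape = p[1L], scale = p[2L])
}

CLASS_LEVELS <- c("UNPAIRED", "HELIX_END", "HELIX_INTERIOR")

#' Classify nucleotides by structural context
#'
#' Unpaired nucleotides are UNPAIRED. A paired nucleotide i with partner j
#' is HELIX_INTERIOR only when both flanking pairs (i-1, j+1) and
#' (i+1, j-1) are present (it sits in two base-pair stacks); otherwise it
#' is HELIX_END. An isolated pair therefore classifies both partners as
#' HELIX_END.
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return factor of length seqLength(s) with levels UNPAIRED, HELIX_END,
#'   HELIX_INTERIOR.
#' @export
classifyNucleotides <- function(s) {
  p <- partnerVector(s)
  n <- s@seqLength
  cls <- rep("UNPAIRED", n)
  paired <- which(p > 0L)
  for (i in paired) {
    j <- p[i]
    lo <- min(i, j); hi <- max(i, j)
    inner <- lo + 1L <= n && hi - 1L >= 1L && p[lo + 1L] == hi - 1L
    outer <- lo - 1L >= 1L && hi + 1L <= n && p[lo - 1L] == hi + 1L
    cls[i] <- if (inner && outer) "HELIX_INTERIOR" else "HELIX_END"
  }
  factor(cls, levels = CLASS_LEVELS)
}

classFrequencies <- function(ens) {
  ## per-nucleotide frequency of each class across the ensemble; rows =
  ## nucleotides, columns = UNPAIRED, HELIX_END, HELIX_INTERIOR
  N <- seqLength(ens)
  counts <- matrix(0, N, 3L, dimnames = list(NULL, CLASS_LEVELS))
  for (s in ens@structures) {
    cl <- as.integer(classifyNucleotides(s))
    counts[cbind(seq_len(N), cl)] <- counts[cbind(seq_len(N), cl)] + 1
  }
  counts / length(ens@structures)
}

#' Estimate ensemble-averaged SHAPE reactivities
#'
#' For every nucleotide, the reactivity expected from the structure
#' ensemble. In \code{"expectation"} mode (default, deterministic) this is
#' the class-frequency-weighted sum of the class means — the large-sample
#' limit. In \code{"montecarlo"} mode each nucleotide in each sampled
#' structure receives one random draw from its class distribution and the
#' draws are averaged across structures.
#'
#' @param ens a \linkS4class{StructureEnsemble}.
#' @param dists a \linkS4class{ReactivityDistributions}.
#' @param mode "expectation" or "montecarlo".
#' @param seed RNG seed (montecarlo mode only).
#' @return a \linkS4class{ReactivityProfile} of estimated reactivities.
#' @export
estimateRcalc <- function(ens, dists = reactivityDistributions(),
                          mode = c("expectation", "montecarlo"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (length(ens@structures) < 1L) stop("empty ensemble")
  if (mode == "expectation") {
    f <- classFrequencies(ens)
    reactivityProfile(as.numeric(f %*% classMeans(dists)))
  } else {
    set.seed(seed)
    N <- seqLength(ens)
    total <- numeric(N)
    for (s in ens@structures) {
      cl <- classifyNucleotides(s)
      draw <- numeric(N)
      for (lv in CLASS_LEVELS) {
        idx <- which(cl == lv)
        if (length(idx))
          draw[idx] <- drawReactivity(dists,
                                      c("unpaired", "helixEnd",
                                        "helixInterior")[match(lv, CLASS_LEVELS)],
                                      length(idx))
      }
      total <- total + draw
    }
    reactivityProfile(total / length(ens@structures))
  }
}

#' Simulate a SHAPE profile from a mixture of structures
#'
#' The forward model of a probing experiment on a conformational mixture:
#' the observed reactivity of a nucleotide is the population-weighted mean
#' of the reactivity it would show in each conformation. Per replicate,
#' one value is drawn from the class distribution of the nucleotide in
#' each structure; the profile is the population-weighted mean averaged
#' over replicates. This is the fixture generator for all end-to-end
#' tests.
#'
#' @param mixture list of \code{list(structure =, population =)} entries;
#'   populations must be non-negative and sum to 1 (tolerance 1e-6).
#' @param dists a \linkS4class{ReactivityDistributions}.
#' @param seed RNG seed.
#' @param replicates number of independent draws averaged per nucleotide;
#'   more replicates mean a less noisy profile.
#' @return a \linkS4class{ReactivityProfile}.
#' @export
simulateShape <- function(mixture, dists = reactivityDistributions(),
                          seed = 1L, replicates = 50L) {
  pops <- vapply(mixture, function(m) m$population, numeric(1L))
  if (any(pops < 0)) stop("populations must be non-negative")
  if (abs(sum(pops) - 1) > 1e-6) stop("populations must sum to 1")
  structs <- lapply(mixture, function(m) m$structure)
  lens <- vapply(structs, seqLength, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("all mixture structures must share one length")
  N <- lens[1L]
  classes <- lapply(structs, classifyNucleotides)
  set.seed(seed)
  acc <- numeric(N)
  for (r in seq_len(replicates)) {
    prof <- numeric(N)
    for (m in seq_along(structs)) {
      cl <- classes[[m]]
      draw <- numeric(N)
      for (lv in seq_along(CLASS_LEVELS)) {
        idx <- which(as.integer(cl) == lv)
        if (length(idx))
          draw[idx] <- drawReactivity(dists,
                                      c("unpaired", "helixEnd",
                                        "helixInterior")[lv], length(idx))
      }
      prof <- prof + pops[m] * draw
    }
    acc <- acc + prof
  }
  reactivityProfile(acc / replicates)
}
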