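## shared argument validation + call into the compiled engine
callEngine <- function(seq, params, consts, bonus, nSamples) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  if (n < params@minHairpin + 2L)
    stop("sequence too short: need at least ", params@minHairpin + 2L,
         " nucleotides")
  if (is.null(bonus)) bonus <- numeric(n)
  if (length(bonus) != n)
    stop("bonus length (", length(bonus), ") does not match sequence (",
         n, ")")
  if (any(!is.finite(bonus))) stop("bonus vector must be finite")
  pen <- loopPenaltyVectors(params, n)
  .foldEngine(seqToInt(seq), unname(params@stack), pen$hairpin,
              pen$internal, params@multibranch, params@minHairpin,
              as.numeric(bonus), consts@kT, as.integer(nSamples))
}

#' Partition function and base-pair probabilities
#'
#' Computes the Boltzmann partition function over all pseudoknot-free
#' secondary structures of \code{seq} under the nearest-neighbor model,
#' optionally restrained by a per-nucleotide pseudo-free-energy
#' \code{bonus} added to every base-pair stack a nucleotide belongs to.
#' Returns the matrix of base-pair probabilities and the ensemble free
#' energy -kT ln Z.
#'
#' @param seq RNA sequence (ACGU; lowercase and T accepted).
#' @param params a \linkS4class{NearestNeighborParams}.
#' @param consts a \linkS4class{ThermoConstants}.
#' @param bonus numeric per-nucleotide bonus vector (kcal/mol) or NULL.
#' @return list with \code{probs} (a \linkS4class{PairProbabilityMatrix})
#'   and \code{freeEnergy} (kcal/mol).
#' @examples
#' pf <- partitionFunction("GGGGAAAACCCC")
#' pf$freeEnergy
#' @export
partitionFunction <- function(seq, params = loadParams(),
                              consts = thermoConstants(), bonus = NULL) {
  res <- callEngine(seq, params, consts, bonus, 0L)
  list(probs = pairProbabilityMatrix(res$P),
       freeEnergy = -consts@kT * res$lnZ)
}

#' Stochastic sample from the Boltzmann ensemble
#'
#' Draws \code{n} i.i.d. structures with probability equal to their
#' Boltzmann probability at equilibrium, by traceback through the
#' partition-function tables. Reproducible given \code{seed}.
#'
#' @inheritParams partitionFunction
#' @param n sample size (default 10000, the size used for reactivity
#'   estimation; clustering uses 1000).
#' @param seed integer RNG seed.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
stochasticSample <- function(seq, n = 10000L, seed = 1L,
                             params = loadParams(),
                             consts = thermoConstants(), bonus = NULL) {
  if (n < 1L) stop("sample size must be >= 1")
  set.seed(seed)
  res <- callEngine(seq, params, consts, bonus, n)
  N <- ncol(res$samples)
  structs <- lapply(seq_len(nrow(res$samples)), function(r) {
    structureFromPartner(res$samples[r, ])
  })
  structureEnsemble(structs, seed = seed,
                    source = if (is.null(bonus) || all(bonus == 0))
                      "unrestrained" else "restrained")
}

#' Pair frequencies of an ensemble
#'
#' Empirical base-pair probabilities: the fraction of structures in the
#' ensemble that contain each pair.
#'
#' @param ens a \linkS4class{StructureEnsemble}.
#' @return a \linkS4class{PairProbabilityMatrix}.
#' @export
pairFrequencies <- function(ens) {
  if (length(ens@structures) < 1L) stop("empty ensemble")
  N <- seqLength(ens)
  M <- matrix(0, N, N)
  for (s in ens@structures) {
    bp <- s@pairs
    if (nrow(bp)) M[bp] <- M[bp] + 1
  }
  pairProbabilityMatrix(M / length(ens@structures))
}

#' Maximum expected accuracy structure
#'
#' Finds the pseudoknot-free structure maximizing
#' \code{sum(2 * gamma * P[i,j])} over its pairs plus
#' \code{sum(1 - totalPairProb[i])} over its unpaired nucleotides, by
#' dynamic programming. Candidate pairs are the entries of P with positive
#' probability that enclose at least \code{minHairpin} nucleotides.
#'
#' @param P a \linkS4class{PairProbabilityMatrix}.
#' @param gamma weight of paired versus unpaired accuracy (default 1).
#' @param minHairpin minimum enclosed nucleotides per pair.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
meaStructure <- function(P, gamma = 1, minHairpin = MIN_HAIRPIN) {
  pm <- pairProbs(P)
  N <- nrow(pm)
  q <- 1 - (rowSums(pm) + colSums(pm))  # unpaired probability
  M <- matrix(0, N + 1L, N + 1L)        # M[i, j+1] = score of region i..j
  choice <- matrix(0L, N, N)            # 0 = i unpaired, k = pair (i,k)
  for (d in 0:(N - 1L)) {
    for (i in seq_len(N - d)) {
      j <- i + d
      best <- (if (i + 1L <= j) M[i + 1L, j + 1L] else 0) + q[i]
      pick <- 0L
      ks <- seq.int(i + minHairpin + 1L, j)
      if (i + minHairpin + 1L <= j) {
        for (k in ks) {
          if (pm[i, k] <= 0) next
          sc <- 2 * gamma * pm[i, k] +
            (if (i + 1L <= k - 1L) M[i + 1L, k] else 0) +
            (if (k + 1L <= j) M[k + 1L, j + 1L] else 0)
          if (sc > best + 1e-12) { best <- sc; pick <- k }
        }
      }
      M[i, j + 1L] <- best
      choice[i, j] <- pick
    }
  }
  pairs <- matrix(integer(0L), ncol = 2L)
  stack <- list(c(1L, N))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (i > j) next
    k <- choice[i, j]
    if (k == 0L) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else {
      pairs <- rbind(pairs, c(i, k))
      stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
      stack[[length(stack) + 1L]] <- c(k + 1L, j)
    }
  }
  secondaryStructure(N, pairs)
}
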