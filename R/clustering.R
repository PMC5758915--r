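#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two base-pair sets: the number
#' of pairs present in exactly one structure. This is the standard
#' structure metric in the field and equals the squared Euclidean distance
#' between the binary pair-indicator embeddings.
#'
#' @param a,b \linkS4class{SecondaryStructure} of equal length.
#' @return non-negative integer.
#' @export
bpDistance <- function(a, b) {
  if (a@seqLength != b@seqLength)
    stop("structures have different lengths: ", a@seqLength, " vs ",
         b@seqLength)
  n <- a@seqLength + 1L
  ka <- a@pairs[, 1L] * n + a@pairs[, 2L]
  kb <- b@pairs[, 1L] * n + b@pairs[, 2L]
  length(ka) + length(kb) - 2L * length(intersect(ka, kb))
}

## n x n matrix of pairwise base-pair distances over an ensemble, via the
## binary pair-indicator embedding (Hamming = squared Euclidean)
bpDistanceMatrix <- function(ens) {
  n <- length(ens@structures)
  N <- seqLength(ens)
  keys <- lapply(ens@structures, function(s)
    s@pairs[, 1L] * (N + 1L) + s@pairs[, 2L])
  allKeys <- sort(unique(unlist(keys)))
  X <- matrix(0, n, length(allKeys))
  for (i in seq_len(n)) X[i, match(keys[[i]], allKeys)] <- 1
  npairs <- rowSums(X)
  G <- tcrossprod(X)
  D <- outer(npairs, npairs, "+") - 2 * G
  D[D < 0] <- 0
  D
}

## Calinski-Harabasz index from a squared-Euclidean distance matrix
chFromD2 <- function(D2, assignments) {
  n <- nrow(D2)
  k <- length(unique(assignments))
  tot <- sum(D2) / (2 * n)
  W <- 0
  for (g in unique(assignments)) {
    idx <- which(assignments == g)
    W <- W + sum(D2[idx, idx, drop = FALSE]) / (2 * length(idx))
  }
  B <- tot - W
  if (W <= 1e-12) return(if (B > 1e-12) Inf else NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Cluster a Boltzmann sample of structures
#'
#' Partitions the sampled structures by k-medoids (\code{cluster::pam}) on
#' the base-pair distance matrix, for each candidate k in 2..kMax, and
#' picks the k maximizing the Calinski-Harabasz index
#' CH(k) = [B(k)/(k-1)] / [W(k)/(n-k)] computed on the binary
#' pair-indicator embedding. Duplicated structures are kept — they carry
#' population weight. Candidate partitions containing a cluster smaller
#' than \code{minClusterFrac} of the sample are rejected during k
#' selection: a Boltzmann sample of a discrete ensemble repeats a few
#' structures many times, and without this guard the CH index can always
#' be driven up by peeling off near-duplicate micro-clusters far below
#' any interpretable population. Falls back to a single cluster when the
#' sample is (near-)homogeneous: fewer than two distinct structures,
#' total dispersion below \code{dispersionFloor}, best CH below
#' \code{chFloor}, or every candidate partition rejected.
#'
#' @param ens a \linkS4class{StructureEnsemble} with >= 2 members.
#' @param kMax largest number of clusters considered (default 10).
#' @param chFloor minimum CH value required to split (default 0).
#' @param dispersionFloor minimum mean squared dispersion required to
#'   split (default 1e-8).
#' @param minClusterFrac smallest admissible cluster, as a fraction of
#'   the sample (default 0.02, the population reporting floor).
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterStructures <- function(ens, kMax = 10L, chFloor = 0,
                              dispersionFloor = 1e-8,
                              minClusterFrac = 0.02) {
  n <- length(ens@structures)
  if (n < 2L) stop("need at least 2 structures to cluster")
  if (kMax < 2L) stop("kMax must be >= 2")
  D2 <- bpDistanceMatrix(ens)
  oneCluster <- function() new("ClusterResult",
                               assignments = rep(1L, n), k = 1L,
                               chScores = c(`1` = NA_real_),
                               distanceMetric = "basepair")
  nDistinct <- nrow(unique(D2))
  if (nDistinct < 2L || sum(D2) / (2 * n * n) < dispersionFloor)
    return(oneCluster())
  dd <- stats::as.dist(D2)
  ks <- 2L:min(kMax, nDistinct)
  ch <- rep(NA_real_, length(ks))
  parts <- vector("list", length(ks))
  for (t in seq_along(ks)) {
    fit <- cluster::pam(dd, k = ks[t], diss = TRUE, cluster.only = TRUE)
    parts[[t]] <- as.integer(fit)
    if (min(tabulate(parts[[t]], nbins = ks[t])) < minClusterFrac * n)
      next  # partition creates a sub-floor micro-cluster; not a candidate
    ch[t] <- chFromD2(D2, parts[[t]])
  }
  names(ch) <- ks
  if (all(is.na(ch)) || max(ch, na.rm = TRUE) < chFloor)
    return(oneCluster())
  best <- which.max(ch)
  new("ClusterResult", assignments = parts[[best]], k = ks[best],
      chScores = ch, distanceMetric = "basepair")
}

#' Centroid structure of a cluster
#'
#' The structure containing exactly the pairs whose frequency among the
#' cluster members exceeds 0.5 (strict). Marginally, two conflicting pairs
#' can each exceed 0.5; conflicts (shared nucleotide or crossing) are
#' resolved by keeping pairs in order of descending frequency, then
#' lexicographic (i, j), dropping later conflicting pairs, and the result
#' is validated as a legal structure.
#'
#' @param structs list of \linkS4class{SecondaryStructure} (non-empty) or
#'   a \linkS4class{StructureEnsemble}.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
centroidStructure <- function(structs) {
  if (is(structs, "StructureEnsemble")) structs <- structs@structures
  if (!length(structs)) stop("empty cluster")
  N <- structs[[1L]]@seqLength
  M <- matrix(0, N, N)
  for (s in structs) {
    bp <- s@pairs
    if (nrow(bp)) M[bp] <- M[bp] + 1
  }
  fr <- M / length(structs)
  idx <- which(fr > 0.5, arr.ind = TRUE)
  if (!nrow(idx)) return(secondaryStructure(N))
  f <- fr[idx]
  o <- order(-f, idx[, 1L], idx[, 2L])
  idx <- idx[o, , drop = FALSE]
  kept <- matrix(integer(0L), ncol = 2L)
  used <- logical(N)
  crosses <- function(i, j, kp) {
    if (!nrow(kp)) return(FALSE)
    any((kp[, 1L] < i & i < kp[, 2L] & kp[, 2L] < j) |
        (i < kp[, 1L] & kp[, 1L] < j & j < kp[, 2L]))
  }
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (used[i] || used[j] || crosses(i, j, kept)) next
    kept <- rbind(kept, c(i, j))
    used[c(i, j)] <- TRUE
  }
  secondaryStructure(N, kept)
}

#' Shannon entropy of base pairing
#'
#' Per-nucleotide ensemble diversity:
#' \deqn{S = -\sum_{i<j} P_{i,j} \log_{10} P_{i,j} / N}
#' summed over all canonical pairs, with 0 log 0 = 0.
#'
#' @param x a \linkS4class{PairProbabilityMatrix}, or an
#'   \linkS4class{EnsembleModel} (returns its stored entropy).
#' @param ... unused.
#' @return non-negative numeric scalar.
#' @export
setMethod("shannonEntropy", "PairProbabilityMatrix", function(x, ...) {
  P <- pairProbs(x)
  pos <- P[P > 0]
  if (!length(pos)) return(0)
  -sum(pos * log10(pos)) / nrow(P)
})

#' @rdname shannonEntropy-PairProbabilityMatrix-method
#' @export
setMethod("shannonEntropy", "EnsembleModel", function(x, ...)
  x@shannonEntropy)

#' Assemble an EnsembleModel from a clustered sample
#'
#' Computes per-cluster centroids, populations (cluster fraction of the
#' sample) and within-cluster pair probabilities, ordered by descending
#' population. Conformations below \code{minPopulation} are kept but
#' flagged.
#'
#' @param ens the clustered \linkS4class{StructureEnsemble}.
#' @param clus the matching \linkS4class{ClusterResult}.
#' @param entropy Shannon entropy of the (restrained) ensemble's pair
#'   probabilities.
#' @param minPopulation flagging floor for small clusters (default 0.02).
#' @return an \linkS4class{EnsembleModel}.
#' @export
buildEnsembleModel <- function(ens, clus, entropy,
                               minPopulation = 0.02) {
  n <- length(ens@structures)
  ord <- order(-tabulate(clus@assignments, nbins = clus@k))
  cents <- list(); pops <- numeric(0L); pps <- list()
  for (g in ord) {
    idx <- which(clus@assignments == g)
    if (!length(idx)) next
    sub <- structureEnsemble(ens@structures[idx], seed = ens@seed,
                             source = ens@source)
    cents[[length(cents) + 1L]] <- centroidStructure(sub)
    pops <- c(pops, length(idx) / n)
    pps[[length(pps) + 1L]] <- pairFrequencies(sub)
  }
  new("EnsembleModel", centroids = cents, populations = pops,
      clusterPairProbs = pps, shannonEntropy = entropy,
      chScores = clus@chScores, lowPopulation = pops < minPopulation)
}

#' Map predicted conformations onto reference structures
#'
#' Each centroid is assigned to the reference structure maximizing the
#' geometric-mean accuracy (sensitivity x PPV, slipped-pair tolerance) if
#' that accuracy reaches \code{accuracyThreshold}; otherwise it is labeled
#' "other". Multiple clusters mapping to one reference are treated as the
#' same conformation and their populations are summed. Ties between
#' references go to the first by reference order (a message is emitted).
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param references list of \linkS4class{SecondaryStructure}.
#' @param accuracyThreshold minimum geometric-mean accuracy (default 0.8).
#' @param slip use slipped-pair tolerance in the comparison (default TRUE).
#' @return list with \code{assignments} (data.frame: conformation,
#'   reference index or NA for "other", accuracy, population) and
#'   \code{populations} (named vector per reference plus "other").
#' @export
mergeEquivalentClusters <- function(model, references,
                                    accuracyThreshold = 0.8, slip = TRUE) {
  k <- length(model@centroids)
  refIdx <- integer(k); acc <- numeric(k)
  for (i in seq_len(k)) {
    gm <- vapply(references, function(ref)
      sensitivityPPV(model@centroids[[i]], ref, slip = slip)$geometric_mean,
      numeric(1L))
    gm[is.na(gm)] <- 0
    best <- which.max(gm)
    if (sum(gm == gm[best]) > 1L)
      message("centroid ", i, " is equidistant from multiple references; ",
              "assigned to the first")
    if (gm[best] >= accuracyThreshold) {
      refIdx[i] <- best; acc[i] <- gm[best]
    } else {
      refIdx[i] <- NA_integer_; acc[i] <- gm[best]
    }
  }
  pops <- stats::setNames(numeric(length(references) + 1L),
                          c(paste0("reference", seq_along(references)),
                            "other"))
  for (i in seq_len(k)) {
    slot_ <- if (is.na(refIdx[i])) length(pops) else refIdx[i]
    pops[slot_] <- pops[slot_] + model@populations[i]
  }
  list(assignments = data.frame(conformation = seq_len(k),
                                reference = refIdx, accuracy = acc,
                                population = model@populations),
       populations = pops)
}
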