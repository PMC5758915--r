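# Independent brute-force oracles used to check the dynamic-programming
# engine: exhaustive enumeration of all pseudoknot-free structures with
# Boltzmann weighting through the loop-decomposition energy evaluator.

canPairMatrix <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  codes <- outer(ch, ch, paste0)
  matrix(codes %in% c("AU", "UA", "GC", "CG", "GU", "UG"), n, n)
}

## all pseudoknot-free pair sets over positions 1..n, allowed by canMat,
## respecting the minimum hairpin span
enumStructures <- function(n, canMat, minH = 3L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0L), ncol = 2L)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)
    if (i + minH + 1L <= j) {
      for (k in (i + minH + 1L):j) {
        if (!canMat[i, k]) next
        for (a in rec(i + 1L, k - 1L)) for (b in rec(k + 1L, j))
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

## exact Boltzmann statistics by enumeration + structureEnergy
boltzmannOracle <- function(seq, bonus = NULL, params = loadParams(),
                            consts = thermoConstants()) {
  n <- nchar(seq)
  structs <- enumStructures(n, canPairMatrix(seq), params@minHairpin)
  E <- vapply(structs, function(bp)
    structureEnergy(seq, secondaryStructure(n, bp), params, bonus),
    numeric(1L))
  w <- exp(-E / consts@kT)
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    bp <- structs[[s]]
    if (nrow(bp)) P[bp] <- P[bp] + w[s]
  }
  list(P = P / Z, freeEnergy = -consts@kT * log(Z),
       structs = structs, probs = w / Z)
}

## brute-force maximizer of the expected-accuracy objective
meaOracle <- function(P, gamma = 1, minH = 3L) {
  pm <- pairProbs(P)
  n <- nrow(pm)
  q <- 1 - (rowSums(pm) + colSums(pm))
  structs <- enumStructures(n, pm > 0, minH)
  score <- vapply(structs, function(bp) {
    paired <- as.vector(bp)
    sum(2 * gamma * pm[bp]) + sum(q[setdiff(seq_len(n), paired)])
  }, numeric(1L))
  list(best = max(score), structs = structs, score = score)
}

meaScore <- function(P, s, gamma = 1) {
  pm <- pairProbs(P)
  q <- 1 - (rowSums(pm) + colSums(pm))
  bp <- basePairs(s)
  sum(2 * gamma * pm[bp]) + sum(q[setdiff(seq_len(nrow(pm)), as.vector(bp))])
}

randomSequence <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## random valid structure: repeatedly try to add random compatible pairs
randomStructure <- function(n, canMat = NULL, minH = 3L, tries = 30L) {
  pairs <- matrix(integer(0L), ncol = 2L)
  used <- logical(n)
  crosses <- function(i, j) {
    if (!nrow(pairs)) return(FALSE)
    any((pairs[, 1L] < i & i < pairs[, 2L] & pairs[, 2L] < j) |
        (i < pairs[, 1L] & pairs[, 1L] < j & j < pairs[, 2L]))
  }
  for (t in seq_len(tries)) {
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (j - i <= minH || used[i] || used[j] || crosses(i, j)) next
    if (!is.null(canMat) && !canMat[i, j]) next
    pairs <- rbind(pairs, c(i, j))
    used[c(i, j)] <- TRUE
  }
  secondaryStructure(n, pairs)
}
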