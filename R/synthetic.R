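#' Designed bistable sequence with two known conformations
#'
#' A 23-nt sequence of the form P-loop-Q-loop-R where Q is the reverse
#' complement of P and R repeats P, so the central segment Q can pair
#' either upstream (hairpin A, pairs 1:5 with 14:10) or downstream
#' (hairpin B, pairs 10:14 with 23:19) but not both. The two conformations
#' differ by 10 base pairs and have similar free energies, making the
#' sequence a two-state switch whose populations respond to probing
#' restraints. Used as the end-to-end recovery fixture: simulate a SHAPE
#' profile from a known mixture of A and B, then test whether the pipeline
#' recovers both conformations and their ratio.
#'
#' @return list with \code{seq}, \code{structures} (list of the two
#'   \linkS4class{SecondaryStructure}: hairpin A then hairpin B) and
#'   \code{name}.
#' @examples
#' fx <- bistableExample()
#' dotBracket(fx$structures[[1]])
#' @export
bistableExample <- function() {
  seq <- "GGAGCAAAAGCUCCAAAAGGAGC"
  hairpinA <- secondaryStructure(23L, cbind(1:5, 14:10))
  hairpinB <- secondaryStructure(23L, cbind(10:14, 23:19))
  checkStructureSequence(seq, hairpinA)
  checkStructureSequence(seq, hairpinB)
  list(seq = seq, structures = list(A = hairpinA, B = hairpinB),
       name = "bistable23")
}

#' Planted-partition structure sample
#'
#' Builds a sample of structures drawn from well-separated groups, for
#' testing the clustering stage: each group has a base structure (helices
#' in distant registers, pairwise base-pair distance >= 10) and members
#' are the base structure with up to \code{wobble} randomly chosen pairs
#' removed, emulating thermal fraying (within-group distance <= 2 at the
#' default wobble of 1). Group sizes give the planted cluster sizes;
#' member order is interleaved deterministically.
#'
#' @param sizes integer vector of group sizes (1 to 3 groups).
#' @param wobble maximum number of pairs removed per member (default 1).
#' @param seed RNG seed for the wobble draws.
#' @return list with \code{ensemble} (a \linkS4class{StructureEnsemble})
#'   and \code{labels} (the planted group of each member).
#' @export
plantedPartitionSample <- function(sizes = c(500L, 300L, 200L),
                                   wobble = 1L, seed = 1L) {
  if (length(sizes) < 1L || length(sizes) > 3L)
    stop("1 to 3 group sizes supported")
  N <- 60L
  bases <- list(
    secondaryStructure(N, cbind(1:8, 20:13)),
    secondaryStructure(N, cbind(25:32, 44:37)),
    secondaryStructure(N, cbind(c(1:6, 49:52), c(60:55, 12:9)))
  )[seq_along(sizes)]
  set.seed(seed)
  structs <- list(); labels <- integer(0L)
  for (g in seq_along(sizes)) {
    bp <- bases[[g]]@pairs
    for (m in seq_len(sizes[g])) {
      drop <- sample.int(wobble + 1L, 1L) - 1L
      keep <- if (drop == 0L) bp
              else bp[-sample.int(nrow(bp), drop), , drop = FALSE]
      structs[[length(structs) + 1L]] <- secondaryStructure(N, keep)
      labels <- c(labels, g)
    }
  }
  o <- order(rep(seq_len(max(sizes)), times = length(sizes))[
    sequence(sizes)])  # interleave groups
  list(ensemble = structureEnsemble(structs[o], seed = seed),
       labels = labels[o])
}
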