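#' Construct a secondary structure
#'
#' @param seqLength number of nucleotides.
#' @param pairs two-column matrix (or empty) of 1-based base pairs; rows
#'   may be given in any order and with i > j (they are normalized).
#' @return a validated \linkS4class{SecondaryStructure}.
#' @examples
#' secondaryStructure(10, cbind(c(1, 2), c(10, 9)))
#' @export
secondaryStructure <- function(seqLength, pairs = NULL) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(0L), ncol = 2L)
  pairs <- matrix(as.integer(round(pairs)), ncol = 2L)
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  if (nrow(pairs) > 1L)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  new("SecondaryStructure", seqLength = as.integer(seqLength), pairs = pairs)
}

#' @describeIn secondaryStructure base pairs as a two-column matrix,
#'   ordered by the 5' partner.
#' @param x a \code{SecondaryStructure}.
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @describeIn secondaryStructure sequence length.
#' @export
setMethod("seqLength", "SecondaryStructure", function(x) x@seqLength)

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure of %d nt with %d base pairs\n",
              object@seqLength, nrow(object@pairs)))
  cat(" ", dotBracket(object), "\n", sep = "")
})

#' Partner vector of a structure
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return integer vector p with p[i] = partner of i, 0 if unpaired.
#' @export
partnerVector <- function(s) {
  p <- integer(s@seqLength)
  bp <- s@pairs
  p[bp[, 1L]] <- bp[, 2L]
  p[bp[, 2L]] <- bp[, 1L]
  p
}

structureFromPartner <- function(partner) {
  i <- which(partner > seq_along(partner))
  secondaryStructure(length(partner), cbind(i, partner[i]))
}

#' Dot-bracket rendering of a structure
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return a character scalar of '.', '(' and ')'.
#' @export
dotBracket <- function(s) {
  ch <- rep(".", s@seqLength)
  ch[s@pairs[, 1L]] <- "("
  ch[s@pairs[, 2L]] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation
#'
#' @param db character scalar of '.', '(' and ')'.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
parseDotBracket <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop("invalid dot-bracket character at position ", bad[1L])
  stack <- integer(0L)
  pairs <- matrix(integer(0L), ncol = 2L)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1L])
  secondaryStructure(length(ch), pairs)
}

#' Construct a reactivity profile
#'
#' @param values numeric vector of normalized SHAPE reactivities; use
#'   \code{NA} for missing measurements.
#' @return a \linkS4class{ReactivityProfile}.
#' @export
reactivityProfile <- function(values) {
  new("ReactivityProfile", values = as.numeric(values))
}

#' @describeIn reactivityProfile reactivity values (NA where missing).
#' @param x a \code{ReactivityProfile}.
#' @export
setMethod("reactivities", "ReactivityProfile", function(x) x@values)

#' @describeIn reactivityProfile logical mask, TRUE where data is missing.
#' @export
setMethod("missingMask", "ReactivityProfile", function(x) is.na(x@values))

setMethod("seqLength", "ReactivityProfile", function(x) length(x@values))

setMethod("show", "ReactivityProfile", function(object) {
  n <- length(object@values)
  cat(sprintf("ReactivityProfile of %d nt (%d missing)\n",
              n, sum(is.na(object@values))))
})

#' Construct a pair-probability matrix
#'
#' @param probs square numeric matrix; only the upper triangle is kept.
#' @return a \linkS4class{PairProbabilityMatrix}.
#' @export
pairProbabilityMatrix <- function(probs) {
  probs[lower.tri(probs, diag = TRUE)] <- 0
  probs[probs < 0 & probs > -1e-12] <- 0  # clip DP round-off
  probs[probs > 1 & probs < 1 + 1e-9] <- 1
  dimnames(probs) <- NULL
  new("PairProbabilityMatrix", probs = probs)
}

#' @describeIn pairProbabilityMatrix the probability matrix.
#' @param x a \code{PairProbabilityMatrix}.
#' @export
setMethod("pairProbs", "PairProbabilityMatrix", function(x) x@probs)

setMethod("seqLength", "PairProbabilityMatrix", function(x) nrow(x@probs))

setMethod("show", "PairProbabilityMatrix", function(object) {
  P <- object@probs
  cat(sprintf("PairProbabilityMatrix %d x %d, %d entries > 0.01\n",
              nrow(P), ncol(P), sum(P > 0.01)))
})

#' Construct a structure ensemble
#'
#' @param structures list of \linkS4class{SecondaryStructure} sharing one
#'   length (repetition allowed; repeats carry population weight).
#' @param seed integer seed used to draw the sample (NA if unknown).
#' @param source "unrestrained" or "restrained".
#' @return a \linkS4class{StructureEnsemble}.
#' @export
structureEnsemble <- function(structures, seed = NA_integer_,
                              source = "unrestrained") {
  new("StructureEnsemble", structures = structures,
      seed = as.integer(seed), source = source)
}

#' @describeIn structureEnsemble list of member structures.
#' @param x a \code{StructureEnsemble}.
#' @export
setMethod("structures", "StructureEnsemble", function(x) x@structures)

setMethod("seqLength", "StructureEnsemble",
          function(x) x@structures[[1L]]@seqLength)

setMethod("length", "StructureEnsemble", function(x) length(x@structures))

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d structures of %d nt (%s, seed %s)\n",
              length(object@structures), seqLength(object),
              object@source, object@seed))
})

setMethod("centroids", "EnsembleModel", function(x) x@centroids)
setMethod("populations", "EnsembleModel", function(x) x@populations)

setMethod("show", "EnsembleModel", function(object) {
  k <- length(object@centroids)
  cat(sprintf("EnsembleModel: %d conformation%s, Shannon entropy %.4f\n",
              k, if (k == 1L) "" else "s", object@shannonEntropy))
  for (i in seq_len(k)) {
    cat(sprintf("  [%d] population %.3f%s  %s\n", i, object@populations[i],
                if (object@lowPopulation[i]) " (low)" else "",
                dotBracket(object@centroids[[i]])))
  }
})

## --- internal sequence helpers -------------------------------------------

#' Normalize an RNA sequence string
#'
#' Uppercases, maps T to U, validates the ACGU alphabet.
#' @param seq character scalar.
#' @return character scalar over ACGU.
#' @export
normalizeSequence <- function(seq) {
  s <- chartr("acgut", "ACGUU", seq)
  s <- gsub("T", "U", toupper(s), fixed = TRUE)
  ch <- strsplit(s, "")[[1L]]
  bad <- which(!ch %in% c("A", "C", "G", "U"))
  if (length(bad))
    stop("invalid sequence character '", ch[bad[1L]],
         "' at position ", bad[1L])
  s
}

seqToInt <- function(seq) {
  match(strsplit(seq, "")[[1L]], c("A", "C", "G", "U")) - 1L
}

## canonical pair code of two bases given as characters, NA if not allowed
pairCode <- function(a, b) {
  code <- paste0(a, b)
  ifelse(code %in% PAIR_CODES, code, NA_character_)
}

#' Check whether a structure is compatible with a sequence
#'
#' All pairs must be canonical (AU, UA, GC, CG, GU, UG) for the sequence.
#' @param seq RNA sequence string.
#' @param s a \linkS4class{SecondaryStructure}.
#' @return TRUE, or an error describing the first offending pair.
#' @export
checkStructureSequence <- function(seq, s) {
  seq <- normalizeSequence(seq)
  if (nchar(seq) != s@seqLength)
    stop("sequence length (", nchar(seq), ") does not match structure (",
         s@seqLength, ")")
  ch <- strsplit(seq, "")[[1L]]
  bp <- s@pairs
  if (nrow(bp)) {
    codes <- paste0(ch[bp[, 1L]], ch[bp[, 2L]])
    bad <- which(!codes %in% PAIR_CODES)
    if (length(bad))
      stop("disallowed pair ", codes[bad[1L]], " at (", bp[bad[1L], 1L],
           ",", bp[bad[1L], 2L], ")")
  }
  TRUE
}
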