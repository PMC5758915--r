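#' Thermodynamic constants
#'
#' @param T absolute temperature in K; default 310.15 (37 C). The gas
#'   constant is 1.9872e-3 kcal/(mol K); kT is derived as R*T.
#' @return a \linkS4class{ThermoConstants}.
#' @examples
#' thermoConstants()          # 310.15 K, kT ~ 0.616 kcal/mol
#' thermoConstants(T = 310)   # the rounded temperature used in worked numbers
#' @export
thermoConstants <- function(T = 310.15) {
  R <- 1.9872e-3
  new("ThermoConstants", R = R, T = T, kT = R * T)
}

#' Load nearest-neighbor thermodynamic parameters
#'
#' Reads the flat key-value parameter file (sections \code{[stack]},
#' \code{[hairpin]}, \code{[internal]}, \code{[multibranch]},
#' \code{[general]}; '#' comments). \code{"default"} loads the set shipped
#' with the package.
#'
#' @param source \code{"default"} or a path to a parameter file.
#' @return a validated \linkS4class{NearestNeighborParams}.
#' @export
loadParams <- function(source = "default") {
  if (identical(source, "default"))
    source <- system.file("extdata", "nn_params.txt",
                          package = "shapeEnsemble", mustWork = TRUE)
  if (!file.exists(source)) stop("parameter file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- NA_character_
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(PAIR_CODES, PAIR_CODES))
  hairpin <- numeric(0L); hairpinExt <- NA_real_
  internal <- numeric(0L); internalExt <- NA_real_
  mb <- c(offset = NA_real_, branch = NA_real_, unpaired = NA_real_)
  minHairpin <- 3L

  num <- function(tok, field) {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("non-numeric entry in field '", field, "': ", tok)
    v
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", ln)
      if (!section %in% c("stack", "hairpin", "internal",
                          "multibranch", "general"))
        stop("unknown section [", section, "]")
      next
    }
    if (is.na(section)) stop("entry before any section header: ", ln)
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (section == "stack") {
      if (length(tok) != 3L) stop("malformed stack entry: ", ln)
      if (!tok[1L] %in% PAIR_CODES || !tok[2L] %in% PAIR_CODES)
        stop("unknown pair key in stack entry: ", ln)
      stack[tok[1L], tok[2L]] <- num(tok[3L], paste("stack", tok[1L], tok[2L]))
    } else if (section %in% c("hairpin", "internal")) {
      if (length(tok) != 2L) stop("malformed ", section, " entry: ", ln)
      if (tok[1L] == "ext") {
        v <- num(tok[2L], paste(section, "ext"))
        if (section == "hairpin") hairpinExt <- v else internalExt <- v
      } else {
        sz <- as.integer(num(tok[1L], paste(section, "size")))
        v <- num(tok[2L], paste(section, tok[1L]))
        if (section == "hairpin") hairpin[as.character(sz)] <- v
        else internal[as.character(sz)] <- v
      }
    } else if (section == "multibranch") {
      if (length(tok) != 2L || !tok[1L] %in% names(mb))
        stop("malformed multibranch entry: ", ln)
      mb[tok[1L]] <- num(tok[2L], paste("multibranch", tok[1L]))
    } else if (section == "general") {
      if (length(tok) != 2L) stop("malformed general entry: ", ln)
      if (tok[1L] == "min_hairpin")
        minHairpin <- as.integer(num(tok[2L], "min_hairpin"))
      else stop("unknown general key: ", tok[1L])
    }
  }
  if (any(is.na(stack)))
    stop("missing stack table entries (", sum(is.na(stack)), " of 36)")
  checkTable <- function(tab, from, what) {
    if (!length(tab)) stop("missing ", what, " table")
    sz <- as.integer(names(tab))
    if (!identical(sz, seq.int(from, from + length(tab) - 1L)))
      stop(what, " table sizes must be contiguous starting at ", from)
    unname(tab)
  }
  hairpin <- checkTable(hairpin, minHairpin, "hairpin")
  internal <- checkTable(internal, 1L, "internal")
  if (is.na(hairpinExt) || is.na(internalExt))
    stop("missing 'ext' extrapolation coefficient in a loop table")
  if (any(is.na(mb))) stop("missing multibranch coefficient: ",
                           paste(names(mb)[is.na(mb)], collapse = ", "))
  new("NearestNeighborParams", stack = stack, hairpin = hairpin,
      hairpinExt = hairpinExt, internal = internal,
      internalExt = internalExt, multibranch = unname(mb),
      minHairpin = minHairpin)
}

#' Loop penalties by size
#'
#' Hairpin penalty for \code{size} enclosed nucleotides, or internal/bulge
#' penalty for \code{size} total unpaired nucleotides in the loop; sizes
#' beyond the parameter table use logarithmic extrapolation.
#' @param params a \linkS4class{NearestNeighborParams}.
#' @param size integer loop size(s).
#' @return numeric penalty, kcal/mol.
#' @export
hairpinPenalty <- function(params, size) {
  tab <- params@hairpin
  mn <- params@minHairpin
  mx <- mn + length(tab) - 1L
  ifelse(size <= mx, tab[pmax(size, mn) - mn + 1L],
         tab[length(tab)] + params@hairpinExt * log(size / mx))
}

#' @rdname hairpinPenalty
#' @export
internalPenalty <- function(params, size) {
  tab <- params@internal
  mx <- length(tab)
  ifelse(size <= mx, tab[pmax(size, 1L)],
         tab[mx] + params@internalExt * log(size / mx))
}

## penalty lookup vectors used by the DP engine: index L+1 holds size L
loopPenaltyVectors <- function(params, N) {
  list(hairpin = hairpinPenalty(params, pmax(0:N, params@minHairpin)),
       internal = internalPenalty(params, pmax(0:(2L * N), 1L)))
}

#' Free energy of a structure by loop decomposition
#'
#' Evaluates the nearest-neighbor free energy of one structure as the sum
#' of its loop terms: stacking energies for stacked pairs, size-dependent
#' hairpin and internal/bulge penalties, and the linear multibranch model.
#' When a per-nucleotide pseudo-free-energy \code{bonus} is supplied, every
#' base-pair stack additionally contributes the bonus of each of its four
#' nucleotide positions, so nucleotides interior to a helix (members of two
#' stacks) receive their bonus twice and helix-end nucleotides once.
#'
#' @param seq RNA sequence string.
#' @param s a \linkS4class{SecondaryStructure} valid for \code{seq}.
#' @param params a \linkS4class{NearestNeighborParams}.
#' @param bonus numeric vector of per-nucleotide bonuses (kcal/mol), or
#'   NULL for the unrestrained model.
#' @return free energy in kcal/mol (0 for the open chain).
#' @export
structureEnergy <- function(seq, s, params = loadParams(), bonus = NULL) {
  seq <- normalizeSequence(seq)
  checkStructureSequence(seq, s)
  n <- s@seqLength
  if (!is.null(bonus) && length(bonus) != n)
    stop("bonus length (", length(bonus),
         ") does not match sequence length (", n, ")")
  if (any(s@pairs[, 2L] - s@pairs[, 1L] <= params@minHairpin))
    stop("a pair violates the minimum hairpin size of the parameter set")
  ch <- strsplit(seq, "")[[1L]]
  p <- partnerVector(s)
  mb <- params@multibranch

  loopEnergy <- function(i, j) {
    ## energy of the loop closed by (i,j); i = 0, j = n+1 means exterior
    children <- matrix(integer(0L), ncol = 2L)
    unpaired <- 0L
    k <- i + 1L
    while (k <= j - 1L) {
      if (p[k] > k) {
        children <- rbind(children, c(k, p[k]))
        k <- p[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    e <- 0
    nc <- nrow(children)
    if (i >= 1L) {
      if (nc == 0L) {
        e <- hairpinPenalty(params, j - i - 1L)
      } else if (nc == 1L) {
        k <- children[1L, 1L]; l <- children[1L, 2L]
        if (k == i + 1L && l == j - 1L) {
          e <- params@stack[paste0(ch[i], ch[j]), paste0(ch[k], ch[l])]
          if (!is.null(bonus))
            e <- e + bonus[i] + bonus[j] + bonus[k] + bonus[l]
        } else {
          e <- internalPenalty(params, (k - i - 1L) + (j - l - 1L))
        }
      } else {
        e <- mb[1L] + mb[2L] * (nc + 1L) + mb[3L] * unpaired
      }
    }
    for (c_ in seq_len(nc))
      e <- e + loopEnergy(children[c_, 1L], children[c_, 2L])
    e
  }
  as.numeric(loopEnergy(0L, n + 1L))
}

#' Per-nucleotide stack membership counts
#'
#' For each nucleotide, the number of base-pair stacks (adjacent nested
#' pairs (i,j), (i+1,j-1)) that contain it: 0 for unpaired or isolated
#' pairs, 1 at helix ends, 2 in helix interiors. The bonus contribution to
#' \code{\link{structureEnergy}} equals \code{sum(stackCounts(s) * bonus)}.
#'
#' @param s a \linkS4class{SecondaryStructure}.
#' @return integer vector of counts in 0..2.
#' @export
stackCounts <- function(s) {
  p <- partnerVector(s)
  cnt <- integer(s@seqLength)
  bp <- s@pairs
  for (r in seq_len(nrow(bp))) {
    i <- bp[r, 1L]; j <- bp[r, 2L]
    if (i + 1L < j - 1L && p[i + 1L] == j - 1L) {
      idx <- c(i, j, i + 1L, j - 1L)
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  cnt
}
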