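#' Sensitivity and PPV of a predicted structure
#'
#' Sensitivity is the fraction of reference base pairs found in the
#' prediction; PPV is the fraction of predicted pairs found in the
#' reference. With \code{slip = TRUE} (the benchmark convention) a pair
#' (i, j) counts as matched if the other set contains any of (i, j),
#' (i+1, j), (i-1, j), (i, j+1) or (i, j-1) — accepted structures cannot
#' distinguish these register shifts and thermal fluctuation samples them.
#' Matching is greedy in reference order and each pair is consumed at most
#' once, so a single predicted pair cannot satisfy two reference pairs.
#'
#' @param predicted,reference \linkS4class{SecondaryStructure} of equal
#'   length.
#' @param slip logical, allow one-position register slips (default TRUE).
#' @return list with \code{sensitivity}, \code{ppv} (NA when the
#'   respective denominator is empty), \code{geometric_mean} and
#'   \code{matched_pairs}.
#' @export
sensitivityPPV <- function(predicted, reference, slip = TRUE) {
  if (predicted@seqLength != reference@seqLength)
    stop("structures have different lengths")
  n <- predicted@seqLength + 2L
  key <- function(bp) bp[, 1L] * n + bp[, 2L]
  variants <- function(i, j) {
    cbind(c(i, i + 1L, i - 1L, i, i),
          c(j, j, j, j + 1L, j - 1L))
  }
  countMatches <- function(from, to) {
    ## greedy one-to-one matching of 'from' pairs against 'to' pairs
    if (!nrow(from) || !nrow(to)) return(0L)
    avail <- key(to)
    matched <- 0L
    for (r in seq_len(nrow(from))) {
      cand <- if (slip) key(variants(from[r, 1L], from[r, 2L]))
              else from[r, 1L] * n + from[r, 2L]
      hit <- which(avail %in% cand)
      if (length(hit)) {
        avail <- avail[-hit[1L]]
        matched <- matched + 1L
      }
    }
    matched
  }
  np <- nrow(predicted@pairs); nr <- nrow(reference@pairs)
  sens <- if (nr == 0L) NA_real_
          else countMatches(reference@pairs, predicted@pairs) / nr
  ppv <- if (np == 0L) NA_real_
         else countMatches(predicted@pairs, reference@pairs) / np
  gm <- if (is.na(sens) || is.na(ppv)) NA_real_ else sqrt(sens * ppv)
  list(sensitivity = sens, ppv = ppv, geometric_mean = gm,
       matched_pairs = if (nr == 0L) 0L
                       else countMatches(reference@pairs, predicted@pairs))
}

#' Free-energy gap between two population ratios
#'
#' For two-state ratios (p, 1-p) and (q, 1-q), the absolute difference of
#' the logit free energies |RT ln(p/(1-p)) - RT ln(q/(1-q))| in kcal/mol.
#' A gap of about 2kT (~1.23 kcal/mol at 310 K) corresponds to a factor
#' of ~7 in odds.
#'
#' @param ratioA,ratioB numeric length-2 population vectors; each must sum
#'   to 1 with both entries strictly inside (0, 1).
#' @param consts a \linkS4class{ThermoConstants}; the worked benchmark
#'   number uses T = 310 K.
#' @return non-negative numeric, kcal/mol.
#' @examples
#' populationDDG(c(0.94, 0.06), c(0.70, 0.30), thermoConstants(T = 310))
#' # ~1.17, i.e. 1.2 kcal/mol after rounding, about 2kT
#' @export
populationDDG <- function(ratioA, ratioB, consts = thermoConstants(T = 310)) {
  chk <- function(r, nm) {
    if (length(r) != 2L || abs(sum(r) - 1) > 1e-6)
      stop(nm, " must be a length-2 ratio summing to 1")
    if (any(r <= 0) || any(r >= 1))
      stop(nm, " is degenerate (a population of 0 or 1 has no finite logit)")
  }
  chk(ratioA, "ratioA"); chk(ratioB, "ratioB")
  RT <- consts@kT
  abs(RT * log(ratioA[1L] / ratioA[2L]) - RT * log(ratioB[1L] / ratioB[2L]))
}

#' RMSD between two reactivity profiles
#'
#' Root-mean-square deviation over the positions unmasked in both
#' profiles.
#'
#' @param a,b \linkS4class{ReactivityProfile} of equal length.
#' @return non-negative numeric.
#' @export
reactivityRMSD <- function(a, b) {
  va <- reactivities(a); vb <- reactivities(b)
  if (length(va) != length(vb)) stop("profile lengths differ")
  keep <- !is.na(va) & !is.na(vb)
  if (!any(keep)) stop("no overlapping unmasked positions")
  sqrt(mean((va[keep] - vb[keep])^2))
}

#' Default calibration grid for C and Offset
#'
#' The 15 x 15 = 225 combinations of C and Offset from 0.1 to 1.5 in
#' steps of 0.1 used to calibrate the restraint.
#'
#' @param Cvalues,OffsetValues candidate values.
#' @return data.frame with columns C and Offset.
#' @export
calibrationGrid <- function(Cvalues = seq(0.1, 1.5, by = 0.1),
                            OffsetValues = seq(0.1, 1.5, by = 0.1)) {
  expand.grid(C = Cvalues, Offset = OffsetValues, KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search calibration of the restraint parameters
#'
#' For every (C, Offset) combination, runs the single-structure pipeline
#' (unrestrained sample, reactivity estimate, restraint, restrained
#' partition function, MEA structure) on each dataset entry and averages
#' the geometric-mean accuracy against the reference structure
#' (slipped-pair tolerance). Returns the maximizing pair — ties broken by
#' smaller C, then smaller Offset — and the full score surface. Entries on
#' which the pipeline fails are skipped with a warning and recorded.
#'
#' @param dataset list of entries \code{list(seq =, rexp =, reference =)}:
#'   sequence string, measured \linkS4class{ReactivityProfile}, reference
#'   \linkS4class{SecondaryStructure}.
#' @param Cvalues,OffsetValues candidate values (defaults give the 225
#'   combination grid).
#' @param params,consts,dists folding model configuration.
#' @param sampleSize Boltzmann sample size for the reactivity estimate.
#' @param seed RNG seed.
#' @return list with \code{C}, \code{Offset}, \code{surface} (data.frame
#'   C, Offset, score) and \code{skipped} (character vector of entry
#'   failures, empty if none).
#' @export
gridSearch <- function(dataset, Cvalues = seq(0.1, 1.5, by = 0.1),
                       OffsetValues = seq(0.1, 1.5, by = 0.1),
                       params = loadParams(), consts = thermoConstants(),
                       dists = reactivityDistributions(),
                       sampleSize = 10000L, seed = 1L) {
  if (!length(dataset)) stop("empty dataset")
  if (!length(Cvalues) || !length(OffsetValues)) stop("empty value grid")
  grid <- calibrationGrid(Cvalues, OffsetValues)
  skipped <- character(0L)

  ## Rcalc does not depend on (C, Offset): compute once per entry
  prep <- vector("list", length(dataset))
  for (e in seq_along(dataset)) {
    d <- dataset[[e]]
    prep[[e]] <- tryCatch({
      ens <- stochasticSample(d$seq, n = sampleSize, seed = seed,
                              params = params, consts = consts)
      list(rcalc = estimateRcalc(ens, dists), ok = TRUE)
    }, error = function(err) {
      list(ok = FALSE, msg = conditionMessage(err))
    })
    if (!prep[[e]]$ok) {
      warning("dataset entry ", e, " skipped: ", prep[[e]]$msg)
      skipped <- c(skipped, sprintf("entry %d: %s", e, prep[[e]]$msg))
    }
  }
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rp <- restraintParams(C = grid$C[g], Offset = grid$Offset[g])
    accs <- numeric(0L)
    for (e in seq_along(dataset)) {
      if (!prep[[e]]$ok) next
      d <- dataset[[e]]
      acc <- tryCatch({
        bonus <- computeBonus(d$rexp, prep[[e]]$rcalc, rp)
        pf <- partitionFunction(d$seq, params = params, consts = consts,
                                bonus = bonus)
        mea <- meaStructure(pf$probs, minHairpin = params@minHairpin)
        sensitivityPPV(mea, d$reference, slip = TRUE)$geometric_mean
      }, error = function(err) NA_real_)
      if (!is.na(acc)) accs <- c(accs, acc)
    }
    score[g] <- if (length(accs)) mean(accs) else NA_real_
  }
  surface <- cbind(grid, score = score)
  ord <- order(-score, grid$C, grid$Offset, na.last = TRUE)
  best <- ord[1L]
  list(C = grid$C[best], Offset = grid$Offset[best], surface = surface,
       skipped = skipped)
}

#' Jackknife validation of the calibration
#'
#' Repeats \code{\link{gridSearch}} leaving out each dataset entry in
#' turn and reports the stability: the fraction of leave-one-out optima
#' agreeing with the full-data optimum.
#'
#' @inheritParams gridSearch
#' @return list with \code{full} (full-data optimum), \code{leaveOneOut}
#'   (data.frame: left-out entry, C, Offset) and \code{stability}.
#' @export
jackknifeCalibration <- function(dataset, Cvalues = seq(0.1, 1.5, by = 0.1),
                                 OffsetValues = seq(0.1, 1.5, by = 0.1),
                                 ...) {
  if (length(dataset) < 2L) stop("jackknife needs at least 2 entries")
  full <- gridSearch(dataset, Cvalues, OffsetValues, ...)
  loo <- data.frame(leftOut = seq_along(dataset),
                    C = NA_real_, Offset = NA_real_)
  for (e in seq_along(dataset)) {
    fit <- gridSearch(dataset[-e], Cvalues, OffsetValues, ...)
    loo$C[e] <- fit$C
    loo$Offset[e] <- fit$Offset
  }
  agree <- loo$C == full$C & loo$Offset == full$Offset
  list(full = full[c("C", "Offset")], leaveOneOut = loo,
       stability = mean(agree))
}
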