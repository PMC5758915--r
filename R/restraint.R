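#' Restraint parameters
#'
#' @param C energy scale in kcal/mol (default 0.5, the calibrated value).
#' @param Offset unitless shift accommodating reactivities <= 0
#'   (default 1.1, the calibrated value).
#' @param epsilon positivity floor applied to (reactivity + Offset) before
#'   taking the log; protects against reactivities below -Offset.
#' @return a \linkS4class{RestraintParams}.
#' @export
restraintParams <- function(C = 0.5, Offset = 1.1, epsilon = 1e-4) {
  ## Class= named explicitly so the slot 'C' cannot partial-match it
  new(Class = "RestraintParams", C = C, Offset = Offset, epsilon = epsilon)
}

#' Pseudo-free-energy bonuses from reactivity mismatch
#'
#' Converts the discrepancy between the measured profile Rexp and the
#' ensemble-estimated profile Rcalc into per-nucleotide bonuses
#' \deqn{\Delta G_{bonus,i} = C \ln\frac{Rexp_i + Offset}{Rcalc_i + Offset}}
#' added to every base-pair stack the nucleotide belongs to. A nucleotide
#' more reactive than estimated receives a positive bonus (destabilizes
#' its pairing); less reactive, a negative bonus (promotes pairing);
#' matching reactivities give zero — the thermodynamic prediction already
#' agrees there. Positions with missing measurements receive bonus 0 (no
#' restraint). Numerator and denominator are floored at epsilon.
#'
#' @param rexp measured \linkS4class{ReactivityProfile}.
#' @param rcalc estimated \linkS4class{ReactivityProfile}.
#' @param params a \linkS4class{RestraintParams}.
#' @return numeric bonus vector, kcal/mol, zero at masked positions.
#' @examples
#' computeBonus(reactivityProfile(2.0), reactivityProfile(0.0))
#' # 0.5 * log(3.1 / 1.1) ~ +0.518 kcal/mol
#' @export
computeBonus <- function(rexp, rcalc, params = restraintParams()) {
  re <- reactivities(rexp)
  rc <- reactivities(rcalc)
  if (length(re) != length(rc))
    stop("profile lengths differ: ", length(re), " vs ", length(rc))
  num <- pmax(re + params@Offset, params@epsilon)
  den <- pmax(rc + params@Offset, params@epsilon)
  bonus <- params@C * log(num / den)
  bonus[is.na(re) | is.na(rc)] <- 0
  bonus
}
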