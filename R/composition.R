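# Membrane-composition calculus: cholesterol mixing ratio <-> mol%, the
# weighted-sum onset of cholesterol bilayer domains (CBDs), and phase labels.

#' Model lens-lipid membrane composition
#'
#' Mole fractions of the four major lens lipids plus the cholesterol mixing
#' ratio (mol cholesterol per mol total lipid). The default is the
#' 60-year-old model human lens-lipid composition: 66% sphingomyelin,
#' 11% POPC, 15% POPE, 8% POPS.
#'
#' @param mol_fractions Named numeric vector over `SM`, `POPC`, `POPE`,
#'   `POPS`; non-negative, summing to 1 (within 1e-9).
#' @param chol_mixing_ratio Mol cholesterol per mol lipid (>= 0).
#' @return A `membrane_composition` object.
#' @examples
#' membrane_composition(chol_mixing_ratio = 0.5)
#' @export
membrane_composition <- function(mol_fractions = c(SM = 0.66, POPC = 0.11, POPE = 0.15, POPS = 0.08),
                                 chol_mixing_ratio = 0) {
  if (is.null(names(mol_fractions)) || any(!nzchar(names(mol_fractions)))) {
    abort("`mol_fractions` must be a named vector.", class = "lensepr_error_composition")
  }
  if (any(mol_fractions < 0) || abs(sum(mol_fractions) - 1) > 1e-9) {
    abort("`mol_fractions` must be non-negative and sum to 1.",
      class = "lensepr_error_composition"
    )
  }
  if (chol_mixing_ratio < 0) {
    abort("`chol_mixing_ratio` must be >= 0.", class = "lensepr_error_composition")
  }
  structure(
    list(
      mol_fractions = mol_fractions,
      chol_mixing_ratio = as.numeric(chol_mixing_ratio)
    ),
    class = "membrane_composition"
  )
}

#' Per-lipid cholesterol thresholds for CBD formation
#'
#' Cholesterol mol% at which cholesterol bilayer domains begin to form in
#' the corresponding single-lipid bilayer. Defaults: SM 48, POPS 46, POPC 50,
#' POPE 33 mol%.
#'
#' @param onset_molpct Named numeric vector, values in (0, 100).
#' @return A named numeric vector (class `cbd_thresholds`).
#' @export
cbd_thresholds <- function(onset_molpct = c(SM = 48, POPS = 46, POPC = 50, POPE = 33)) {
  if (is.null(names(onset_molpct)) || any(onset_molpct <= 0) || any(onset_molpct >= 100)) {
    abort("thresholds must be named and in (0, 100) mol%.",
      class = "lensepr_error_composition"
    )
  }
  structure(onset_molpct, class = c("cbd_thresholds", "numeric"))
}

#' Cholesterol mixing ratio to mol%
#'
#' A mixing ratio `r` (mol cholesterol per mol lipid) corresponds to
#' `100 * r / (1 + r)` mol% cholesterol: 0 -> 0, 0.5 -> 33, 1.5 -> 60 mol%.
#'
#' @param r Mixing ratio(s), >= 0.
#' @return Mol% cholesterol (exact value; round for presentation).
#' @examples
#' round(mixing_ratio_to_molpct(c(0, 0.5, 1.5)))
#' @export
mixing_ratio_to_molpct <- function(r) {
  if (any(r < 0)) abort("`r` must be >= 0.", class = "lensepr_error_composition")
  100 * r / (1 + r)
}

#' Mol% cholesterol to mixing ratio
#'
#' Exact inverse of [mixing_ratio_to_molpct()]: `p / (100 - p)`.
#'
#' @param p Mol% cholesterol, in \[0, 100).
#' @return Mixing ratio(s).
#' @examples
#' molpct_to_mixing_ratio(60) # 1.5
#' @export
molpct_to_mixing_ratio <- function(p) {
  if (any(p < 0) || any(p >= 100)) {
    abort("`p` must be in [0, 100).", class = "lensepr_error_composition")
  }
  p / (100 - p)
}

#' CBD onset of a mixed membrane
#'
#' The cholesterol mol% at which cholesterol bilayer domains begin to form in
#' a mixed bilayer, estimated as the composition-weighted sum of the
#' single-lipid onsets: `sum_lipid fraction(lipid) * onset(lipid)`. For the
#' default lens-lipid composition and thresholds this gives 45.81, i.e.
#' about 46 mol%.
#'
#' @param comp A [membrane_composition()] (or named fraction vector).
#' @param thresholds A [cbd_thresholds()] vector covering every lipid with
#'   non-zero fraction.
#' @return The onset in mol% cholesterol (exact; round for presentation).
#' @examples
#' cbd_onset(membrane_composition()) # 45.81
#' @export
cbd_onset <- function(comp = membrane_composition(), thresholds = cbd_thresholds()) {
  fr <- if (inherits(comp, "membrane_composition")) comp$mol_fractions else comp
  used <- names(fr)[fr > 0]
  missing <- setdiff(used, names(thresholds))
  if (length(missing)) {
    abort(
      sprintf("no CBD onset threshold for lipid(s): %s.", paste(missing, collapse = ", ")),
      class = "lensepr_error_composition"
    )
  }
  sum(fr[used] * unclass(thresholds)[used])
}

#' Classify the cholesterol-domain state of a membrane
#'
#' Labels a membrane by its cholesterol content relative to two boundaries:
#' below `lcd_molpct` the membrane is not cholesterol-saturated
#' (`"no saturation"`); from saturation up to the CBD onset a
#' lipid-cholesterol domain forms (`"LCD"`); strictly above the onset pure
#' cholesterol bilayer domains coexist with it (`"LCD+CBD"`). The CBD
#' boundary is strict ("above" the onset); the saturation boundary is a
#' configurable heuristic defaulting to 33 mol%, the content at which the
#' lens-lipid membrane is observed saturated.
#'
#' @param molpct_chol Cholesterol content, mol%.
#' @param onset CBD onset, mol% (default the lens-lipid value from
#'   [cbd_onset()]).
#' @param lcd_molpct Saturation boundary, mol% (default 33).
#' @return Character vector of labels.
#' @examples
#' classify_domains(c(0, 33.3, 60))
#' @export
classify_domains <- function(molpct_chol, onset = cbd_onset(), lcd_molpct = 33) {
  dplyr::case_when(
    molpct_chol > onset ~ "LCD+CBD",
    molpct_chol >= lcd_molpct ~ "LCD",
    .default = "no saturation"
  )
}

#' Round half away from zero
#'
#' Presentation rounding used for reported mol% values (45.81 -> 46;
#' 33.33 -> 33), as opposed to R's round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @examples
#' round_half_up(c(45.81, 0.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
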