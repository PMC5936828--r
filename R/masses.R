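# Monoisotopic mass bookkeeping for native, permethylated and 2-AB glycans.
#
# All masses in Da (u). The only supported adduct is the singly charged
# sodiated species [M+Na]+, the form MALDI spectra of permethylated and
# 2-AB labeled glycans are reported in.

## atomic / group monoisotopic masses
.mass <- list(
  CH2      = 14.0156500,   # methyl increment (replacing H on O/N)
  H2O      = 18.0105646,
  twoAB    = 120.0687480,  # net 2-aminobenzamide label (reductive amination), C7H8N2
  Na_ion   = 22.9892180,   # Na+ cation (Na minus one electron mass)
  electron = 0.0005486
)

## residue (glycosidically condensed) increments, by mass class
.residue_native <- c(Hex = 162.0528234, HexNAc = 203.0793725, dHex = 146.0579088)

## permethylation adds CH2 at every free hydroxyl/amide of the condensed
## residue: 3 per Hex, 3 per HexNAc (2 OH + N-methyl), 2 per dHex
.perm_ch2 <- c(Hex = 3L, HexNAc = 3L, dHex = 2L)

#' Mass convention for a derivatization state
#'
#' Returns the set of monoisotopic increments used throughout the package:
#' per-residue increments, the end-group increment completing an intact
#' (free or labeled reducing end) molecule, the end-group increments for
#' Domon-Costello B- and Y-fragments, the methyl increment and the sodium
#' cation mass.
#'
#' For `"permethylated"` the residue increments already account for one
#' methyl on every free hydroxyl, so per-residue natural methyl counts are
#' ignored (a natural O-methyl is indistinguishable from a permethylation
#' methyl). For `"native"` and `"2AB"` natural methyls add 14.0157 Da each.
#'
#' @param derivatization one of `"native"`, `"permethylated"`, `"2AB"`.
#' @return a list with elements `residue` (named numeric: Hex, HexNAc, dHex),
#'   `end_intact`, `end_B`, `end_Y`, `methyl`, `na`.
#' @export
#' @examples
#' mass_convention("permethylated")$residue
mass_convention <- function(derivatization = c("permethylated", "2AB", "native")) {
  derivatization <- normalize_derivatization(derivatization)
  res <- switch(derivatization,
    permethylated = .residue_native + .perm_ch2 * .mass$CH2,
    native        = .residue_native,
    `2AB`         = .residue_native
  )
  end <- switch(derivatization,
    # free reducing end, fully methylated: H2O plus the two methyls on the
    # anomeric and terminal positions opened by hydration
    permethylated = .mass$H2O + 2 * .mass$CH2,
    native        = .mass$H2O,
    `2AB`         = .mass$H2O + .mass$twoAB
  )
  endB <- switch(derivatization,
    # sodiated B-type oxocarbenium-equivalent: one methyl closes the
    # non-reducing composition
    permethylated = .mass$CH2,
    native        = 0,
    `2AB`         = NA_real_  # no fixed convention; see enumerate_BY()
  )
  endY <- switch(derivatization,
    permethylated = .mass$H2O + .mass$CH2,
    native        = .mass$H2O,
    `2AB`         = .mass$H2O + .mass$twoAB
  )
  list(residue = res, end_intact = end, end_B = endB, end_Y = endY,
       methyl = .mass$CH2, na = .mass$Na_ion)
}

normalize_derivatization <- function(x) {
  x <- x[[1L]]
  if (identical(x, "twoAB")) x <- "2AB"
  if (!x %in% c("native", "permethylated", "2AB"))
    stop("unsupported derivatization: ", x, call. = FALSE)
  x
}

check_adduct <- function(adduct) {
  if (!identical(adduct, "[M+Na]+"))
    stop("unsupported adduct '", adduct,
         "': only singly charged [M+Na]+ is modeled", call. = FALSE)
  invisible(adduct)
}

#' Monosaccharide composition of a glycan
#'
#' A composition counts residues by mass class: hexoses (Hex; Man, Gal, Glc),
#' N-acetylhexosamines (HexNAc; GlcNAc) and deoxyhexoses (dHex; Fuc),
#' plus natural O-methyl groups, together with the derivatization state.
#' The field's shorthand FxHnNy (e.g. `F1H3N2`) maps to
#' `ndHex = x, nHex = n, nHexNAc = y`.
#'
#' @param hex,hexnac,dhex,me non-negative integer counts.
#' @param derivatization `"native"`, `"permethylated"` or `"2AB"`.
#' @return an object of class `glycan_composition`.
#' @export
#' @examples
#' composition(3, 2, derivatization = "permethylated")
composition <- function(hex = 0, hexnac = 0, dhex = 0, me = 0,
                        derivatization = "permethylated") {
  counts <- c(hex, hexnac, dhex, me)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("invalid composition: counts must be non-negative integers",
         call. = FALSE)
  structure(
    list(nHex = as.integer(hex), nHexNAc = as.integer(hexnac),
         ndHex = as.integer(dhex), nMe = as.integer(me),
         derivatization = normalize_derivatization(derivatization)),
    class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) {
  sprintf("Hex%d HexNAc%d dHex%d Me%d [%s]",
          x$nHex, x$nHexNAc, x$ndHex, x$nMe, x$derivatization)
}

#' Parse the F/H/N composition shorthand
#'
#' Converts strings such as `"F1H6N2"` (1 dHex, 6 Hex, 2 HexNAc) or
#' `"H5N2"` into a [composition()].
#'
#' @param text shorthand string; letters F (dHex), H (Hex), N (HexNAc),
#'   M (methyl), each followed by a count, in any order.
#' @param derivatization passed to [composition()].
#' @export
#' @examples
#' parse_fhn("F1H6N2")
parse_fhn <- function(text, derivatization = "permethylated") {
  m <- gregexpr("([FHNM])(\\d+)", text)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse composition shorthand: ", text, call. = FALSE)
  parts <- regmatches(text, gregexpr("([FHNM])(\\d+)", text))[[1]]
  counts <- c(F = 0, H = 0, N = 0, M = 0)
  for (p in parts) counts[substr(p, 1, 1)] <- as.integer(substr(p, 2, nchar(p)))
  composition(hex = counts[["H"]], hexnac = counts[["N"]],
              dhex = counts[["F"]], me = counts[["M"]],
              derivatization = derivatization)
}

comp_add <- function(a, b) {
  composition(a$nHex + b$nHex, a$nHexNAc + b$nHexNAc, a$ndHex + b$ndHex,
              a$nMe + b$nMe, a$derivatization)
}

comp_sub <- function(a, b) {
  composition(a$nHex - b$nHex, a$nHexNAc - b$nHexNAc, a$ndHex - b$ndHex,
              max(a$nMe - b$nMe, 0L), a$derivatization)
}

comp_equal <- function(a, b, ignore_me = FALSE) {
  a$nHex == b$nHex && a$nHexNAc == b$nHexNAc && a$ndHex == b$ndHex &&
    (ignore_me || a$nMe == b$nMe)
}

residue_sum <- function(comp, conv) {
  comp$nHex * conv$residue[["Hex"]] +
    comp$nHexNAc * conv$residue[["HexNAc"]] +
    comp$ndHex * conv$residue[["dHex"]]
}

#' Monoisotopic m/z of an intact glycan composition
#'
#' Sums the derivatization-specific residue increments, the intact end-group
#' increment, natural methyls (native/2-AB only; under permethylation every
#' free hydroxyl carries a methyl already, so `nMe` is ignored) and the
#' sodium cation.
#'
#' @param comp a [composition()].
#' @param adduct adduct label; only `"[M+Na]+"` is supported.
#' @return monoisotopic m/z (Da) of the singly charged sodiated species.
#' @export
#' @examples
#' composition_mass(composition(3, 2, derivatization = "permethylated"))  # 1171.6
composition_mass <- function(comp, adduct = "[M+Na]+") {
  stopifnot(inherits(comp, "glycan_composition"))
  check_adduct(adduct)
  conv <- mass_convention(comp$derivatization)
  me <- if (comp$derivatization == "permethylated") 0L else comp$nMe
  residue_sum(comp, conv) + me * conv$methyl + conv$end_intact + conv$na
}

#' Monoisotopic m/z of a B- or Y-type glycosidic fragment
#'
#' B fragments retain the non-reducing end, Y fragments the reducing end
#' (with its label, if any); both are reported sodiated. Permethylated
#' fragment conventions reproduce the field's printed values (e.g. B 690.3
#' for Hex2HexNAc1, Y 474.2 for Fuc1HexNAc1). 2-AB B-ion end groups have no
#' settled convention; supply `b_end` explicitly to compute them.
#'
#' @param comp fragment [composition()].
#' @param type `"B"` or `"Y"`.
#' @param b_end optional numeric end-group increment overriding the
#'   convention's B end group (required for 2-AB B-ions).
#' @return monoisotopic m/z (Da), sodiated.
#' @export
fragment_mass <- function(comp, type = c("B", "Y"), b_end = NULL) {
  stopifnot(inherits(comp, "glycan_composition"))
  type <- match.arg(type)
  conv <- mass_convention(comp$derivatization)
  me <- if (comp$derivatization == "permethylated") 0L else comp$nMe
  end <- if (type == "B") {
    if (!is.null(b_end)) b_end
    else if (is.na(conv$end_B))
      stop("no fixed B-ion convention for 2-AB fragments; supply b_end",
           call. = FALSE)
    else conv$end_B
  } else conv$end_Y
  residue_sum(comp, conv) + me * conv$methyl + end + conv$na
}
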