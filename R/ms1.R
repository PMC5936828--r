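# MS1 composition assignment: bounded enumeration of Hex/HexNAc/dHex/Me
# compositions matching a peak m/z, glycan-class labelling, and 14-Da
# methyl-ladder profiling of 2-AB spectra.

default_bounds <- function() list(hex = 12L, hexnac = 6L, dhex = 2L, me = 8L)

#' Enumerate compositions matching an observed m/z
#'
#' Exhaustive bounded integer search over (nHex, nHexNAc, ndHex, nMe): every
#' combination within `bounds` whose theoretical sodiated m/z lies within
#' `tolerance` of `mz` is returned. Methyl counts are searched only for
#' native/2-AB spectra (permethylation makes natural methyls invisible).
#' Candidates are sorted by |observed - theoretical|, then fewest residues,
#' then fewest methyls.
#'
#' @param mz observed m/z (Da), positive.
#' @param derivatization derivatization of the spectrum.
#' @param tolerance matching tolerance in Da (default 0.1).
#' @param bounds list with elements `hex`, `hexnac`, `dhex`, `me` (maximum
#'   counts); defaults Hex<=12, HexNAc<=6, dHex<=2, Me<=8.
#' @param budget maximum number of grid points searched before an explicit
#'   error (guards runaway bounds; default 5e6).
#' @return data.frame of class `composition_assignment`: columns `mz`,
#'   `nHex`, `nHexNAc`, `ndHex`, `nMe`, `theoretical`, `delta`, `class`.
#' @export
#' @examples
#' enumerate_compositions(1171.6, "permethylated")[1, ]
enumerate_compositions <- function(mz, derivatization = "permethylated",
                                   tolerance = 0.1, bounds = default_bounds(),
                                   budget = 5e6) {
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0)
    stop("invalid input: mz must be a positive scalar", call. = FALSE)
  stopifnot(tolerance > 0)
  derivatization <- normalize_derivatization(derivatization)
  me_max <- if (derivatization == "permethylated") 0L else as.integer(bounds$me)
  dims <- c(bounds$hex + 1, bounds$hexnac + 1, bounds$dhex + 1, me_max + 1)
  if (prod(dims) > budget)
    stop("enumeration budget exceeded (", prod(dims), " > ", budget,
         " grid points); tighten bounds", call. = FALSE)
  grid <- expand.grid(nHex = 0:bounds$hex, nHexNAc = 0:bounds$hexnac,
                      ndHex = 0:bounds$dhex, nMe = 0:me_max)
  conv <- mass_convention(derivatization)
  theo <- grid$nHex * conv$residue[["Hex"]] +
    grid$nHexNAc * conv$residue[["HexNAc"]] +
    grid$ndHex * conv$residue[["dHex"]] +
    grid$nMe * conv$methyl + conv$end_intact + conv$na
  keep <- abs(mz - theo) <= tolerance
  out <- grid[keep, , drop = FALSE]
  out$theoretical <- theo[keep]
  out$delta <- mz - out$theoretical
  out <- cbind(data.frame(mz = rep(mz, nrow(out))), out)
  ord <- order(abs(out$delta), out$nHex + out$nHexNAc + out$ndHex, out$nMe)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$class <- if (nrow(out) == 0L) character() else
    vapply(seq_len(nrow(out)), function(i)
      classify_glycan(composition(out$nHex[i], out$nHexNAc[i], out$ndHex[i],
                                  out$nMe[i], derivatization)), character(1))
  class(out) <- c("composition_assignment", "data.frame")
  out
}

#' Classify a composition into a glycan class
#'
#' Rules (a partition of composition space): with 2 HexNAc and no dHex,
#' up to 4 Hex is paucimannose and 5+ Hex is high-mannose; 2 HexNAc with
#' one dHex is the galactosylated-core-fucose F1HnN2 series; 3 or more
#' HexNAc is a complex/hybrid candidate; anything else is unassigned.
#'
#' @param comp a [composition()].
#' @return one of `"paucimannose"`, `"high-mannose"`, `"F1HnN2"`,
#'   `"complex/hybrid-candidate"`, `"unassigned"`.
#' @export
classify_glycan <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (comp$nHexNAc >= 3L) return("complex/hybrid-candidate")
  if (comp$nHexNAc == 2L && comp$ndHex == 0L)
    return(if (comp$nHex <= 4L) "paucimannose" else "high-mannose")
  if (comp$nHexNAc == 2L && comp$ndHex == 1L) return("F1HnN2")
  "unassigned"
}

## nearest peak within tolerance; ties broken toward lower m/z
match_peak_nearest <- function(peaks, mz, tolerance) {
  d <- abs(peaks$mz - mz)
  hit <- which(d <= tolerance)
  if (length(hit) == 0L) return(NA_integer_)
  hit[order(d[hit], peaks$mz[hit])][1L]
}

#' Profile 14-Da methylation ladders in a 2-AB MS1 spectrum
#'
#' For each base composition, peaks are matched at the theoretical m/z plus
#' k x 14.0157 Da (k = 0..`max_me`); the summed intensity per k is the
#' methylation distribution and its argmax the predominant methylation
#' state. A peak claimed by more than one ladder position is flagged
#' ambiguous and its intensity split equally among the claimants, so total
#' ladder intensity never exceeds the spectrum total.
#'
#' @param peaks a 2-AB MS1 [peak_list()].
#' @param base_comps list of base [composition()]s (or F/H/N strings),
#'   methyl counts ignored.
#' @param max_me maximum methylation state searched (default 8).
#' @param tolerance m/z matching tolerance (default 0.1 Da).
#' @return list with `distributions` (named list of data.frames
#'   `k`, `mz_theoretical`, `intensity`), `predominant` (named integer
#'   vector, NA when the ladder is empty) and `ambiguous` (data.frame of
#'   split peaks).
#' @export
detect_methyl_ladders <- function(peaks, base_comps, max_me = 8,
                                  tolerance = 0.1) {
  peaks <- as_peak_list(peaks)
  if (attr(peaks, "derivatization") != "2AB")
    stop("methyl-ladder profiling expects a 2-AB spectrum", call. = FALSE)
  if (is.character(base_comps)) base_comps <- as.list(base_comps)
  if (!is.list(base_comps) || inherits(base_comps, "glycan_composition"))
    base_comps <- list(base_comps)
  base_comps <- lapply(base_comps, function(b)
    if (is.character(b)) parse_fhn(b, "2AB") else b)
  labels <- vapply(base_comps, function(b)
    sprintf("H%dN%dF%d", b$nHex, b$nHexNAc, b$ndHex), character(1))
  ladder <- do.call(rbind, lapply(seq_along(base_comps), function(i) {
    b <- base_comps[[i]]
    base0 <- composition(b$nHex, b$nHexNAc, b$ndHex, me = 0,
                         derivatization = "2AB")
    k <- 0:max_me
    data.frame(base = i, k = k,
               mz_theoretical = composition_mass(base0) +
                 k * mass_convention("2AB")$methyl)
  }))
  ladder$peak <- vapply(ladder$mz_theoretical, function(m)
    match_peak_nearest(peaks, m, tolerance), integer(1))
  claimed <- ladder$peak[!is.na(ladder$peak)]
  nclaims <- table(claimed)
  ladder$intensity <- ifelse(
    is.na(ladder$peak), 0,
    peaks$intensity[ladder$peak] /
      as.numeric(nclaims[as.character(ladder$peak)]))
  ambiguous <- ladder[!is.na(ladder$peak) &
                        ladder$peak %in% as.integer(names(nclaims)[nclaims > 1]),
                      c("base", "k", "mz_theoretical", "peak", "intensity")]
  if (nrow(ambiguous)) {
    ambiguous$observed_mz <- peaks$mz[ambiguous$peak]
    warning("ambiguous ladder peaks split among ",
            length(unique(ambiguous$peak)), " claimant set(s)", call. = FALSE)
  }
  dists <- lapply(seq_along(base_comps), function(i) {
    d <- ladder[ladder$base == i, c("k", "mz_theoretical", "intensity")]
    rownames(d) <- NULL
    d
  })
  names(dists) <- labels
  predominant <- vapply(dists, function(d)
    if (all(d$intensity == 0)) NA_integer_
    else d$k[which.max(d$intensity)], integer(1))
  list(distributions = dists, predominant = predominant,
       ambiguous = ambiguous)
}
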