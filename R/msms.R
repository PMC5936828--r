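# Domon-Costello B/Y fragment enumeration, candidate chitobiose pairs for
# the Fuc1HexnHexNAc2 series, glycomer calling from complementary pairs,
# and the relative-distribution statistic.

#' Enumerate single-cleavage B/Y fragment pairs of a glycan tree
#'
#' One complementary (B, Y) pair per glycosidic edge: B is the subtree
#' distal to the cleaved bond (non-reducing end), Y is the remainder
#' containing the root (reducing end, with its label). Both are sodiated.
#' For permethylated glycans every pair satisfies
#' `B + Y = intact [M+Na]+ + 22.9892` (a second sodium).
#'
#' @param tree a [glycan_tree()]; derivatization `"permethylated"` or
#'   `"2AB"` (the experiments report no native MS/MS).
#' @param emit_2ab_b_ions 2-AB B-ion end groups follow no settled
#'   convention; B rows for 2-AB trees are emitted only when this is `TRUE`.
#' @param b_end end-group increment used for 2-AB B-ions when emitted.
#' @return a data.frame with one row per fragment (two per edge, or one Y
#'   per edge for 2-AB without opt-in): columns `edge` (id), `ion` ("B"/"Y"),
#'   `nHex`, `nHexNAc`, `ndHex`, `nMe`, `mz`, `parent_identity`,
#'   `child_identity`.
#' @export
#' @examples
#' tr <- build_nglycan(man = 3, fucosylated = TRUE)  # F1H3N2
#' enumerate_BY(tr)
enumerate_BY <- function(tree, emit_2ab_b_ions = FALSE, b_end = 0) {
  stopifnot(inherits(tree, "glycan_tree"))
  if (tree$derivatization == "native")
    stop("native MS/MS is not supported; derivatize first", call. = FALSE)
  parent_comp <- tree_composition(tree)
  edges <- collect_edges(tree$root)
  rows <- lapply(seq_along(edges), function(i) {
    e <- edges[[i]]
    bcomp <- subtree_composition(e$child, tree$derivatization)
    ycomp <- comp_sub(parent_comp, bcomp)
    b_mz <- if (tree$derivatization == "permethylated")
      fragment_mass(bcomp, "B")
    else if (emit_2ab_b_ions) fragment_mass(bcomp, "B", b_end = b_end)
    else NA_real_
    y_mz <- fragment_mass(ycomp, "Y")
    out <- data.frame(
      edge = i,
      ion = c("B", "Y"),
      nHex = c(bcomp$nHex, ycomp$nHex),
      nHexNAc = c(bcomp$nHexNAc, ycomp$nHexNAc),
      ndHex = c(bcomp$ndHex, ycomp$ndHex),
      nMe = c(bcomp$nMe, ycomp$nMe),
      mz = c(b_mz, y_mz),
      parent_identity = e$parent$identity,
      child_identity = e$child$identity,
      stringsAsFactors = FALSE)
    if (is.na(b_mz)) out <- out[out$ion == "Y", , drop = FALSE]
    out
  })
  rbind_rows(rows, data.frame(
    edge = integer(), ion = character(), nHex = integer(),
    nHexNAc = integer(), ndHex = integer(), nMe = integer(),
    mz = numeric(), parent_identity = character(),
    child_identity = character(), stringsAsFactors = FALSE))
}

collect_edges <- function(node) {
  out <- list()
  for (ch in node$children) {
    out[[length(out) + 1L]] <- list(parent = node, child = ch)
    out <- c(out, collect_edges(ch))
  }
  out
}

subtree_composition <- function(node, derivatization) {
  nodes <- tree_nodes(node)
  cls <- vapply(nodes, function(n) n$massClass, character(1))
  composition(hex = sum(cls == "Hex"), hexnac = sum(cls == "HexNAc"),
              dhex = sum(cls == "dHex"),
              me = sum(vapply(nodes, function(n) n$me, integer(1))),
              derivatization = derivatization)
}

#' Candidate chitobiose B/Y pairs for a Fuc1HexnHexNAc2 parent
#'
#' Cleavage of the facile glycosidic bond between the two core GlcNAcs of an
#' F1HnN2 glycan splits it into B = Hex_a HexNAc_1 (the mannose arm plus
#' distal GlcNAc) and Y = Fuc_1 Hex_b HexNAc_1 (the proximal GlcNAc with its
#' galactosylated core fucose), with a + b = n. Each split is one candidate
#' glycomer; b = 0..5 maps to the form letters a-f. The non-reducing part
#' must hold at least `min_b_hex` hexoses (default 2, the smallest observed
#' B-ion being Hex2HexNAc1 at m/z 690).
#'
#' @param parent_comp a [composition()] with `ndHex = 1`, `nHexNAc = 2`
#'   (permethylated), or an F/H/N shorthand string such as `"F1H6N2"`.
#' @param min_b_hex minimal hexose count on the B side.
#' @return data.frame with columns `form`, `b_hex`, `y_hex`, `B_mz`, `Y_mz`.
#' @export
#' @examples
#' candidate_pairs("F1H6N2")  # five pairs, B 690..1506 / Y 1494..678
candidate_pairs <- function(parent_comp, min_b_hex = 2) {
  if (is.character(parent_comp))
    parent_comp <- parse_fhn(parent_comp, derivatization = "permethylated")
  stopifnot(inherits(parent_comp, "glycan_composition"))
  if (parent_comp$derivatization != "permethylated")
    stop("candidate pairs are defined for permethylated spectra",
         call. = FALSE)
  if (parent_comp$ndHex != 1L || parent_comp$nHexNAc != 2L)
    stop("unsupported series: parent must be Fuc1Hex(n)HexNAc2",
         call. = FALSE)
  n <- parent_comp$nHex
  b_gal <- 0:min(5L, n - min_b_hex)
  b_gal <- b_gal[n - b_gal >= min_b_hex]
  if (length(b_gal) == 0L)
    return(data.frame(form = character(), b_hex = integer(),
                      y_hex = integer(), B_mz = numeric(), Y_mz = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(b_gal, function(b) {
    a <- n - b
    B <- composition(hex = a, hexnac = 1, derivatization = "permethylated")
    Y <- composition(hex = b, hexnac = 1, dhex = 1,
                     derivatization = "permethylated")
    data.frame(form = glycomer_form(b), b_hex = a, y_hex = b,
               B_mz = fragment_mass(B, "B"), Y_mz = fragment_mass(Y, "Y"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## nearest observed peak within tolerance; among several peaks in tolerance
## take the most intense, breaking exact-intensity ties toward lower m/z
match_peak <- function(peaks, mz, tolerance) {
  d <- abs(peaks$mz - mz)
  hit <- which(d <= tolerance)
  if (length(hit) == 0L) return(NA_integer_)
  hit[order(-peaks$intensity[hit], peaks$mz[hit])][1L]
}

#' Call glycomers from an MS/MS spectrum of an F1HnN2 parent
#'
#' A glycomer (form a-f) is called when both members of its candidate
#' chitobiose B/Y pair match observed peaks at or above
#' `major_ion_threshold` of the base peak. The pair intensity is the sum of
#' the matched B and Y intensities; [relative_distribution()] fills the
#' per-parent fractions.
#'
#' @param msms a [peak_list()] with `ms_level = 2`.
#' @param parent_comp the parent composition (object or `"F1HnN2"` string).
#' @param tolerance m/z matching tolerance in Da (printed fragment values
#'   are integers; default 0.5).
#' @param major_ion_threshold fraction of the base-peak intensity an ion
#'   must reach to count as major (default 0.05).
#' @param min_b_hex passed to [candidate_pairs()].
#' @return data.frame of calls: `form`, `B_mz`, `Y_mz` (theoretical),
#'   `B_obs`, `Y_obs`, `pair_intensity`, `fraction`.
#' @export
call_glycomers <- function(msms, parent_comp, tolerance = 0.5,
                           major_ion_threshold = 0.05, min_b_hex = 2) {
  msms <- as_peak_list(msms)
  cand <- candidate_pairs(parent_comp, min_b_hex = min_b_hex)
  empty <- data.frame(form = character(), B_mz = numeric(), Y_mz = numeric(),
                      B_obs = numeric(), Y_obs = numeric(),
                      pair_intensity = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(msms) == 0L || nrow(cand) == 0L) return(empty)
  base <- max(msms$intensity)
  floor_int <- major_ion_threshold * base
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    bi <- match_peak(msms, cand$B_mz[i], tolerance)
    yi <- match_peak(msms, cand$Y_mz[i], tolerance)
    if (is.na(bi) || is.na(yi)) return(NULL)
    if (msms$intensity[bi] < floor_int || msms$intensity[yi] < floor_int)
      return(NULL)
    data.frame(form = cand$form[i], B_mz = cand$B_mz[i], Y_mz = cand$Y_mz[i],
               B_obs = msms$mz[bi], Y_obs = msms$mz[yi],
               pair_intensity = msms$intensity[bi] + msms$intensity[yi],
               fraction = NA_real_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  relative_distribution(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Relative distribution of glycomers within one parent mass
#'
#' Each call's fraction is its B+Y pair intensity divided by the summed pair
#' intensities of all glycomers called for the parent.
#'
#' @param calls a data.frame of glycomer calls with a `pair_intensity`
#'   column (as from [call_glycomers()]).
#' @return `calls` with the `fraction` column filled; fractions sum to 1.
#' @export
relative_distribution <- function(calls) {
  stopifnot(is.data.frame(calls), "pair_intensity" %in% names(calls))
  if (nrow(calls) == 0L) stop("no glycomer calls to normalize", call. = FALSE)
  total <- sum(calls$pair_intensity)
  if (!is.finite(total) || total <= 0)
    stop("undefined distribution: total pair intensity is zero",
         call. = FALSE)
  calls$fraction <- calls$pair_intensity / total
  calls
}
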