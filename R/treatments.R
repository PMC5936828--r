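# Exoglycosidase / chemical treatment simulation and the decision-table
# inference from observed susceptibility to linkage constraints.
#
# A treatment removes residues whose identity (or mass class), anomericity
# and linkage match its specificity. Unknown anomericity or linkage never
# matches (conservative). Exoglycosidases act on terminal (leaf) residues
# only; O-methylation of the terminal residue itself blocks hydrolysis.
# Exhaustive treatments iterate until no further site matches, so termini
# exposed during the same incubation are digested too.

#' Define a treatment specificity
#'
#' @param name label used in reports.
#' @param removes residue identity (`"Gal"`, `"Man"`, `"Fuc"`, ...) or mass
#'   class (`"Hex"`, `"HexNAc"`, `"dHex"`) removed.
#' @param anomer required anomericity, `"a"`, `"b"` or `"any"`.
#' @param linkages allowed linkages toward the parent (e.g. `c("1-2","1-3")`)
#'   or `"any"`.
#' @param terminal_only if `TRUE` (exoglycosidase) only leaf residues are
#'   eligible; if `FALSE` (chemical cleavage, e.g. HF) internal residues are
#'   removed together with everything attached beyond them.
#' @param blocked_by_methylation if `TRUE`, a residue carrying one or more
#'   O-methyls resists removal.
#' @param exhaustive repeat until no eligible site remains.
#' @return an object of class `treatment_spec`.
#' @export
treatment_spec <- function(name, removes, anomer = "any", linkages = "any",
                           terminal_only = TRUE,
                           blocked_by_methylation = TRUE,
                           exhaustive = FALSE) {
  if (!removes %in% c(names(.residue_class), "Hex", "HexNAc", "dHex"))
    stop("unknown removal target: ", removes, call. = FALSE)
  if (!anomer %in% c("a", "b", "any"))
    stop("anomer must be 'a', 'b' or 'any'", call. = FALSE)
  ok_link <- c("1-2", "1-3", "1-4", "1-6", "any")
  if (!all(linkages %in% ok_link))
    stop("linkages must be drawn from ", paste(ok_link, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, removes = removes, anomer = anomer,
                 linkages = linkages, terminal_only = isTRUE(terminal_only),
                 blocked_by_methylation = isTRUE(blocked_by_methylation),
                 exhaustive = isTRUE(exhaustive)),
            class = "treatment_spec")
}

#' Built-in treatment specificities
#'
#' The six treatments used to interrogate the core chitobiose modifications:
#' hydrofluoric acid (cleaves alpha1-2/alpha1-3 fucose, terminal or
#' internal), bovine-kidney alpha-fucosidase, *A. oryzae*
#' beta(1-4)-galactosidase, *X. manihotis* beta(1-3/6)-galactosidase,
#' coffee-bean alpha-galactosidase, and jack-bean alpha-mannosidase
#' (exhaustive). All enzymes are blocked by O-methylation of the terminal
#' residue.
#'
#' @param name one of `"hf"`, `"a_fucosidase"`, `"b14_galactosidase"`,
#'   `"b36_galactosidase"`, `"a_galactosidase"`, `"a_mannosidase"`; omit to
#'   get the full named list.
#' @return a [treatment_spec()], or the named list of all six.
#' @export
#' @examples
#' builtin_treatments("b14_galactosidase")
builtin_treatments <- function(name = NULL) {
  specs <- list(
    hf = treatment_spec("hydrofluoric acid", removes = "dHex", anomer = "a",
                        linkages = c("1-2", "1-3"), terminal_only = FALSE,
                        blocked_by_methylation = FALSE, exhaustive = TRUE),
    a_fucosidase = treatment_spec("alpha-fucosidase (bovine kidney)",
                                  removes = "dHex", anomer = "a"),
    b14_galactosidase = treatment_spec(
      "beta(1-4)-galactosidase (A. oryzae)", removes = "Gal", anomer = "b",
      linkages = "1-4"),
    b36_galactosidase = treatment_spec(
      "beta(1-3/6)-galactosidase (X. manihotis)", removes = "Gal",
      anomer = "b", linkages = c("1-3", "1-6")),
    a_galactosidase = treatment_spec("alpha-galactosidase (coffee bean)",
                                     removes = "Gal", anomer = "a"),
    a_mannosidase = treatment_spec("alpha-mannosidase (jack bean)",
                                   removes = "Man", anomer = "a",
                                   exhaustive = TRUE)
  )
  if (is.null(name)) return(specs)
  if (!name %in% names(specs))
    stop("unknown built-in treatment: ", name, call. = FALSE)
  specs[[name]]
}

matches_spec <- function(node, spec) {
  id_ok <- node$identity == spec$removes || node$massClass == spec$removes
  if (!id_ok) return(FALSE)
  if (spec$anomer != "any" &&
      (node$anomer == "?" || node$anomer != spec$anomer)) return(FALSE)
  if (!identical(spec$linkages, "any") &&
      (node$linkage %in% c("1-?", "none") ||
       !node$linkage %in% spec$linkages)) return(FALSE)
  if (spec$blocked_by_methylation && node$me > 0L) return(FALSE)
  TRUE
}

## one digestion pass; removing an internal residue (terminal_only = FALSE)
## drops its whole subtree
digest_pass <- function(node, spec) {
  keep <- list()
  for (ch in node$children) {
    eligible <- matches_spec(ch, spec) &&
      (!spec$terminal_only || length(ch$children) == 0L)
    if (!eligible) keep[[length(keep) + 1L]] <- digest_pass(ch, spec)
  }
  node$children <- keep
  node
}

#' Apply a treatment to a glycan tree
#'
#' Removes every currently eligible residue in one pass; exhaustive
#' treatments repeat until a fixpoint, so termini exposed by earlier
#' removals within the same treatment become eligible. The reducing-end
#' root is never removed. A treatment with no matching site is a no-op.
#'
#' @param tree a [glycan_tree()].
#' @param spec a [treatment_spec()] or the name of a built-in.
#' @return the product [glycan_tree()].
#' @export
#' @examples
#' tr <- build_nglycan(man = 2, core_gal = 1)           # F1H3N2
#' tree_mass(apply_treatment(tr, "b14_galactosidase"))  # loses the Gal
apply_treatment <- function(tree, spec) {
  stopifnot(inherits(tree, "glycan_tree"))
  if (is.character(spec)) spec <- builtin_treatments(spec)
  stopifnot(inherits(spec, "treatment_spec"))
  root <- digest_pass(tree$root, spec)
  if (spec$exhaustive) {
    repeat {
      nxt <- digest_pass(root, spec)
      if (identical(nxt, root)) break
      root <- nxt
    }
  }
  glycan_tree(root, tree$derivatization)
}

#' Predict MS1 spectrum shifts under a treatment
#'
#' Applies `spec` to every structure, recomputes intact sodiated masses and
#' reports, per distinct input m/z, whether its intensity is expected to be
#' reduced (some structure at that mass lost residues), and which product
#' masses gain intensity. Product masses differ from their precursors by
#' integer multiples of residue increments.
#'
#' @param structures list of [glycan_tree()]s sharing one derivatization.
#' @param spec a [treatment_spec()] or built-in name.
#' @param abundances optional non-negative weights (default equal).
#' @return list with `peaks`: data.frame (`mz`, `status` in
#'   reduced/increased/unchanged), and `mapping`: data.frame
#'   (`mz_before`, `mz_after`, `abundance`) for structures that changed.
#' @export
predict_shift <- function(structures, spec, abundances = NULL) {
  if (length(structures) == 0L)
    return(list(peaks = data.frame(mz = numeric(), status = character(),
                                   stringsAsFactors = FALSE),
                mapping = data.frame(mz_before = numeric(),
                                     mz_after = numeric(),
                                     abundance = numeric())))
  derivs <- unique(vapply(structures, function(t) t$derivatization,
                          character(1)))
  if (length(derivs) != 1L)
    stop("structures must share one derivatization", call. = FALSE)
  if (is.null(abundances)) abundances <- rep(1, length(structures))
  stopifnot(length(abundances) == length(structures))
  before <- vapply(structures, tree_mass, numeric(1))
  products <- lapply(structures, apply_treatment, spec = spec)
  after <- vapply(products, tree_mass, numeric(1))
  changed <- abs(after - before) > 1e-9
  r <- function(x) round(x, 4)
  reduced <- unique(r(before[changed]))
  increased <- setdiff(unique(r(after[changed])), reduced)
  all_mz <- sort(unique(c(r(before), r(after))))
  status <- ifelse(all_mz %in% reduced, "reduced",
                   ifelse(all_mz %in% increased, "increased", "unchanged"))
  list(peaks = data.frame(mz = all_mz, status = status,
                          stringsAsFactors = FALSE),
       mapping = data.frame(mz_before = r(before[changed]),
                            mz_after = r(after[changed]),
                            abundance = abundances[changed]))
}

#' Infer linkage constraints from a treatment susceptibility table
#'
#' Encodes the decision rules used to reason from before/after spectra:
#' resistance to both hydrofluoric acid (alpha1-2/3-fucose specific) and
#' alpha-fucosidase, for a fucosylated species, places the fucose alpha1-6
#' on the core GlcNAc and capped by hexose; susceptibility to
#' beta(1-4)-galactosidase demonstrates a terminal unmethylated
#' beta1-4-galactose; resistance to all galactosidases despite PMAA evidence
#' of terminal galactose leaves a flagged disjunction (methylated galactose
#' or an untested anomer). The result is a conjunction of constraints, never
#' a unique structure.
#'
#' @param shift_table data.frame with columns `treatment` (built-in names)
#'   and `outcome` (`"susceptible"` or `"resistant"`).
#' @param has_dhex does the species composition contain a deoxyhexose?
#' @param pmaa_terminal_gal does PMAA linkage analysis show terminal
#'   galactose?
#' @return list with `constraints` (character), `ambiguous` (character,
#'   unresolved disjunctions).
#' @export
infer_constraints <- function(shift_table, has_dhex = TRUE,
                              pmaa_terminal_gal = FALSE) {
  if (is.null(shift_table) || nrow(shift_table) == 0L)
    return(list(constraints = character(), ambiguous = character()))
  stopifnot(all(c("treatment", "outcome") %in% names(shift_table)))
  if (!all(shift_table$outcome %in% c("susceptible", "resistant")))
    stop("outcome must be 'susceptible' or 'resistant'", call. = FALSE)
  dup <- tapply(shift_table$outcome, shift_table$treatment,
                function(x) length(unique(x)))
  if (any(dup > 1L))
    stop("inconsistent table: treatment(s) ",
         paste(names(dup)[dup > 1L], collapse = ", "),
         " marked both susceptible and resistant", call. = FALSE)
  out <- function(tr) {
    o <- shift_table$outcome[shift_table$treatment == tr]
    if (length(o)) o[1] else NA_character_
  }
  constraints <- character()
  ambiguous <- character()
  if (has_dhex && identical(out("hf"), "resistant") &&
      identical(out("a_fucosidase"), "resistant"))
    constraints <- c(constraints,
                     "Fuc alpha1-6 linked to core GlcNAc",
                     "Fuc capped by hexose")
  if (identical(out("b14_galactosidase"), "susceptible"))
    constraints <- c(constraints,
                     "terminal Gal beta1-4 present, unmethylated")
  gals <- c("b14_galactosidase", "b36_galactosidase", "a_galactosidase")
  gal_out <- vapply(gals, out, character(1))
  if (pmaa_terminal_gal && all(gal_out == "resistant", na.rm = TRUE) &&
      !all(is.na(gal_out)))
    ambiguous <- c(ambiguous,
                   "terminal Gal methylated OR anomer/linkage untested")
  list(constraints = constraints, ambiguous = ambiguous)
}
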