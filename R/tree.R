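# Rooted glycan trees and their condensed-IUPAC text encoding.
#
# Grammar (condensed IUPAC subset), read right to left:
#   tree     := chain
#   chain    := item* residue
#   item     := chain-with-linkage | "[" chain "]"
#   residue  := NAME methyl? linkage?
#   NAME     := Man | Gal | Glc | GlcNAc | Fuc | Hex | HexNAc | dHex
#   methyl   := "{" INT "Me}"
#   linkage  := "(" anomer "1-" pos ")"   anomer := a | b | ?   pos := 2|3|4|6|?
# The rightmost residue is the reducing end (root); "Gal(b1-4)Fuc(a1-6)GlcNAc"
# is Gal beta1-4 linked to Fuc alpha1-6 linked to the root GlcNAc. Branches
# sit in square brackets before their parent: "Man(a1-3)[Man(a1-6)]Man".
# Non-root residues must carry a linkage; the root must not.

.residue_class <- c(Man = "Hex", Gal = "Hex", Glc = "Hex", Hex = "Hex",
                    GlcNAc = "HexNAc", HexNAc = "HexNAc",
                    Fuc = "dHex", dHex = "dHex")

#' Construct a glycan residue node
#'
#' @param identity one of Man, Gal, Glc, GlcNAc, Fuc, or the generic
#'   Hex/HexNAc/dHex.
#' @param anomer `"a"`, `"b"` or `"?"` (unknown).
#' @param linkage position on the parent, `"1-2"`, `"1-3"`, `"1-4"`, `"1-6"`,
#'   `"1-?"` (unknown) or `"none"` for the root.
#' @param me natural O-methyl count carried by this residue (at most 4).
#' @param children list of child residue nodes.
#' @return a `glycan_residue` list node.
#' @export
residue <- function(identity, anomer = "?", linkage = "none", me = 0,
                    children = list()) {
  if (!identity %in% names(.residue_class))
    stop("unknown residue identity: ", identity, call. = FALSE)
  if (!anomer %in% c("a", "b", "?"))
    stop("invalid anomericity: ", anomer, call. = FALSE)
  if (!linkage %in% c("1-2", "1-3", "1-4", "1-6", "1-?", "none"))
    stop("invalid linkage: ", linkage, call. = FALSE)
  if (me < 0 || me > 4)
    stop("methyl count out of range [0, 4]: ", me, call. = FALSE)
  structure(list(identity = identity, massClass = .residue_class[[identity]],
                 anomer = anomer, linkage = linkage, me = as.integer(me),
                 children = children),
            class = "glycan_residue")
}

#' Construct a glycan tree
#'
#' @param root a [residue()] node with `linkage = "none"`; for N-glycans this
#'   is the reducing-end (proximal) GlcNAc.
#' @param derivatization `"native"`, `"permethylated"` or `"2AB"`.
#' @return an object of class `glycan_tree`.
#' @export
glycan_tree <- function(root, derivatization = "permethylated") {
  stopifnot(inherits(root, "glycan_residue"))
  if (root$linkage != "none")
    stop("root residue must have linkage 'none'", call. = FALSE)
  structure(list(root = root,
                 derivatization = normalize_derivatization(derivatization)),
            class = "glycan_tree")
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", serialize_structure(x), " [", x$derivatization, "]\n",
      sep = "")
  invisible(x)
}

## ---- tokenizer -------------------------------------------------------------

.token_res <- "^(GlcNAc|HexNAc|Glc|Gal|Man|Fuc|Hex|dHex)"
.token_me  <- "^\\{(\\d+)Me\\}"
.token_lnk <- "^\\(([ab?])1-([2346?])\\)"

tokenize_structure <- function(text) {
  tokens <- list()
  pos <- 1L
  s <- text
  while (nchar(s) > 0L) {
    ch <- substr(s, 1, 1)
    if (ch %in% c("[", "]")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = pos)
      s <- substr(s, 2, nchar(s)); pos <- pos + 1L
      next
    }
    m <- regmatches(s, regexec(.token_res, s))[[1]]
    if (length(m) == 0L)
      stop("parse error at position ", pos, ": unknown residue token near '",
           substr(text, pos, pos + 8), "'", call. = FALSE)
    name <- m[2]
    consumed <- nchar(name)
    rest <- substr(s, consumed + 1L, nchar(s))
    me <- 0L
    mm <- regmatches(rest, regexec(.token_me, rest))[[1]]
    if (length(mm)) {
      me <- as.integer(mm[2])
      consumed <- consumed + nchar(mm[1])
      rest <- substr(s, consumed + 1L, nchar(s))
    }
    anomer <- "?"; linkage <- "none"
    ml <- regmatches(rest, regexec(.token_lnk, rest))[[1]]
    if (length(ml)) {
      anomer <- ml[2]
      linkage <- paste0("1-", ml[3])
      consumed <- consumed + nchar(ml[1])
    }
    tokens[[length(tokens) + 1L]] <-
      list(type = "res", name = name, me = me, anomer = anomer,
           linkage = linkage, pos = pos)
    s <- substr(s, consumed + 1L, nchar(s))
    pos <- pos + consumed
  }
  tokens
}

## parse a token span into a residue node; the last token is the local root
parse_tokens <- function(tokens, as_root) {
  n <- length(tokens)
  if (n == 0L) stop("parse error: empty chain", call. = FALSE)
  last <- tokens[[n]]
  if (last$type != "res")
    stop("parse error at position ", last$pos,
         ": expected a residue", call. = FALSE)
  if (as_root && last$linkage != "none")
    stop("parse error at position ", last$pos,
         ": reducing-end residue must not carry a linkage", call. = FALSE)
  if (!as_root && last$linkage == "none")
    stop("parse error at position ", last$pos,
         ": residue '", last$name, "' lacks a linkage to its parent ",
         "(two reducing ends?)", call. = FALSE)
  children <- list()
  i <- n - 1L
  while (i >= 1L) {
    if (tokens[[i]]$type == "]") {
      depth <- 1L; j <- i - 1L
      while (j >= 1L && depth > 0L) {
        if (tokens[[j]]$type == "]") depth <- depth + 1L
        if (tokens[[j]]$type == "[") depth <- depth - 1L
        if (depth > 0L) j <- j - 1L
      }
      if (depth > 0L)
        stop("parse error at position ", tokens[[i]]$pos,
             ": unbalanced ']'", call. = FALSE)
      children[[length(children) + 1L]] <-
        parse_tokens(tokens[seq.int(j + 1L, i - 1L)], as_root = FALSE)
      i <- j - 1L
    } else if (tokens[[i]]$type == "[") {
      stop("parse error at position ", tokens[[i]]$pos,
           ": unbalanced '['", call. = FALSE)
    } else {
      children[[length(children) + 1L]] <-
        parse_tokens(tokens[seq_len(i)], as_root = FALSE)
      i <- 0L
    }
  }
  residue(last$name, anomer = if (as_root) "?" else last$anomer,
          linkage = if (as_root) "none" else last$linkage,
          me = last$me, children = rev(children))
}

#' Parse a condensed glycan structure string
#'
#' See the grammar in the package sources / vignette; examples:
#' `"Gal(b1-4)Fuc(a1-6)GlcNAc"` (the GalFuc epitope on a reducing-end
#' GlcNAc), `"Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc"` (the
#' trimannosyl chitobiose core), `"Gal{1Me}(?1-4)Gal(b1-4)Fuc(a1-6)GlcNAc"`
#' (a methylated second galactose of unknown anomericity).
#'
#' @param text structure string.
#' @param derivatization derivatization state attached to the tree.
#' @return a [glycan_tree()].
#' @export
parse_structure <- function(text, derivatization = "permethylated") {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- tokenize_structure(gsub("[[:space:]]", "", text))
  glycan_tree(parse_tokens(tokens, as_root = TRUE), derivatization)
}

#' Serialize a glycan tree to canonical condensed text
#'
#' The canonical form orders the children of each residue by linkage, then
#' identity, then serialized subtree; the first child is written as the plain
#' chain and the rest in square brackets. `parse_structure()` and
#' `serialize_structure()` round-trip on canonical text.
#'
#' @param tree a [glycan_tree()] (or a bare `glycan_residue`).
#' @return a character scalar.
#' @export
serialize_structure <- function(tree) {
  node <- if (inherits(tree, "glycan_tree")) tree$root else tree
  ser_node(node)
}

ser_node <- function(node) {
  tok <- node$identity
  if (node$me > 0L) tok <- paste0(tok, "{", node$me, "Me}")
  if (node$linkage != "none")
    tok <- paste0(tok, "(", node$anomer, substr(node$linkage, 1, 1), "-",
                  substr(node$linkage, 3, 3), ")")
  kids <- node$children
  if (length(kids) == 0L) return(tok)
  ser <- vapply(kids, ser_node, character(1))
  ord <- order(vapply(kids, function(k) k$linkage, character(1)),
               vapply(kids, function(k) k$identity, character(1)), ser)
  ser <- ser[ord]
  branches <- if (length(ser) > 1L)
    paste0("[", ser[-1L], "]", collapse = "") else ""
  paste0(ser[1L], branches, tok)
}

## ---- traversal -------------------------------------------------------------

tree_nodes <- function(tree) {
  node <- if (inherits(tree, "glycan_tree")) tree$root else tree
  out <- list(node)
  for (ch in node$children) out <- c(out, tree_nodes(ch))
  out
}

#' Monosaccharide composition of a glycan tree
#'
#' @param tree a [glycan_tree()].
#' @return a [composition()] with the tree's derivatization; `nMe` is the sum
#'   of per-residue natural methyl counts.
#' @export
tree_composition <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  nodes <- tree_nodes(tree)
  cls <- vapply(nodes, function(n) n$massClass, character(1))
  composition(hex = sum(cls == "Hex"), hexnac = sum(cls == "HexNAc"),
              dhex = sum(cls == "dHex"),
              me = sum(vapply(nodes, function(n) n$me, integer(1))),
              derivatization = tree$derivatization)
}

#' Monoisotopic m/z of an intact glycan tree
#'
#' Equals [composition_mass()] of [tree_composition()]; under permethylation
#' per-residue natural methyls are ignored (indistinguishable from
#' permethylation methyls).
#'
#' @inheritParams composition_mass
#' @param tree a [glycan_tree()].
#' @export
tree_mass <- function(tree, adduct = "[M+Na]+") {
  composition_mass(tree_composition(tree), adduct)
}

## number of residues
tree_size <- function(tree) length(tree_nodes(tree))
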