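# Builders for the N-glycan structures this glycome is made of:
# Man1-Man6 cores on the chitobiose (GlcNAc-beta1-4-GlcNAc), optionally with
# an alpha1-6 core fucose extended by 0-5 galactoses (the a- to f-form
# core chitobiose modifications), and optional O-methylation.

## mannose arm topologies, as subtree specs on the beta-Man (chains of
## (anomer, linkage) from the beta-Man outward)
.man_arms <- list(
  `1` = list(),
  `2` = list(list(c("a", "1-6"))),
  `3` = list(list(c("a", "1-3")), list(c("a", "1-6"))),
  `4` = list(list(c("a", "1-3")), list(c("a", "1-6"), c("a", "1-6"))),
  `5` = list(list(c("a", "1-3")),
             list(c("a", "1-6"), c("a", "1-3")),
             list(c("a", "1-6"), c("a", "1-6"))),
  `6` = list(list(c("a", "1-3"), c("a", "1-2")),
             list(c("a", "1-6"), c("a", "1-3")),
             list(c("a", "1-6"), c("a", "1-6")))
)

build_man_arms <- function(n_man) {
  if (n_man < 1 || n_man > 6)
    stop("mannose count must be in 1..6", call. = FALSE)
  arms <- .man_arms[[as.character(n_man)]]
  lapply(arms, function(steps) {
    node <- NULL
    for (s in rev(steps))
      node <- residue("Man", anomer = s[[1]], linkage = s[[2]],
                      children = if (is.null(node)) list() else list(node))
    node
  })
}

#' Build an N-glycan with optional core chitobiose modification
#'
#' Constructs a paucimannose / high-mannose tree: `man` mannoses (the
#' beta1-4 Man plus alpha arms per the canonical Man-2..Man-6 topologies) on
#' the chitobiose core, optionally carrying an alpha1-6 fucose on the
#' proximal (reducing-end) GlcNAc extended by `core_gal` 1-4-linked
#' galactoses. The innermost galactose is beta1-4 (the GalFuc epitope) and
#' unmethylated; when `polygal_me = TRUE` (default, mirroring the observed
#' selective methylation) every further galactose carries one O-methyl and
#' unknown anomericity.
#'
#' @param man number of mannoses (1-6).
#' @param fucosylated add the alpha1-6 core fucose.
#' @param core_gal number of galactoses on the core fucose (0-5; forms a-f).
#' @param man_me number of terminal mannoses carrying one O-methyl each.
#' @param polygal_me methylate galactoses beyond the first.
#' @param derivatization derivatization state of the tree.
#' @return a [glycan_tree()].
#' @export
#' @examples
#' build_nglycan(man = 2, core_gal = 1)  # F1H3N2, the m/z 1345.7 b-form
build_nglycan <- function(man = 3, fucosylated = core_gal > 0, core_gal = 0,
                          man_me = 0, polygal_me = TRUE,
                          derivatization = "permethylated") {
  if (core_gal > 0 && !fucosylated)
    stop("core galactoses require the core fucose", call. = FALSE)
  if (core_gal < 0 || core_gal > 5)
    stop("core_gal must be in 0..5 (forms a-f)", call. = FALSE)
  arms <- build_man_arms(man)
  bman <- residue("Man", anomer = "b", linkage = "1-4",
                  children = arms[!vapply(arms, is.null, logical(1))])
  bman <- set_terminal_man_me(bman, man_me)
  distal <- residue("GlcNAc", anomer = "b", linkage = "1-4",
                    children = list(bman))
  root_children <- list(distal)
  if (fucosylated) {
    gal <- NULL
    if (core_gal > 0) {
      for (i in seq_len(core_gal)) {  # outermost first
        depth <- core_gal - i + 1L    # 1 = innermost
        gal <- residue("Gal",
                       anomer = if (depth == 1L) "b" else "?",
                       linkage = "1-4",
                       me = if (depth > 1L && polygal_me) 1L else 0L,
                       children = if (is.null(gal)) list() else list(gal))
      }
    }
    fuc <- residue("Fuc", anomer = "a", linkage = "1-6",
                   children = if (is.null(gal)) list() else list(gal))
    root_children <- c(root_children, list(fuc))
  }
  root <- residue("GlcNAc", children = root_children)
  glycan_tree(root, derivatization)
}

## put one methyl on each of the first k terminal Man residues (depth-first)
set_terminal_man_me <- function(node, k) {
  walk <- function(n, left) {
    if (n$identity == "Man" && length(n$children) == 0L && left > 0L) {
      n$me <- 1L
      left <- left - 1L
    }
    if (length(n$children)) {
      for (i in seq_along(n$children)) {
        res <- walk(n$children[[i]], left)
        n$children[[i]] <- res$node
        left <- res$left
      }
    }
    list(node = n, left = left)
  }
  res <- walk(node, as.integer(k))
  if (res$left > 0L)
    stop("man_me exceeds the number of terminal mannoses", call. = FALSE)
  res$node
}

#' Core-extension form label
#'
#' Maps the number of galactoses on the core fucose to the form letters used
#' for glycomers (a = bare fucose ... f = pentagalactosylated fucose), and
#' back.
#'
#' @param gal integer number of core galactoses (0-5), or a form letter.
#' @return the form letter (for numeric input) or the galactose count.
#' @export
#' @examples
#' glycomer_form(2)    # "c"
#' glycomer_form("c")  # 2
glycomer_form <- function(gal) {
  if (is.character(gal)) {
    i <- match(gal, letters[1:6])
    if (any(is.na(i))) stop("form letter must be a-f", call. = FALSE)
    return(i - 1L)
  }
  if (any(gal < 0 | gal > 5)) stop("form index must be 0..5", call. = FALSE)
  letters[gal + 1L]
}
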