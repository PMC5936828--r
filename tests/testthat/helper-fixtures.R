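# Shared fixtures: random structure/composition generators and independent
# oracles used across test files.

random_composition <- function(derivatization = "permethylated",
                               max_me = if (derivatization == "permethylated") 0 else 6) {
  composition(hex = sample(0:9, 1), hexnac = sample(0:4, 1),
              dhex = sample(0:2, 1), me = if (max_me > 0) sample(0:max_me, 1) else 0,
              derivatization = derivatization)
}

random_tree <- function(max_depth = 3, derivatization = "permethylated") {
  ids <- c("Man", "Gal", "Glc", "GlcNAc", "Fuc", "Hex", "HexNAc", "dHex")
  grow <- function(depth) {
    n_kids <- if (depth >= max_depth) 0L else sample(0:2, 1,
                                                     prob = c(.5, .3, .2))
    kids <- lapply(seq_len(n_kids), function(i) grow(depth + 1))
    residue(sample(ids, 1), anomer = sample(c("a", "b", "?"), 1),
            linkage = sample(c("1-2", "1-3", "1-4", "1-6", "1-?"), 1),
            me = sample(0:2, 1, prob = c(.7, .2, .1)), children = kids)
  }
  root <- grow(1)
  root$linkage <- "none"
  root$anomer <- "?"
  glycan_tree(root, derivatization)
}

## independent elemental-composition oracle: assemble the molecule from
## atom counts and monoisotopic atomic masses
elemental_mz <- function(hex, hexnac, dhex, me = 0,
                         derivatization = "native") {
  am <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
          Na = 22.98976928, e = 0.00054858)
  atoms <- c(C = 0, H = 0, N = 0, O = 0)
  add <- function(atoms, v, times = 1) atoms + v * times
  atoms <- add(atoms, c(C = 6, H = 10, N = 0, O = 5), hex)     # Hex residue
  atoms <- add(atoms, c(C = 8, H = 13, N = 1, O = 5), hexnac)  # HexNAc residue
  atoms <- add(atoms, c(C = 6, H = 10, N = 0, O = 4), dhex)    # dHex residue
  atoms <- add(atoms, c(C = 1, H = 2, N = 0, O = 0), me)       # O-methyl
  atoms <- add(atoms, c(C = 0, H = 2, N = 0, O = 1))           # reducing-end H2O
  if (derivatization == "2AB")
    atoms <- add(atoms, c(C = 7, H = 8, N = 2, O = 0))         # net 2-AB label
  sum(atoms * am[names(atoms)]) + am[["Na"]] - am[["e"]]
}

## naive quadruple-loop enumeration oracle for MS1 assignment
naive_enumerate <- function(mz, derivatization, tolerance,
                            bounds = list(hex = 12, hexnac = 6, dhex = 2,
                                          me = 8)) {
  conv <- mass_convention(derivatization)
  me_max <- if (derivatization == "permethylated") 0 else bounds$me
  hits <- list()
  for (h in 0:bounds$hex) for (n in 0:bounds$hexnac)
    for (f in 0:bounds$dhex) for (m in 0:me_max) {
      theo <- h * conv$residue[["Hex"]] + n * conv$residue[["HexNAc"]] +
        f * conv$residue[["dHex"]] + m * conv$methyl +
        conv$end_intact + conv$na
      if (abs(mz - theo) <= tolerance)
        hits[[length(hits) + 1L]] <- c(h, n, f, m)
    }
  if (!length(hits)) return(matrix(numeric(), ncol = 4))
  mat <- do.call(rbind, hits)
  mat[order(mat[, 1], mat[, 2], mat[, 3], mat[, 4]), , drop = FALSE]
}

perm_comp <- function(hex, hexnac, dhex = 0)
  composition(hex, hexnac, dhex, derivatization = "permethylated")
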