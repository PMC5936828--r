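# Treatment simulation: specificity matching, spectrum shifts, constraint
# inference.

test_that("beta(1-4)-galactosidase removes only terminal unmethylated b1-4 Gal", {
  f1h4n2 <- build_nglycan(man = 3, core_gal = 1)  # GalFuc core, m/z 1549.8
  out <- apply_treatment(f1h4n2, "b14_galactosidase")
  expect_equal(tree_composition(out)$nHex, 3L)
  expect_lt(abs(tree_mass(f1h4n2) - 1549.8), 0.15)
  expect_lt(abs(tree_mass(out) - 1345.7), 0.15)

  # methylated terminal Gal resists (the polygalactosylated forms)
  polygal <- build_nglycan(man = 3, core_gal = 2)  # outer Gal carries 1 Me
  expect_equal(serialize_structure(apply_treatment(polygal,
                                                   "b14_galactosidase")),
               serialize_structure(polygal))
  # unknown anomericity never matches (conservative)
  unk <- parse_structure("Gal(?1-4)Fuc(a1-6)GlcNAc")
  expect_equal(glycomer:::tree_size(apply_treatment(unk,
                                                    "b14_galactosidase")), 3L)
})

test_that("capped and alpha1-6 fucose resist fucosidase and HF", {
  capped <- build_nglycan(man = 2, core_gal = 1)
  expect_equal(serialize_structure(apply_treatment(capped, "a_fucosidase")),
               serialize_structure(capped))
  bare <- build_nglycan(man = 2, fucosylated = TRUE, core_gal = 0)
  expect_equal(serialize_structure(apply_treatment(bare, "hf")),
               serialize_structure(bare))  # HF only cleaves a1-2/a1-3
  # but terminal a1-6 fucose is fucosidase-susceptible
  digested <- apply_treatment(bare, "a_fucosidase")
  expect_equal(tree_composition(digested)$ndHex, 0L)
})

test_that("alpha-mannosidase digests unmethylated Man5 to the core", {
  man5 <- build_nglycan(man = 5, derivatization = "2AB")
  out <- apply_treatment(man5, "a_mannosidase")
  # exhaustive: all four alpha-mannoses go, only the beta-Man core remains
  expect_equal(tree_composition(out)$nHex, 1L)
  # terminal methylation blocks the corresponding arm
  man5me <- build_nglycan(man = 5, man_me = 3, derivatization = "2AB")
  kept <- apply_treatment(man5me, "a_mannosidase")
  expect_gt(tree_composition(kept)$nHex, 1L)
})

test_that("treatments are idempotent at their fixpoint", {
  for (tr in c("b14_galactosidase", "a_mannosidase", "hf")) {
    g <- build_nglycan(man = 5, core_gal = 1, derivatization = "2AB")
    once <- apply_treatment(g, tr)
    twice <- apply_treatment(once, tr)
    expect_equal(serialize_structure(twice), serialize_structure(once))
  }
})

test_that("digestion order matters for capped fucose", {
  g <- build_nglycan(man = 2, core_gal = 1)
  fuc_only <- apply_treatment(g, "a_fucosidase")
  expect_equal(tree_composition(fuc_only)$ndHex, 1L)  # still capped
  seq_digest <- apply_treatment(apply_treatment(g, "b14_galactosidase"),
                                "a_fucosidase")
  expect_equal(tree_composition(seq_digest)$ndHex, 0L)
  expect_equal(tree_composition(seq_digest)$nHex, 2L)
})

test_that("mass conservation holds across random digestions", {
  set.seed(31)
  specs <- builtin_treatments()
  incr <- mass_convention("permethylated")$residue
  for (i in 1:20) {
    tr <- random_tree()
    sp <- specs[[sample(length(specs), 1)]]
    out <- apply_treatment(tr, sp)
    n_before <- tree_composition(tr)
    n_after <- tree_composition(out)
    delta <- tree_mass(tr) - tree_mass(out)
    expected <- (n_before$nHex - n_after$nHex) * incr[["Hex"]] +
      (n_before$nHexNAc - n_after$nHexNAc) * incr[["HexNAc"]] +
      (n_before$ndHex - n_after$ndHex) * incr[["dHex"]]
    expect_equal(delta, expected, tolerance = 1e-6)
  }
})

test_that("predicted shifts reproduce the galactosidase spectrum changes", {
  structures <- list(
    build_nglycan(man = 3, core_gal = 1),                    # 1549.8, b-form
    build_nglycan(man = 3, core_gal = 2),                    # resistant
    build_nglycan(man = 3, fucosylated = TRUE, core_gal = 0) # 1345.7, a-form
  )
  rep <- predict_shift(structures, "b14_galactosidase")
  peak <- function(mz) rep$peaks$status[
    which.min(abs(rep$peaks$mz - mz))]
  expect_equal(peak(1549.8), "reduced")
  expect_equal(peak(1345.7), "increased")
  expect_equal(rep$mapping$mz_before - rep$mapping$mz_after, 204.0998,
               tolerance = 1e-3)

  # identity treatment: everything unchanged
  noop <- treatment_spec("noop", removes = "Glc", anomer = "b",
                         linkages = "1-2")
  rep2 <- predict_shift(structures, noop)
  expect_true(all(rep2$peaks$status == "unchanged"))
  expect_equal(nrow(predict_shift(list(), noop)$peaks), 0L)
})

test_that("constraint inference encodes the decision table", {
  tab <- data.frame(
    treatment = c("hf", "a_fucosidase", "b14_galactosidase",
                  "b36_galactosidase", "a_galactosidase"),
    outcome = c("resistant", "resistant", "susceptible", "resistant",
                "resistant"))
  res <- infer_constraints(tab, has_dhex = TRUE)
  expect_true("Fuc alpha1-6 linked to core GlcNAc" %in% res$constraints)
  expect_true("Fuc capped by hexose" %in% res$constraints)
  expect_true(any(grepl("terminal Gal beta1-4", res$constraints)))

  all_res <- tab
  all_res$outcome <- "resistant"
  amb <- infer_constraints(all_res, pmaa_terminal_gal = TRUE)
  expect_true(any(grepl("methylated OR", amb$ambiguous)))

  expect_equal(infer_constraints(NULL)$constraints, character())
  bad <- rbind(tab, data.frame(treatment = "hf", outcome = "susceptible"))
  expect_error(infer_constraints(bad), "inconsistent")
})
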