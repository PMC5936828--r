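# B/Y enumeration, candidate chitobiose pairs, glycomer calling and the
# relative-distribution statistic.

test_that("chitobiose cleavage yields the printed B/Y pairs of m/z 1345.7", {
  # the two glycomers of parent F1H3N2: Man3 + bare core fucose (a-form)
  # and Man2 + GalFuc (b-form)
  man3a <- build_nglycan(man = 3, fucosylated = TRUE, core_gal = 0)
  fr <- enumerate_BY(man3a)
  chito <- fr[fr$parent_identity == "GlcNAc" & fr$child_identity == "GlcNAc", ]
  expect_equal(round(chito$mz[chito$ion == "B"]), 894)
  expect_equal(round(chito$mz[chito$ion == "Y"]), 474)

  man2b <- build_nglycan(man = 2, core_gal = 1)
  fr2 <- enumerate_BY(man2b)
  chito2 <- fr2[fr2$parent_identity == "GlcNAc" &
                  fr2$child_identity == "GlcNAc", ]
  expect_equal(round(chito2$mz[chito2$ion == "B"]), 690)
  expect_equal(round(chito2$mz[chito2$ion == "Y"]), 678)
  expect_lt(abs(tree_mass(man2b) - 1345.7), 0.15)
})

test_that("B/Y enumeration conserves composition and complementarity", {
  set.seed(21)
  for (i in 1:25) {
    tr <- random_tree()
    parent <- tree_composition(tr)
    fr <- enumerate_BY(tr)
    if (nrow(fr) == 0L) {
      expect_equal(glycomer:::tree_size(tr), 1L)
      next
    }
    for (e in unique(fr$edge)) {
      b <- fr[fr$edge == e & fr$ion == "B", ]
      y <- fr[fr$edge == e & fr$ion == "Y", ]
      expect_equal(b$nHex + y$nHex, parent$nHex)
      expect_equal(b$nHexNAc + y$nHexNAc, parent$nHexNAc)
      expect_equal(b$ndHex + y$ndHex, parent$ndHex)
      # permethylated complementarity: B + Y = intact [M+Na]+ + Na
      expect_equal(b$mz + y$mz, tree_mass(tr) + 22.9892, tolerance = 1e-3)
    }
  }
})

test_that("single residues fragment to nothing; native MS/MS is rejected", {
  expect_equal(nrow(enumerate_BY(parse_structure("GlcNAc"))), 0L)
  expect_error(enumerate_BY(parse_structure("GlcNAc", "native")), "native")
})

test_that("2-AB Y-ions carry the label; B-ions require the opt-in", {
  tr <- build_nglycan(man = 3, core_gal = 1, derivatization = "2AB")
  fr <- enumerate_BY(tr)
  expect_true(all(fr$ion == "Y"))
  chito_y <- fr[fr$parent_identity == "GlcNAc" &
                  fr$child_identity == "GlcNAc", ]
  expect_equal(round(chito_y$mz), 672)  # GalFuc on the 2-AB core GlcNAc
  fr_b <- enumerate_BY(tr, emit_2ab_b_ions = TRUE, b_end = 0)
  expect_true(any(fr_b$ion == "B"))
})

test_that("candidate pairs enumerate the chitobiose splits of the series", {
  # printed fragment values are truncated to integers (1098.53 -> 1098)
  p6 <- candidate_pairs("F1H6N2")
  expect_equal(nrow(p6), 5L)
  expect_setequal(floor(p6$B_mz), c(690, 894, 1098, 1302, 1506))
  # parent m/z 2162.0 resolves to F1H7N2 by arithmetic; its candidate set
  # contains every printed major pair
  p7 <- candidate_pairs("F1H7N2")
  expect_lt(abs(composition_mass(parse_fhn("F1H7N2")) - 2162.0), 0.15)
  pairs <- paste(floor(p7$B_mz), floor(p7$Y_mz))
  expect_true(all(c("690 1494", "894 1290", "1098 1086", "1302 882")
                  %in% pairs))

  p3 <- candidate_pairs("F1H3N2")
  expect_setequal(paste(round(p3$B_mz), round(p3$Y_mz)),
                  c("690 678", "894 474"))

  # complementarity across the whole series
  for (n in 3:7) {
    co <- parse_fhn(sprintf("F1H%dN2", n))
    pp <- candidate_pairs(co)
    expect_equal(pp$B_mz + pp$Y_mz,
                 rep(composition_mass(co) + 22.9892, nrow(pp)),
                 tolerance = 1e-2)
    # no two pairs of one parent share a theoretical fragment m/z
    expect_equal(anyDuplicated(round(c(pp$B_mz, pp$Y_mz), 3)), 0L)
  }
  expect_error(candidate_pairs("H5N2"), "unsupported series")
})

test_that("glycomer calls require both members of a pair", {
  p7 <- candidate_pairs("F1H7N2")
  four <- p7[p7$form %in% c("b", "c", "d", "e"), ]
  sp <- peak_list(c(four$B_mz, four$Y_mz), rep(100, 8), ms_level = 2,
                  parent_mz = 2162.0)
  calls <- call_glycomers(sp, "F1H7N2")
  expect_equal(nrow(calls), 4L)
  expect_setequal(calls$form, c("b", "c", "d", "e"))

  # B present but Y absent: no call
  lone <- peak_list(894.43, 100, ms_level = 2, parent_mz = 1345.7)
  expect_equal(nrow(call_glycomers(lone, "F1H3N2")), 0L)

  # sub-threshold partner: no call
  weak <- peak_list(c(894.43, 474.23, 690.33, 678.33),
                    c(100, 100, 100, 2), ms_level = 2, parent_mz = 1345.7)
  calls2 <- call_glycomers(weak, "F1H3N2", major_ion_threshold = 0.05)
  expect_equal(calls2$form, "a")
})

test_that("synthetic three-glycomer truth is recovered exactly", {
  truth <- c(b = 0.2, c = 0.5, d = 0.3)
  sp <- synthesize_msms(truth, "F1H5N2")
  calls <- call_glycomers(sp, "F1H5N2", major_ion_threshold = 0.05)
  expect_setequal(calls$form, names(truth))
  expect_equal(calls$fraction[match(names(truth), calls$form)],
               unname(truth), tolerance = 1e-9)
})

test_that("relative distribution normalizes pair intensities", {
  calls <- data.frame(form = c("b", "c"), pair_intensity = c(300, 100))
  out <- relative_distribution(calls)
  expect_equal(out$fraction, c(0.75, 0.25))
  one <- relative_distribution(data.frame(form = "c", pair_intensity = 42))
  expect_equal(one$fraction, 1.0)
  expect_error(relative_distribution(data.frame(pair_intensity = 0)),
               "undefined distribution")
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    cc <- data.frame(pair_intensity = runif(k, 1, 100))
    fr <- relative_distribution(cc)$fraction
    expect_true(all(fr >= 0))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("fractions are recovered within 0.05 under 10% intensity noise", {
  truth <- c(b = 0.1, c = 0.45, d = 0.35, e = 0.1)
  set.seed(99)
  noise <- list(mz_sd = 0.02, int_sdlog = 0.1, spurious_rate = 5,
                spurious_frac = 0.01)
  rec <- matrix(0, nrow = 50, ncol = length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in 1:50) {
    sp <- synthesize_msms(truth, "F1H6N2", noise = noise)
    calls <- call_glycomers(sp, "F1H6N2")
    rec[r, calls$form] <- calls$fraction
  }
  expect_lt(max(abs(colMeans(rec) - truth)), 0.05)
})
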