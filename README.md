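# glycomer

Annotation and isomer deconvolution of MALDI-TOF mass spectra of
permethylated and 2-AB-labeled N-glycans.

Invertebrate N-glycomes — flatworms in particular — are dominated by
paucimannose and high-mannose structures whose chitobiose core carries an
unusual modification: an α1-6 fucose on the proximal GlcNAc, extended by
one to five 1-4-linked galactoses (the GalFuc epitope and its poly-Gal
chains), with extensive but selective O-methylation. A single MALDI parent
mass in the Fuc₁HexₙHexNAc₂ (F1HnN2) series therefore hides several
isomers ("glycomers") that differ only in how the n hexoses are split
between the mannose arm and the core-fucose galactose chain. `glycomer`
implements the complete inference chain used to resolve such glycomes:

- **Mass model.** Monoisotopic residue increments per derivatization
  (permethylated Hex 204.0998, HexNAc 245.1266, dHex 174.0892; native/2-AB
  162.0528 / 203.0794 / 146.0579), intact end groups (permethylated
  +46.0419, 2-AB +18.0106 +120.0687), Domon–Costello fragment end groups
  (permethylated B +14.0157, Y +32.0262) and the Na⁺ adduct — all singly
  charged [M+Na]⁺.
- **MS1 annotation.** Exhaustive bounded enumeration of
  (Hex, HexNAc, dHex, Me) compositions within a tolerance, classification
  into paucimannose / high-mannose / F1HnN2 / complex-hybrid, and 14-Da
  methyl-ladder profiling of 2-AB spectra.
- **Glycomer deconvolution.** Cleavage of the facile bond between the two
  core GlcNAcs splits an F1HnN2 glycan into complementary B = HexₐHexNAc₁
  and Y = Fuc₁HexᵦHexNAc₁ ions with a + b = n and
  B + Y = parent + 22.989 (Na). A glycomer (form a–f, b = 0–5 galactoses
  on the core fucose) is called when both pair members are major ions; its
  relative fraction is its B+Y intensity over the summed pair intensities.
- **Treatment simulation.** Built-in specificities for HF, α-fucosidase,
  β(1-4)-, β(1-3/6)- and α-galactosidase and α-mannosidase, with
  O-methylation of the terminal residue blocking hydrolysis; spectrum-shift
  prediction and a decision-table inference from
  susceptible/resistant patterns to linkage constraints.
- **PMAA linkage lookup.** GC-MS signature-ion matching (Jaccard, RT
  tie-break) against the ten-row reference table, plus the
  terminal : 4-linked galactose abundance ratio.
- **Synthetic data.** A seeded generator for the full structural grammar
  (Man-2..Man-6 cores × core-fucose forms a–f × methylation states,
  112 glycoforms by default) and the MS1 / MS-MS / treatment-pair / PMAA
  datasets derived from it, so every stage is testable end to end.

## Worked example

```r
library(glycomer)

## intact mass of the permethylated trimannosyl core, [M+Na]+
composition_mass(composition(3, 2, derivatization = "permethylated"))
#> 1171.6

## the monogalactosylated-core-fucose glycomer of parent m/z 1345.7
## (Man2 core + GalFuc)
tr <- build_nglycan(man = 2, core_gal = 1)
tr
#> <glycan_tree> Man(a1-6)Man(b1-4)GlcNAc(b1-4)[Gal(b1-4)Fuc(a1-6)]GlcNAc [permethylated]
tree_mass(tr)
#> 1345.7

## assign an MS1 peak
enumerate_compositions(1549.8, "permethylated")[1, ]
#>       mz nHex nHexNAc ndHex nMe theoretical   delta  class
#> 1 1549.8    4       2     1   0    1549.772 0.02797 F1HnN2

## deconvolve glycomers from a (here: synthetic) MS/MS spectrum of F1H5N2
sp <- synthesize_msms(c(a = 0.2, b = 0.45, c = 0.35), "F1H5N2")
call_glycomers(sp, "F1H5N2")[, c("form", "B_mz", "Y_mz", "fraction")]
#>   form      B_mz     Y_mz fraction
#> 1    a 1302.6301 474.2310     0.20
#> 2    b 1098.5303 678.3307     0.45
#> 3    c  894.4305 882.4305     0.35

## simulate beta(1-4)-galactosidase digestion: the GalFuc core loses its
## galactose, a 204 Da shift
sprintf("%.1f -> %.1f", tree_mass(tr),
        tree_mass(apply_treatment(tr, "b14_galactosidase")))
#> "1345.7 -> 1141.6"

## PMAA lookup
assign_linkage(c(113, 118, 131, 173, 233), rt = 11.2)$linkage
#> "4-linked galactose"
```

The forms a/b/c called above are the bare-fucose, GalFuc and digalactosyl
core glycomers; their fractions are the relative distribution of isomers
within the parent mass. `run_pipeline(list(seed = 1))` chains all stages
(simulate → annotate → call → treat → infer) into a `glycome_report`, and
`write_report()` serializes it deterministically.

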