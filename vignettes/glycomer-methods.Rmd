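---
title: "Methods: mass conventions, glycomer deconvolution and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass conventions, glycomer deconvolution and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomer)
```

# The problem

MALDI-TOF spectra of released N-glycans report one peak per composition,
but invertebrate glycomes — flatworms especially — hide several isomeric
structures beneath each peak of the Fuc₁HexₙHexNAc₂ (F1HnN2) series.
The n hexoses split between a mannose arm (Man-2 to Man-6 on the distal
core GlcNAc) and a galactose chain on the α1-6 core fucose of the proximal
GlcNAc. Because the glycosidic bond between the two core GlcNAcs is the
most facile cleavage under MALDI-TOF/TOF CID, each isomer announces itself
as one complementary B/Y ion pair. This vignette documents the models,
conventions, parameters and design choices the package uses to turn that
observation into a quantitative pipeline.

# Mass model

All masses are monoisotopic, all ions singly charged sodium adducts —
the only species the underlying experiments report. Other adducts are
rejected rather than silently computed.

Residue (glycosidically condensed) increments, in Da:

| class  | native / 2-AB | permethylated |
|--------|---------------|---------------|
| Hex    | 162.0528      | 204.0998      |
| HexNAc | 203.0794      | 245.1266      |
| dHex   | 146.0579      | 174.0892      |

Permethylation adds one methyl (CH₂, 14.0157 Da) per free hydroxyl/amide:
three per Hex and HexNAc, two per dHex. End-group increments complete the
molecule or fragment:

- intact permethylated: +46.0419 (H₂O plus the two methyls at the opened
  reducing end) + Na;
- intact 2-AB: +18.0106 + 120.0687 (the net 2-aminobenzamide label,
  C₇H₈N₂) + Na;
- permethylated B ion: +14.0157 + Na; permethylated Y ion: +32.0262 + Na;
- 2-AB Y ion: same end group as the intact 2-AB molecule.

Two consequences matter downstream. First, under permethylation a natural
O-methyl is chemically indistinguishable from a permethylation methyl, so
per-residue methyl counts contribute to mass only for native and 2-AB
analyses; this is why methylation profiling requires the 2-AB route.
Second, for permethylated fragments B + Y = intact [M+Na]⁺ + 22.989 (the
second sodium), an invariant the caller exploits and the tests assert to
10⁻³ Da.

These constants are standard monoisotopic values; the test suite refits
the four end-group constants by least squares from the printed anchor
masses (967.5 … 1579.8 intact; 690/894 B; 474/678 Y; 364/672/848/1419.5
2-AB) and verifies the fit lands on the tabled conventions. One caveat
found during calibration: reference spectra print integer fragment masses
by truncation, not rounding (computed 1098.53 prints as 1098, computed
2162.07 as 2162.0), so integer-printed anchors are compared after
truncation while one-decimal anchors are held to ±0.15 Da.

No settled end-group convention reproduced the 2-AB B ions we examined
against the rest of the anchor set, so 2-AB B ions are emitted only behind
an explicit opt-in (`enumerate_BY(..., emit_2ab_b_ions = TRUE, b_end =)`)
with a user-supplied end group, and nothing in the pipeline depends on
them; 2-AB deconvolution rests on Y ions.

# Structure encoding

Structures use a condensed-IUPAC subset read right to left:
`Gal(b1-4)Fuc(a1-6)GlcNAc` puts the reducing-end GlcNAc rightmost,
branches in square brackets
(`Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc`), per-residue methyls
as `{1Me}`, and `?` for unknown anomericity or position. Serialization is
canonical — children ordered by linkage, identity, then subtree — so
`parse` and `serialize` round-trip, which the tests check on 100 random
trees. Unknown linkage or anomericity never matches an enzyme specificity
predicate: inference stays conservative.

# MS1 assignment and methyl ladders

Composition assignment is exhaustive bounded integer enumeration
(defaults Hex ≤ 12, HexNAc ≤ 6, dHex ≤ 2, Me ≤ 8, the last searched only
for native/2-AB), sorted by mass error, then parsimony (fewest residues,
fewest methyls). The default MS1 tolerance is 0.1 Da — looser than the
±0.05 Da instrument accuracy, tighter than anything that would admit a
wrong composition: a brute-force scan in the tests confirms no two
distinct compositions within the 2-AB search bounds sit closer than
0.05 Da. Class labels partition composition space at the boundaries the
observed series define: 2 HexNAc + 0 dHex with ≤ 4 Hex is paucimannose,
≥ 5 Hex high-mannose; 2 HexNAc + 1 dHex is F1HnN2; ≥ 3 HexNAc
complex/hybrid. (The conventional series shorthand is off by one against
the m/z arithmetic — 1345.7 computes as F1H**3**N2 — and the package
trusts arithmetic throughout.)

Methyl-ladder profiling matches peaks at base + k×14.0157 Da; nearest
peak within tolerance wins, ties break toward lower m/z. A peak claimed
by two ladders is split equally with a warning — conserving total
intensity was preferred over any arbitrary winner-takes-all rule.

# Glycomer calling

For an F1HnN2 parent the candidate chitobiose splits are
B = HexₐHexNAc₁ / Y = Fuc₁HexᵦHexNAc₁ with a + b = n, b = 0–5 (forms
a–f), and a ≥ 2 — the smallest B ion the spectra show is Hex₂HexNAc₁ at
m/z 690, consistent with cores trimmed no further than Man-2. A glycomer
is called only when **both** pair members match observed peaks at or above
5% of the base peak ("major" ions carry no printed definition; 5% is the
package default and configurable). MS/MS matching tolerance defaults to
0.5 Da since printed fragment values are integers; when two peaks fall
within tolerance of one theoretical mass the more intense wins. Within a
parent no two candidate pairs share a theoretical fragment mass (asserted
in tests), so a peak supports at most one pair. Relative fractions divide
each pair's B+Y intensity by the summed pair intensities of the parent.
Reference percentages for this statistic exist only as an image in the
source material, so fraction recovery is validated against synthetic
ground truth: exact at zero noise, mean absolute error < 0.05 over 50
replicates at 10% intensity CV.

# Treatment simulation

Each treatment is a specificity predicate: removed identity or mass
class, required anomericity, allowed linkages, terminal-only flag,
methylation blocking, exhaustiveness. The six built-ins follow the
reagents' documented specificities — HF cleaves α1-2/α1-3 fucose
(terminal or internal, exhaustive, not blocked by methylation); the
exoglycosidases (α-fucosidase, β1-4- and β1-3/6- and α-galactosidase,
α-mannosidase) act on terminal residues and are blocked when the terminal
residue itself carries ≥ 1 O-methyl; α-mannosidase and HF iterate to a
fixpoint so newly exposed termini are digested within the same
incubation. Removal of an internal residue (HF only) drops its subtree,
modeling release of everything attached beyond the cleaved bond.
Order sensitivity is real and tested: α-fucosidase alone cannot touch a
Gal-capped fucose, but removes it after galactosidase exposure.

The constraint engine encodes the decision table used on before/after
spectra: HF- and fucosidase-resistance of a fucosylated species ⇒ the
fucose is α1-6 on the core GlcNAc and capped; β(1-4)-galactosidase
susceptibility with a −204 Da (−Hex) shift ⇒ a terminal unmethylated
β1-4 galactose; resistance to all galactosidases despite PMAA evidence of
terminal galactose is returned as an explicitly flagged disjunction
(methylated galactose OR untested anomer/linkage) — the anomericity of
the poly-Gal extensions cannot be resolved by these reagents and the
engine carries that ambiguity rather than resolving it.

# PMAA lookup

PMAA fragmentation chemistry is not simulated; the ten-row reference
table (elution time, EI signature ions, linkage) is authoritative.
Matching maximizes Jaccard similarity of ion sets with a 0.8 cutoff;
terminal mannose and terminal galactose share an identical ion set and are
separated only by retention time (±0.3 min window, nearest wins) — the
0.8 / 0.3 defaults separate every pair of reference rows. Terminal fucose
has no reference row (undetected in this system) and is therefore
unassignable by construction. The terminal : 4-linked galactose ratio is
reported normalized as 1:x.

# Synthetic data: what it emulates, what it does not

The generator's default roster **is** the structural grammar of this
glycome: Man-2..Man-6 cores (canonical arm topologies), each unmodified or
carrying the core fucose with 0–5 galactoses (forms a–f), crossed with
0–3 O-methyls on terminal mannoses — 112 glycoforms, comfortably past the
> 60 the glycome is known to contain. The methylation policy mirrors the
observed selectivity: the first (GalFuc) galactose is never methylated;
every further galactose carries one methyl, which is exactly what makes
the polygalactosylated forms galactosidase-resistant in simulation, as in
the experiment. Abundances are Dirichlet draws with concentration weights
elevated for forms c and d (di/trihexosylated core fucose, the dominant
glycomers). Noise defaults — m/z jitter SD 0.02 Da, lognormal intensity
SD 0.1, five spurious peaks per spectrum at 1% of base — sit below the
matching tolerances but above zero, so matching logic is exercised
without being overwhelmed. One RNG stream per dataset, seeded; outputs
are byte-reproducible.

What the simulation does **not** model: isotope envelopes, multiple
charging or protonated adducts, in-source fragmentation, cross-ring
(A/X) or C/Z fragments, fragmentation-efficiency differences between
isomers, detector saturation, partial digestion time courses, or
chromatographic dimensions. Passing recovery tests therefore demonstrate
the correctness of the inference chain under its own assumptions — not
robustness to every artifact of real spectra. Peak picking and
deisotoping are upstream of this package: inputs are centroided peak
lists.

One synthetic construction deserves a flag: the molar
terminal : 4-linked-galactose ratio of any mixture drawn from the roster
grammar is bounded at 1:4 (a chain of k ≤ 5 galactoses contributes one
terminal and k−1 internal residues), so the 1:8 ratio check uses a
clearly-labelled synthetic structure with a nine-galactose chain
(1 terminal + 8 internal) rather than a grammar mixture. In the real
sample the 1:8 chromatographic ratio plausibly also reflects response
factors and species outside the resolved roster; the package makes no
claim either way.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate/read → assign → call → treat → infer in
fixed order; a parent whose MS/MS fails is recorded as a diagnostic and
the run continues. Reports carry provenance (MD5 of the canonical config
JSON, seed, package version) and serialize with fixed digits and no
timestamps, so identical config and seed give byte-identical files — the
determinism harness in the tests checks exactly that.

Simulation sizes used in the validation suite — 112-structure rosters,
50-replicate recovery studies, 200-draw round-trip and 50-mass
enumeration-oracle checks — were chosen to exercise every code path while
keeping the whole suite fast on a single CPU; all statistics they compute
are stable well below the asserted tolerances at these sizes.

# Known limitations

- The 2-AB B-ion convention is unresolved; 2-AB deconvolution uses Y ions
  only.
- Glycomer fractions are intensity ratios; no correction for differential
  ionization or fragmentation efficiency between isomers is attempted.
- The treatment model is binary (site removed or not); partial digestion
  and kinetics are out of scope.
- PMAA assignment is a table lookup; retention-index calibration across
  instruments and EI fragmentation prediction are not modeled.
- O-glycans, glycopeptides and multiply charged species are out of scope.
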