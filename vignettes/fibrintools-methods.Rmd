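---
title: "Methods: models, parameters and design choices in fibrintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fibrintools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrintools)
```

fibrintools implements the analysis layer of an in-silico fibrinolysis
study: positional protease-specificity scanning of fibrin chains,
docking-peptide preparation, first-principles structural metrics,
catalytic pose screening, trajectory summaries, thermodynamic
conversion, and the clot-lysis statistics. This vignette records the
models behind each piece, the parameters that matter, and the choices
made where the design was genuinely open.

## The specificity model and scanner

Substrate positions are named in Schechter–Berger nomenclature, P4…P1
on the amino side of the scissile bond and P1′…P4′ on the carboxy side;
the bond is cut between P1 and P1′. A specificity model is a set of
*evidence sources*. Each source constrains a subset of the eight
positions with a set of allowed one-letter residues; a position a
source does not mention is unconstrained *for that source*. The bundled
actinidin model has two sources: one derived from observed cleavages of
kiwellin, constraining only P1 ∈ {T,H,R} and P1′ ∈ {T,S,G}, and one
from insulin degradation, constraining all eight positions.

Two design points deserve a note:

* **Combination rule.** The default is `any_source`: a position is a
  site as soon as one source matches completely. With the bundled
  model, an Arg–Gly bond matches the kiwellin source on P1/P1′ alone,
  while Arg–Glu and Lys–Gln bonds fail kiwellin at P1′ and need the
  full insulin column. `any_source` is the only simple rule consistent
  with all of these coexisting as predicted sites, so it is the
  calibrated default; `all_sources` is available in the config for
  enzymes whose evidence should be intersected instead.
* **Per-position sets, not literal pairs.** The kiwellin evidence is
  treated as independent position sets ({T,H,R} × {T,S,G}), i.e. nine
  admissible dipeptides, rather than as the three literal pairs that
  were observed. This follows from reading the definition as columns of
  allowed residues per position; a user who prefers the literal-pair
  reading can express each pair as its own source in the YAML config.

Edge semantics: a source whose constrained positions would extend past
a chain terminus does **not** match there (no wraparound, no partial
credit) — the conservative reading when the reference tool's behaviour
is undocumented. Windows never span a numbering break recorded by
`extract_sequence()`, because a break means the physical chain is not
contiguous there. An `X` at a constrained position makes the window
*indeterminate* (reported via an attribute) rather than matched or
silently dropped.

The scanner is validated against an exhaustive window-by-window oracle
on 100 seeded random sequences, and on planted-motif sequences whose
background alphabet excludes every P1′ residue, so the planted count is
exactly recoverable.

## Peptide windows

Each site yields one docking peptide: the two digestion fragments
flanking the bond, truncated to at most `flank = 10` residues per side
— a 20-mer with the scissile bond at its centre for interior sites.
Adjacent sites are *not* merged into a single longer peptide: each
scissile bond is docked in its own complex, so each site gets its own
window. Truncation happens per side at termini and numbering breaks; a
P1 sitting directly on a break is an error because nothing lies
C-terminal of its bond.

## Sequence identity

`pairwise_identity()` compares equal-length sequences position-wise;
unequal lengths are first globally aligned with Needleman–Wunsch
(match +1, mismatch 0, linear gap −1). On score ties the traceback
prefers a residue pair, then a gap in the second sequence, then in the
first — a deterministic leftmost-gap rule, documented because alignment
software rarely pins it down. The identity denominator is the aligned
length including gap columns; for the equal-length case this is just
the sequence length, so a single substitution in a 218-mer gives
217/218 = 99.5 %.

## Structural metrics

**Superposition.** `kabsch_superpose()` computes the least-squares
rigid transform by SVD of the 3×3 covariance, with the determinant
correction that excludes reflections. Collinear point sets are rejected
(the rotation is undetermined). The implementation is checked against
an independently coded quaternion (Horn) method to 10⁻⁹ Å on 100 seeded
clouds. `rmsd_series()` fits every frame to the reference on the same
selection it scores — the molecular-dynamics convention — with no mass
weighting.

**Torsions.** φ(i) = dihedral(C(i−1), N(i), CA(i), C(i)), ψ(i) =
dihedral(N(i), CA(i), C(i), N(i+1)), IUPAC sign convention (0° at cis,
positive clockwise looking down the central bond); the convention is
stated explicitly and pinned by a hand-computed four-point case
(−90°). Terminal residues have the undefined angle set to `NA`.

**Ramachandran regions.** Classification uses bundled polygons: simple
convex outlines around the α-helical, β-sheet and left-handed-α basins,
with `favored` the tight outline and `allowed` a dilated one. These are
deliberately schematic package data — published probability contours
derived from curated structure databases are not redistributable as
formulas — and are swappable via the `regions` argument. Consequently
region *labels* are calibration data, not results; no claim is made of
reproducing any published contour percentage.

**SASA.** Shrake–Rupley: each atom is covered with `n_points = 960`
deterministic Fibonacci-spiral points at radius r_vdw + probe
(probe 1.4 Å, water); a point is exposed iff outside every neighbour's
expanded sphere. Van der Waals radii are a bundled table (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20 Å) following common SASA practice, with
a per-call override; the radii used are echoed in the result object.
Accuracy is pinned by closed forms: an isolated carbon to 0.5 %, an
overlapping pair against the analytic two-cap formula to 2 %, and a
960-vs-4000-point convergence check under 1 %. Whether the "unbound"
surface of a cleavage site should be computed on the isolated 20-mer or
on the intact chain is ambiguous in general; both are possible by
passing the corresponding atom subset, and neither is asserted as
canonical.

## Pose screening and trajectories

A pose is *accepted* when the SG–C distance — catalytic cysteine Sγ to
the P1 carbonyl carbon — is ≤ the threshold. The default threshold is
5.0 Å with 4.5 Å as the stricter alternative, both being literature
values for the maximum distance at which nucleophilic attack is
considered feasible; the threshold used is always echoed in the output.
Only the nucleophile distance is gated: His/Asn triad geometry is
measured and reported but not thresholded, because the corresponding
published screens were visual and give no reducible criterion.

Hydrogen bonds are geometric: donor–acceptor ≤ 3.5 Å and, when the
donor carries a hydrogen, some H–D–A angle ≤ 30° — the common MD
convention, used because no criteria are otherwise stated. Without
hydrogens the angle term is skipped (and logged). Counting is validated
against exhaustive enumeration. Quartiles in `five_number()` are R's
default linear-interpolation (type 7) quantiles.

ΔG↔K_d conversion uses K_d = exp(ΔG/RT) with R = 1.9872×10⁻³
kcal·mol⁻¹·K⁻¹ and T = 310.15 K by default — the dimensionless
exponential form with no standard-state concentration, matching how
docking post-processors report it.

## Clot-lysis statistics

The degradation percentage defaults to the assay's printed formula,
(initial − final)/**final** × 100. This is unusual — most lysis assays
divide by the initial weight — so the conventional form is available as
`convention = "fraction_of_initial"` and the convention used is always
attached to the output; with no published raw weights, neither can be
validated against the wet-lab numbers, and no attempt is made to.

`anova_posthoc()` is classical one-way fixed-effects ANOVA (delegated
to `stats::aov`; an independent sums-of-squares oracle checks it in the
tests) followed by all pairwise t tests, pooled-variance by default
(Welch by flag), adjusted by **both** Bonferroni and Holm and reported
side by side — the source method names both without saying whether they
were combined, so neither is hidden. Degenerate inputs (identical
groups, zero within-group variance) take an explicit F = 0, p = 1 path
rather than dividing by zero. Calibration: on 1,000 null replicates the
test rejects at α = 0.05 within 5 % ± 1.5 points. A worked example
{0.010, 0.030, 0.040} at α = 0.05 steps to Bonferroni {0.03, 0.09,
0.12} and Holm {0.03, 0.06, 0.06}: each procedure rejects exactly the
first hypothesis, and Holm is never above Bonferroni.

## What the synthetic generators emulate — and what they do not

Every consuming analysis has a seeded generator that plants a known
truth it must recover; that inverse property is the backbone of the
test suite.

* `gen_sequence()` plants P4…P4′ octamers drawn from the model's
  allowed sets on a background alphabet excluded from every P1′ set, so
  background sites are impossible; because uniformly drawn octamers can
  still create accidental matches at other offsets, the generator
  redraws (seeded, at most 1,000 attempts) until a scan finds exactly
  the planted sites. `gen_fibrin_chains()` uses this to lay out the
  reported fibrin site positions (Aα 162/171, Bβ 346, γ 406) on chains
  of roughly fibrin-like length; `gen_actinidin_pair()` builds a
  218-mer pair differing only at position 101 (E vs D). Both are
  clearly labelled synthetic stand-ins: they exercise exactly the code
  paths real sequences would, but passing on them shows correctness of
  the scanner and identity machinery, not anything about real fibrin
  or real actinidin.
* `gen_polypeptide()` builds ideal-geometry backbones (N–CA 1.458,
  CA–C 1.525, C–N 1.329 Å; angles 111.2°, 116.2°, 121.7°) whose
  interior torsions equal the requested (φ, ψ) exactly — the ground
  truth for the torsion code.
* `gen_pose()` and `gen_trajectory()` are deliberately minimal —
  backbone plus the named key atoms, not physically relaxed. They are
  sufficient for geometric metrics (planted SG–C distances recoverable
  to 10⁻⁶ Å; planted hydrogen-bond counts exactly) and honest about
  not being MD-quality structures. The `"bad-pose"` preset mirrors the
  negative-control design of the motivating study: a 7 Å initial SG–C
  distance, a plateau near 5.5–6.4 Å, and few hydrogen bonds, which
  the analysis must separate from a competent pose at α = 0.01.
* `gen_clot_table()` plants dose-ordered degradation means
  (control ≈ 12 %, mid ≈ 55 %, high ≈ 73 % — the reported ordering) on
  triplicates with σ = 2 percentage points, a replicate scatter
  consistent with standard errors of the order reported for such
  assays; initial weights are uniform on 0.10–0.15 g, the stated clot
  size range.

Problem sizes in the routine runs — 60-mers and 100 seeds for scanner
oracles, 10-point clouds for superposition, a 10,000-frame trajectory
for quartile recovery, 1,000 null replicates for calibration — were
chosen so the full suite completes on a single CPU in well under ten
minutes while keeping Monte-Carlo tolerances tight (quartile recovery
to ±0.02 Å relative, type-I rate to ±1.5 points).

## Known limitations

* The headline wet-lab and heavyweight in-silico numbers of the
  motivating study (the 0.350 Å superposition of a predicted structure,
  docking SASA/ΔG tables, 100-ns trajectory hydrogen-bond means,
  73.0 ± 1.12 % clot reduction) require external artifacts — predicted
  structures, docked poses, production trajectories, raw assay weights
  — and are out of scope; the package computes the *methods*, and its
  tests assert their correctness on constructed ground truth.
* PDB parsing is fixed-column v3.3 only (no mmCIF, no compressed
  trajectory formats); trajectories are multi-model PDB.
* No probabilistic/PSSM scoring or cleavage-efficiency prediction; the
  specificity model is set-based.
* Hydrogen-bond detection does not infer missing hydrogens; it falls
  back to the distance criterion.
* The compact letter display uses the standard greedy insert-absorb
  heuristic on the Holm-adjusted pairwise flags; for many groups with
  tangled non-significance patterns the lettering is a readable
  summary, not a unique canonical form.
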