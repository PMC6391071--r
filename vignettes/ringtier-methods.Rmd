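---
title: "Measuring ring opening in hexameric helicase assemblies"
author: "ringtier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ring opening in hexameric helicase assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtier)
```

## The problem

Hexameric replicative helicases are closed protein rings built from six
protomers, each contributing an N-terminal domain (NTD) to one stacked
layer and a C-terminal motor domain (CTD) to another. Loading such a ring
onto an endless ssDNA substrate requires a loader protein that cracks one
subunit interface and reconfigures the two layers into open, right-handed
spirals. The transition is quantified with a small set of geometric
observables — per-subunit helical rise and twist of each tier, the angle
between tier planes, the width of the breached interface, the inner
chamber diameter — complemented by buried-surface measurements of how
tightly the layers are held, native-MS arithmetic that pins down how many
loader protomers are bound, and crosslinking-MS distance restraints that
validate the model. `ringtier` implements all of these behind one
consistent set of conventions, plus generators of synthetic assemblies
with known ground truth so that every measurement can be verified
end-to-end without external data.

## Tier geometry

### Ordered domain centers

A *tier* is an explicitly ordered list of domains (chain + inclusive
author-numbered residue interval), bottom of the spiral first. The order
is part of the input — it is never inferred from chain identifiers,
because deposited models name chains in ways unrelated to spiral
position. Each domain is reduced to a center of mass; both
atomic-mass-weighted and uniform ("center of geometry") averaging are
available because published protocols are often silent on the choice, as
are all-atom versus Cα-only selections. Domains with unmodelled intervals
contribute the COM of their modelled atoms, with the modelled fraction
reported alongside. On synthetic assemblies the two weightings coincide
(all pseudo-atoms are carbon); on real models the difference is well
below the scale of the quantities of interest.

### Planes and inter-tier angles

The plane through a tier is the least-squares plane of its domain
centers: centroid plus the smallest principal component of the centered
points. The angle between two tiers is the *acute* dihedral
`acos(|n_a · n_b|)`, symmetric and bounded in [0°, 90°]. (A published
description of this angle as "the arc-cosine of the quotient of the dot
product and the cross product" of the normals is not a well-formed scalar
expression; the normalized-dot-product reading is the only standard one
and is what the reported inter-tier angles are consistent with.) Note
that the best plane of a *rising* spiral is itself inclined to the helix
axis, so inter-tier angles are meaningful between tiers of comparable
rise — the synthetic tests therefore plant tilts between planar rings,
where the recovery is exact.

### Pseudo-helical parameters

Given an ordered center series and an axis, each consecutive pair yields
a rise (difference of axial coordinates) and a signed twist (angle
between the radial components, positive = right-handed screw when the
axis points along increasing rise). A tier is summarised by the means,
the mean radius, and the *turn pitch* `pitch = rise × 360 / |twist|` —
the axial distance per full turn of the idealised helix. An alternative
reading of "pitch" for an open spiral is the *axial extent* of the
observed arc (`(n−1) × rise` for n subunits); both are computed and
reported side by side, because published pitch figures for these
assemblies do not satisfy the turn-pitch identity and their operational
definition cannot be recovered from the text. Neither value is asserted
against published pitches; rise and twist are the load-bearing
quantities.

### Axis fitting and its degeneracy

No standard protocol exists for fitting the pseudo-helical axis of six
points, so the package defines one and documents it. For a candidate
direction, the optimal axis anchor has a closed form: project the points
along the direction and fit a circle center by linear least squares. The
direction itself is refined by Nelder–Mead on the variance of
point-to-axis radii (an ideal helix has constant radius), started from
the plane normal of the points, from the mean cross product of
consecutive chords (much closer to the axis for steep helices), and from
the best cells of a coarse 15° direction grid; two polishing passes run
per start, with an iteration budget of 200 per pass and convergence at
1e-9 on the variance.

Radial variance alone does not identify the axis: a finite helical point
set can be *exactly* equidistant from more than one line, the discrete
analogue of aliasing when sampling a sinusoid. For six points generated
with rise 7.4 Å / twist 60°, a second zero-variance axis exists whose
implied per-step rises are wildly uneven (≈ 13.0, 0.5, −5.7, 0.5,
13.0 Å). The fitter therefore breaks near-ties in radial variance by the
evenness of the rise steps — the generating axis gives (near-)constant
rise, spurious axes do not. With this rule, noise-free generated helices
across rise 0.5–10 Å, twist 30–70°, radius 10–50 Å are recovered to 1e-6
relative, and a brute-force 2° grid search never beats the refined fit.

### Gaps, diameters, rotations

Breach widths are minimum inter-atomic distances between the two domains
flanking an interface; all-atom is the default, with Cα-only and
vdW-subtracted (surface-to-surface) modes selectable, since published
"gap" figures rarely state the convention. Chamber diameters partition a
tier's atoms into 5 Å axial slabs and report, per slab,
`2 × min(distance to axis − vdW radius)`; the headline value is the
tightest positive slab (the constriction). Subunit rotations between two
conformers superpose both models on an anchor domain (Kabsch, proper
rotation), then extract the residual rotation angle
`acos((tr R − 1)/2)` of the probe domain; per-residue Cα displacements
use the same anchor superposition. The cis/trans conformer call for a
protomer tests whether the NTD helical hairpin points toward (< 90° at
the globe COM) or away from the same chain's CTD.

## Surface areas

SASA is Shrake–Rupley sampling on a golden-spiral lattice: deterministic
for a given point count, so results are bit-reproducible. The default is
960 points per atom (single-sphere analytic error < 1 %; doubling the
lattice changes totals by < 0.5 % on test assemblies) with a 1.4 Å water
probe and Bondi vdW radii (table shipped and versioned). Hydrogens are
absent from the models of interest and simply treated as atoms when
present. Buried surface area is reported two-sided,
`BSA = SASA(A) + SASA(B) − SASA(A∪B)`, with the halved one-sided value
alongside, because published values rarely state the convention.
Interface residue lists use a 4 Å any-atom contact cutoff and a 10 Å
atom-to-Cα footprint cutoff, both configurable.

## Native-MS arithmetic

All masses are average masses — appropriate for intact assemblies of
hundreds of kDa, where isotopic structure is unresolved. Protein masses
are summed from a fixed residue table plus water, with optional
N-terminal Met loss; ssDNA masses from deoxynucleotide-monophosphate
residues plus water, with 5′/3′ OH-versus-phosphate termini differing by
one HPO₃ (79.98 Da). The 43-mer origin-derived strand with both termini
OH computes to 13,140.4 Da, matching its published 13,141 Da within
rounding of the residue table.

Stoichiometry assignment enumerates every composition within bounded
per-component count ranges, keeps those within tolerance of the measured
mass, and ranks by |Δ|, ties broken by fewer total subunits then
lexicographically. The count bounds are scientific constraints, and they
matter: the 446.5 kDa species is assigned hexamer + 5 loaders over fully
open ranges, but for the 473.1 kDa species an unconstrained search finds
a 5-helicase/8-loader composition 99 Da closer than hexamer + 6 loaders.
Since the helicase is a constitutive hexamer (six protomers are present
in every relevant assembly), the package's worked analyses fix the
helicase count at six when assigning loader stoichiometry; with that
constraint the 473.1 kDa species is hexamer + 6 loaders, as expected.
This is the textbook reason composition decomposition should encode
known biology in its bounds rather than rely on mass proximity alone.

Charge-series inference implements the standard consecutive-charge
identity: for adjacent peaks m₁ > m₂, the lower peak's charge is
`round((m₁ − A)/(m₁ − m₂))` with A the adduct (proton) mass, and each
peak then yields an estimate `M = z(m − A)`. The mean over peaks is
reported with its SD; a series whose per-peak estimates scatter beyond
100 ppm of the mean is rejected as inconsistent with any
consecutive-charge assignment (instrument-level m/z noise keeps the
scatter in the Da range; misassignment disperses it by orders of
magnitude). Per-peak residuals localise corrupted peaks. Magnesium
adduction, which broadens native-MS peaks in magnesium-containing
buffers, is outside the model and only affects the measured values fed
in.

Fixed component masses (helicase protomer with N-terminal Met loss
52,259 Da; loader protomer 26,518 Da; 43-mer ssDNA 13,141 Da) ship as
defaults. Expected masses built from these rounded values can differ by
1 Da from sums computed with unrounded masses, so regression checks
carry a ±2 Da tolerance; percent errors are computed before rounding and
reproduce published two-decimal values regardless.

## Crosslink restraints

DSS crosslinks lysine pairs whose Cα–Cα distance is compatible with
roughly 30 Å. Pair tables (protein, residue, protein, residue) are
mapped onto a model through a protein→chains map; in a homo-hexamer a
pair is satisfiable by many chain combinations, so the default distance
is the minimum over allowed chain pairs, with a fixed-chain mode for
reproducing a specific published mapping. Distances default to Cα–Cα
(side-chain NZ atoms are often unmodelled at moderate resolution; NZ
mode is selectable, and the shipped table's published evaluation does
not state which atom was used — both are computed). Pairs touching
residues absent from the model are *unmapped*, never counted as
violated. Raising the cutoff can only grow the satisfied count, and
planted fixtures recover their violation counts exactly in both atom
modes.

## Synthetic assemblies

Generators are pure functions of their parameter records, including the
seed (R's Mersenne–Twister, set per call), and every fixture carries its
ground truth so tests never hand-copy numbers. Subunits are clouds of
carbon pseudo-atoms (one per residue, named CA, optionally with an
offset NZ partner) whose COM sits exactly on the generating helix point;
a single element keeps the SASA and diameter oracles analytic. Planted
breaches displace the subunits after the breach along the opening
direction with a linear taper — full displacement beside the breach,
none at the far end — so the wrap-around interface stays closed and the
planted opening is the unique widest gap, as in a ring-opening
transition; the realised gap is solved to < 0.01 Å by fixed-point
iteration. Multi-tier builds add a second ring/spiral with its own
rise/twist, axial offset and inter-tier tilt.

What the fixtures do *not* emulate: real domain shapes and packing,
side-chain chemistry, heterogeneous B-factors/occupancies, or
partially modelled chains. Passing the synthetic battery demonstrates
the correctness of the measurements' geometry and arithmetic; it does
not by itself validate conclusions about any particular deposited model.
Analyses of the deposited open-spiral complex and its comparators are
wired in `accessionBattery()` and run against a local cache populated by
`downloadAccessions()` (network required once); tier definitions for
those models ship in `inst/extdata/`, including both circulating
conventions for the NTD globe interval (31–113 and 32–123/124–173),
which disagree in the literature and are therefore both selectable with
no claim as to which is canonical.

## Problem sizes and determinism

The default test battery uses 6–8-subunit assemblies of 30–40 atoms per
domain, 960–1920-point SASA lattices, an 18-cell helix-recovery grid and
100-replicate charge-series calibration; the full suite runs in well
under a minute of CPU. Reports produced by `runReport()` are
byte-identical across reruns with the same inputs, and every report
block records the convention settings (COM weighting, gap mode, distance
atom, cutoffs) it was computed with.

## Known limitations

- The axis fit is defined for ordered series of ≥ 3 (practically ≥ 4)
  points; with exactly 3 points the helix is underdetermined and results
  reduce to circle geometry.
- SASA is O(N²) in atoms per group; it is intended for tier-scale
  selections (10³–10⁴ atoms), not whole large complexes at high lattice
  density.
- Cross-species comparisons require explicit residue-correspondence
  intervals in the tier configs; no sequence alignment is performed.
- Published pitch values for these assemblies cannot be reproduced under
  either computed definition (see above); rise and twist are asserted
  instead.
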