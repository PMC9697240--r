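---
title: "Methods: rigid-body step geometry, pucker and interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body step geometry, pucker and interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucgeom)
```

## Scope and model

`nucgeom` measures the local coiling of nucleic-acid strands with the
rigid-body formalism used throughout the nucleic-acid structure
literature: each base carries an orthonormal reference frame, and the
geometry between consecutive frames is summarized by six step
coordinates plus two helical coordinates.  The package applies the same
formalism to single strands (frames on bases), duplexes (frames on
Watson–Crick base pairs), and multi-model ensembles, and complements it
with sugar-pucker analysis and geometric stacking/hydrogen-bond
detection.  A fiber-model generator provides structures whose true
parameters are known by construction, which is how the package validates
itself.

### Base frames

The frame of a base is obtained by least-squares superposition of a
standard base geometry — expressed in the standard (Tsukuba-convention)
reference frame and shipped as a versioned text table in
`inst/extdata/standard_bases.tsv` — onto the observed ring atoms (9 for
purines, 6 for pyrimidines; exocyclic atoms are excluded from the fit
but included in base centers).  The solver is a quaternion-free
Kabsch/SVD superposition with determinant correction, so near-planar
rings can never produce an improper (mirror) rotation.  Because a planar
point set is achiral, the mirror of a base fits with the same residual
as the original; the determinant constraint is what keeps the recovered
frame right-handed.

Watson–Crick pair frames flip the strand-II frame by a 180° rotation
about its x-axis and then take the rigid mean of the two frames: average
origin, and the rotation halfway along the geodesic of the relative
rotation.  Pairs whose z-axes still subtend more than 90° after flipping
are rejected as non-Watson–Crick.

### Step and helical coordinates

`step_parameters()` implements the mid-frame (CEHS-style) construction:
the bending angle γ between the two z-axes is removed symmetrically by
rotating each frame by ∓γ/2 about the hinge axis z<sub>i</sub> ×
z<sub>j</sub>; twist is the signed angle between the rotated y-axes
about the common z; (shift, slide, rise) is the inter-origin vector read
in the mid-frame whose y-axis bisects the rotated y-axes; and γ is
decomposed into roll = γ·cos φ and tilt = γ·sin φ with φ the hinge phase
from the mid-frame y-axis.  This convention was chosen (over axis-based
alternatives such as Curves+) because it is the one used by the
3DNA-family tools whose outputs the package's numbers are meant to be
comparable with.  `build_step()` is the closed-form inverse, which gives
the package its strongest self-test: build-then-measure round trips
recover random parameter sets to 10⁻⁶.

Helical coordinates come from the axis-angle decomposition of the
relative rotation: helical twist is the rotation angle about the helical
axis, helical rise the projection of the inter-origin vector onto it,
signed along the 5′→3′ advance.  Two conventions deserve note:

* **Origins versus centers.** Helical rise projects the *frame-origin*
  difference by default, the de facto standard.  A `centers` argument
  accepts base geometric centers instead, for the reading in which the
  projected vector links base centers; for ideal fiber geometry the two
  coincide.
* **Degenerate rotations.** When the relative rotation is below 0.01°
  the helical axis is taken as the mid-frame z-axis, so a pure
  translation reports h\_twist = 0 and h\_rise equal to the translation
  component along z.

Angles are reported in (−180°, 180°], ties at ±180° resolved to +180°.
Steps whose z-axes subtend ≥ 90° (flipped bases) are an error rather
than a number, as the mid-frame construction is meaningless there.

### Sugar pucker and torsions

The five ring torsions ν0–ν4 follow the standard furanose definitions;
pseudorotation uses the Altona–Sundaralingam phase formula with the
quadrant fixed by the sign of ν2.  The amplitude τ<sub>m</sub> is
recovered by orthogonal projection onto ν<sub>j</sub> =
τ<sub>m</sub> cos(P + 144°(j−2)) rather than the textbook quotient
ν2/cos P, which is identical for exact sinusoids but numerically
unstable where cos P vanishes (P near 90°/270°).  A planar ring (all ν =
0) has no defined phase and raises an error rather than returning an
arbitrary value.

Pucker classes use the coarse ten-name wheel of 36°-wide sectors
centered at 18° + k·36° (C3′-endo at 18°, …, C2′-endo at 162°), with
half-open sectors [center − 18°, center + 18°) so boundary phases
classify deterministically; a finer 20-name wheel is available behind
`fine = TRUE`.  The coarse wheel is the default because pucker
distributions in this problem domain are discussed in terms of those ten
families.

All dihedrals follow the sign convention of the established tools
(verified in the test suite against bio3d's torsion code), so backbone
torsion tables are directly comparable with published values.

### Stacking and hydrogen bonds

The stacking criteria are geometric and threshold-based: minimum
base-heavy-atom distance < 4 Å, base center-of-mass distance < 5 Å, and
base-normal angle in [0°, 45°) ∪ (135°, 180°].  All three thresholds are
exposed (`default_thresholds()`), comparisons are strict inequalities
("lower than" read literally), and all three diagnostics are always
reported so borderline pairs can be inspected.  Centers of mass use
standard atomic masses over the nucleobase atoms with hydrogens included
when present; a centroid mode exists for heavy-atom-only reasoning.
Normals are unsigned plane normals folded to [0°, 180°], which makes the
two allowed angular windows equivalent to a sign-free test.

Hydrogen bonds X⋯H–Y require X, Y to be base nitrogens/oxygens of
*different* nucleobases, H covalently bound to Y (< 1.2 Å, resolved to
the nearest heteroatom), d(X,Y) < 3.3 Å and ∠XHY > 150°.  Structures
without explicit hydrogens are refused unless idealized base hydrogens
are requested: amino hydrogens are placed in-plane at ±60° from the C–N
extension, imino hydrogens along the external bisector, both at 1.01 Å.
Donor/acceptor bookkeeping is purely geometric; no energetic scoring is
attempted.

`trajectory_stats()` evaluates both detectors in every model of a
multi-model structure: stacking for *all* residue pairs (adjacent pairs
yield fractions of models, non-adjacent pairs occurrence counts), bonds
per model, and persistence as the number of identical (X, H, Y) triples
detected in consecutive models.

## The fiber-model generator

The generator stands in for external model-building software and for
molecular-dynamics ensembles.  What it emulates, and what it does not,
determines what the package's green tests mean.

Uniform step parameters for the two canonical families are shipped as a
documented table (`inst/extdata/fiber_steps.tsv`): the B form uses the
calf-thymus fiber values (twist 36°, rise 3.38 Å, vanishing slide/roll,
C2′-endo sugars, anti χ = −105°), the A form 32.7° twist with slide
−1.5 Å and roll +12°, C3′-endo sugars, χ = −160°.  These are inputs, not
constants in code; structures are built by chaining `build_step()`
transforms and placing per-base atom templates into the resulting
frames, and duplexes add the complementary strand through the
Watson–Crick frame flip.  With the A-form values the helical rise
evaluates to ≈ 2.6 Å, well below the 3.3 Å stacking rise — the
qualitative A/B discriminator the analysis side tests for — while the
B form has helical and step coordinates coinciding by construction.

Sugar templates are built at load time rather than recalled from a
table: ring coordinates are generated from an out-of-plane displacement
model whose two parameters are solved numerically so that the measured
pseudorotation phase and amplitude equal the form's targets exactly;
the ring is then anchored to the base through the glycosidic torsion,
O3′ is placed by the form's canonical backbone δ, and the two free
dihedrals of the O5′/P branch are calibrated so the next residue's P
closes onto O3′ at the 1.60 Å phosphodiester bond length under the
form's own step transform.  This yields chemically plausible backbone
torsions without any force field.  The calibration targets the uniform
helix; in heavily perturbed conformers the backbone does not re-close,
which is a stated non-goal (detectors and step measures, not backbone
refinement, are under test).

`build_unstacked()` produces the deterministic elongated conformer: per
step, rise 7 Å and roll 60° with alternating sign.  The 60° roll places
every adjacent normal angle inside the forbidden window, and the 7 Å
rise defeats both distance criteria, so the conformer fails all three
stacking tests at once — the only property the original (a
force-field-minimized structure with dispersion disabled) contributes
to the analysis.

`make_mock_trajectory()` samples each snapshot independently: per
adjacent step, the template's own geometry (stacked) or the
unstacked-replacement geometry, with programmed probability
p<sub>i</sub>, plus isotropic Gaussian coordinate noise (default
σ = 0.05 Å, small enough that detection never flips on noise alone).
There is no kinetics — snapshots are exchangeable — because the
quantities under test are per-snapshot detections and their
aggregation, not dynamics.  Hydrogen-bond events are staged at a
programmed per-snapshot rate by rigidly translating the 3′-terminal
residue so one acceptor sits at 2.9 Å along a 5′-donor N–H axis
(∠XHY = 180°), then rotating it about that axis until exactly one triple
satisfies the criteria; the affected final step is thereby unstacked and
the returned ground-truth labels record that.  Events are never placed
in consecutive snapshots, so the true persistence count is zero, mirror
of the observation the persistence statistic exists to make.  The
generator returns its truth alongside the structure, and the test suite
requires the detectors to reproduce it exactly (labels) and to recover
the programmed rates within 3 binomial/Poisson standard deviations.

What the generator does *not* emulate: sequence-dependent step
variation, correlated motions, solvent and ions, backbone closure in
perturbed conformers, non-canonical pairing.  Green tests therefore
certify the measurement machinery — frames, steps, pucker, detectors,
aggregation — on geometry with known truth; they do not certify claims
about real ensembles, which enter only through user-supplied PDB files.

## Numerical choices

* Superposition: SVD with smallest-singular-direction sign flip;
  proper rotations always.  RMSD after superposition is the objective
  value itself.
* Hinge detection: the mid-frame branch switches to the unbent case on
  the hinge-vector norm (< 10⁻⁹), not on the angle, so exactly parallel
  z-axes cannot reach the normalization of a zero axis.
* Averages are arithmetic, including angles: all in-scope values sit far
  from the ±180° wrap, and arithmetic means match how such tables are
  conventionally reported.  Circular averaging is deliberately not used.
* The A/B dividing line in the slide–roll plane defaults to
  roll = 4° − 4°·slide/Å.  The line is a configurable stand-in
  calibrated so the canonical fiber A and B steps fall on their correct
  sides (A-like iff roll exceeds the line; on-line points are B-like);
  published analyses cite such a line from external work without
  printing it, so the package owns an explicit, overridable default.
* Multi-model input (NMR ensembles, trajectories) is analyzed on model 1
  by default with the model index exposed everywhere; which deposited
  NMR model "the" analysis should use is a user decision the package
  does not make silently.
* Homo-dinucleotide group averages (AA/TT/CC/GG) pool steps from both
  strands in per-strand mode, matching how single per-step-type numbers
  are reported for duplexes.
* PDB atom-name dialects are normalized on input (`C1*` → `C1'`,
  `O1P` → `OP1`, `C5M` → `C7`); residues are renumbered 1..n per strand
  with direction inferred from O3′(i)→P(i+1) connectivity (< 2 Å),
  falling back to author ordering when phosphates are absent.  Common
  solvent/ion residues are dropped; any other unrecognized residue name
  is an error naming the residue.

## Problem sizes

The validation suite uses sizes chosen to give sharp statistical bounds
while remaining quick on a single core: 1000 random step-parameter round
trips, a 360-point pseudorotation grid, 5000-snapshot trajectories for
the stacking-fraction regimes (binomial 3σ ≈ 0.02 at p = 0.6), and a
25 000-snapshot run at the sparse hydrogen-bond rate of 104 events per
5 × 10⁴ snapshots (Poisson 3σ ≈ 22 at λ = 52).  The acceptance script
analyzes a single dodecamer duplex and completes in seconds.

## Known limitations

* Canonical deoxynucleotides only: no RNA, modified bases, mmCIF, or
  binary trajectory formats.
* The fiber templates idealize the backbone; ε/ζ torsions of generated
  structures are plausible but not fiber-refined, and sugars carry no
  hydrogens.
* Stacking is a geometric classification, not an energy; π-overlap
  areas and energetic scores are out of scope.
* Base-pair-internal parameters (buckle, propeller, opening) are not
  computed; pair frames serve only as step endpoints.
* The experimental regression against deposited duplexes requires the
  PDB entries as local files; the package does not download them.
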