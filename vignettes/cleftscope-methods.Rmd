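---
title: "cleftscope: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cleftscope: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cleftscope is the analysis layer of a protein–ligand molecular-dynamics
study, rebuilt as a self-contained, testable package. The motivating system
is the green-tea catechin EGCg in the hydrophobic cleft of the C-terminal
domain of cardiac troponin C (cCTnC), a calcium-binding protein with two
high-affinity EF-hand sites; nothing in the code is specific to that
system beyond the residue templates and the shape of the synthetic ligand.
Units are fixed project-wide: Å for lengths, ps for times, kcal/mol for
energies, degrees for angles, and k_B = 0.0019872 kcal mol⁻¹ K⁻¹.

## Interaction fingerprints

A hydrogen bond is a (donor heavy atom, hydrogen, acceptor) triple with
donor–acceptor distance strictly below 3.5 Å — relaxed to 4.0 Å when the
acceptor carries the sulphur class tag (methionine SD; cysteine SG gets the
same tag) — and a donor–H–acceptor angle strictly above 120°. Two
conventions needed fixing:

* **Angle vertex.** The angle is measured at the hydrogen, so 180° is a
  linear bond. The "donor–H–acceptor" ordering makes this the natural
  reading; placing the vertex at the donor would make the default
  threshold geometrically meaningless.
* **Strict inequalities.** Cutoffs are exclusive ("smaller than" /
  "larger than"), so boundary fixtures (a pair at exactly 3.5 Å) are
  unambiguous: not a bond.

Each hydrogen on a donor is tested independently and each satisfying
(H, acceptor) combination is one event; per-frame means are therefore event
counts, which is the convention that makes "average number of hydrogen
bonds" additive across partner classes. Donor and acceptor in the same
residue are excluded unless intramolecular mode is on. There is no
periodic-boundary minimum image: all fixtures are non-periodic.

π–π contacts pair aromatic rings from different residues when the centroid
distance is below 5 Å and the angle between the ring normals, folded to
[0°, 90°], is below 45°. Normals are least-squares plane fits (SVD of the
centred ring coordinates), so slightly puckered rings are handled and the
result is independent of vertex order and normal orientation.

**Salt bridges** are a definitional choice rather than a measurement: the
package keeps hydrogen bonds whose donor-side and acceptor-side residues
carry opposite charge classes, restricted to side-chain atoms. The
percentage of salt bridges among hydrogen bonds is reported **truncated**
to an integer, because that is the only single rounding rule consistent
with the reference bookkeeping this package reproduces (8.8 of 11.2 bonds
prints as 78%, where round-half-up would give 79%). One historical row of
that bookkeeping (8.6 of 12.5 printing as 69%) is inconsistent with
truncation — those percentages were evidently computed from unrounded
means — and is documented here rather than fitted.

## NOE-style effective distances

NOE cross-peak intensity decays as r⁻⁶, so the default effective distance
over an equivalence group pair is the power mean ⟨r⁻⁶⟩^(−1/6), pooling all
frames and all equivalent-pair combinations into a single number per entry
(one point per plot symbol, not a per-frame minimum). A plain arithmetic
mean is retained as an option and the mode is recorded in output metadata.
By the power-mean inequality the r⁻⁶ value never exceeds the arithmetic
one; this is a tested invariant. Distances above the 6 Å detection cutoff
are flagged undetected.

Class bins are lower-edge inclusive: medium up to 3.3 Å, weak [3.3, 5.0),
very weak [5.0, 6.0] with 6.0 Å itself still very weak (the cutoff is "at
6 Å"). Distances below the conventional 2.7 Å lower edge of "medium" are
classed medium — an NOE at least that strong — so that classification is
total over positive distances, another tested invariant. The experimental
comparison operates on classes, not on reconstructed intensities, because
class boundaries are what an experimental table actually pins down.

## Trajectory geometry

Superposition is the Kabsch least-squares fit with the standard
determinant-sign correction, so reflections are never returned even for
degenerate inputs; collinear selections raise an error. RMSF is measured
about the window-average structure computed by iterative superposition
(2 passes, convergence threshold 1e-4 Å); with isotropic per-axis jitter σ
the expected per-atom RMSF is σ√3 reduced by the ~√(1−2/N) factor that
rigid-body fitting removes — the tests use N = 100 atoms so this correction
stays inside the 2% acceptance band. Ion mobility uses the first frame of
the analysis window as the displacement reference (the "end of
equilibration" convention), configurable; the joint site-I/site-II
histogram carries an explicit overflow bin so its mass sums to exactly 1.

Dihedrals are signed torsions in (−180°, 180°] via the atan2 form, 0° cis
and 180° trans. Two symmetry facts are worth recording because they are
easy to misstate: the standard torsion is **invariant** under reversing the
four-atom order, and **negates** under mirror reflection; both are tested.
Collinear triples yield a flagged NA for that frame rather than an error.
Mode populations come from the circularly smoothed histogram (5° bins,
3-bin moving average) — smoothing suppresses single-bin noise peaks — with
each mode's population being the probability mass of its uphill basin.

## Well-tempered metadynamics

The engine does overdamped Euler–Maruyama Langevin dynamics at temperature
T on an analytic toy potential plus bias plus wall:
x ← x − (D/k_BT) ∇(U+V+W) dt + √(2 D dt) ξ. It is compiled (Rcpp) because
10⁶ sequential steps are not feasible in interpreted R within a test
budget; this is the one place the package uses native code. Defaults
dt = 0.02 ps and D = 0.05 Å²/ps keep the drift per step far below the well
width of the default landscapes.

Hills of width σ = 0.2 Å are deposited every 1 ps with initial height
w₀ = 0.1 kcal/mol and the well-tempered damping
w = w₀ exp(−V(s)/k_BΔT), ΔT = (γ−1)T, γ = 10; at γ → ∞ the height stays w₀
(standard metadynamics). The bias and its **analytic** gradient are
accumulated on a dense grid (spacing σ/5) as each hill is deposited and
linearly interpolated at the particle position — the gradient stored on the
grid is the exact Gaussian-sum derivative, never a finite difference.
Biased runs support 1- and 2-dimensional CV spaces; a dense 3-D bias grid
at this resolution is beyond desk scale, and 3-D surfaces enter only
through reconstruction and projection. The wall is a one-sided harmonic,
κ(s−limit)² with κ = 100 kcal/mol at 12 Å, zero at the limit itself; the
harmonic form and its application per CV are package choices recorded in
output metadata, not claims about any reference setup.

The free energy is recovered by the direct scaling F(s) = −γ/(γ−1)·V(s),
gauge-fixed so the grid minimum is exactly 0; time-averaged estimators are
out of scope. Because the instantaneous estimate oscillates, profiles are
averaged: 100 reconstructions at hill counts evenly spaced over the final
half of the deposition history, re-zeroed after averaging. On the
3 kcal/mol double well at the default parameters this lands within a few
percent of the analytic barrier (the acceptance band is 15%).

The Boltzmann check of the unbiased sampler deserves a note: a χ² test
assumes independent draws, so samples are taken every 20 ps — far beyond
the slowest relaxation (well hopping, ~6 ps by Kramers' estimate for the
1 kcal/mol double well with D = 0.2 Å²/ps used in that test). At a
3 kcal/mol barrier the hopping time is two orders of magnitude longer and
10⁶ steps would not give enough independent crossings for an honest test,
which is why the distributional check uses the lower barrier while the
reconstruction check keeps the 3 kcal/mol one.

Projection onto two CVs is the Boltzmann marginal
F₂(a,b) = −k_BT ln Σ_c exp(−F₃/k_BT) Δc, computed with a log-sum-exp guard
so the result is finite whenever any slice value is; a separable surface
F₃ = f(a,b) + g(c) projects to f − min f exactly (tested to 1e-10).

## MM/PBSA bookkeeping

The entropy column is stored as the penalty −TΔS (positive for binding) so
that the combination is a plain sum, ΔG = ΔH + (−TΔS). Uncertainties are
combined in quadrature, which treats the enthalpy and entropy estimates as
independent; that assumption is exactly what reproduces the printed
uncertainties of the reference tables, and it is recorded here as an
assumption, not a theorem. Rounding to one decimal (half away from zero)
happens only in the presentation layer. The bundled table
`inst/extdata/mmpbsa_components.tsv` carries printed component columns from
an EGCg/cCTnC binding study; the package recomputes ΔG, its sd and ΔΔG
from them at run time. Three kinds of internal inconsistency in such
printed tables are worth knowing about, all attributable to rounding of
unprinted precision, and none reverse-engineered: one row whose printed sd
(5.1) differs by 0.1 from the quadrature of its printed components
(5.17 → 5.2), a few rows whose printed ΔG differs by 0.1 from the sum of
the printed components, and ΔΔG columns computed from the unrounded ΔG.
The package's ΔΔG check therefore runs on the printed ΔG column, which is
internally consistent.

Snapshot selection takes frames at multiples of the 10 ps cadence inside a
half-open window (start, end] — so "the final 45 ns" of a 50 ns run at
10 ps yields exactly 4500 enthalpy snapshots — and 20 evenly spaced members
of that set (first and last included) for normal-mode entropies.

## The synthetic-data module

Everything the pipeline consumes is generated: a deterministic toy complex
(a seven-residue scaffold with the side chains that matter — a methionine
sulphur acceptor and methyl CV group, leucine/valine methyls, a
phenylalanine ring, a lysine/glutamate salt-bridge pair — plus a three-ring
catechin-like ligand with labelled aromatic protons H12/H13, H16/H17,
H9/H10, three named dihedrals, two calcium sites and up to 30 waters), and
trajectories with *planted* interactions: "on" frames place the
donor–H–acceptor triple collinear at 2.9 Å, "off" frames stretch it to
4.5 Å along the same axis; π–π plants place parallel rings 3.5 Å apart and
break them at 6.5 Å with a 60° tilt. Episodes are contiguous, with the
off-frames spread evenly between them, so lifetime fractions are
recoverable alongside occupancies. Geometries are constructed analytically,
not energy-minimised: the module exists to test detectors, not physics.

Occupancy schedules realise ⌈occupancy × n_frames⌉ on-frames exactly (with
an epsilon in the ceiling so that exactly representable targets like
0.8 × 400 do not round up). The partner-split generator, which reproduces
printed per-class bond totals, chooses each planted pair's approach
direction by *probing the detector itself*: since any spurious contact
involves the atoms of at most two planted pairs, checking the four on/off
state combinations of each new pair against the already-placed set is an
exhaustive guarantee that the detector sees exactly the planted set in
every frame. The detector being probed is itself validated independently
against a brute-force oracle, so the loop is not circular.

What a green closed-loop test establishes: that the detector, the
summariser and the schedule machinery are mutually consistent and exact on
geometries that are unambiguous by construction. What it does not
establish: behaviour on real MD geometry — thermal bond-length
distributions, borderline angles, periodic images, competing bifurcated
bonds — none of which the generator emulates. The oracle-equivalence tests
on random frames cover the borderline-geometry half of that gap; the rest
is out of scope by design.

Ion sites follow anchor + drift·t + N(0, σ²I₃) per frame; a non-zero drift
emulates a site relocating over a run. The jitter model for all other
atoms is iid isotropic Gaussian noise — no covariance, no slow modes — so
RMSD/RMSF tests against closed forms are exact up to sampling error, and
nothing more should be read into them.

## Degenerate inputs and error policy

Unknown residue names are hard errors listing the residue (silent skips
would corrupt interaction counts). Zero-atom files, ragged multi-model
PDBs, truncated XYZ frames, HILLS header/row arity mismatches and
non-numeric fields are parse errors naming the location. Zero hydrogen
bonds makes the salt-bridge percentage undefined and flagged, never zero.
Collinear superposition selections and empty analysis windows are errors;
collinear dihedral frames are flagged NAs. Engine divergence (non-finite
or runaway coordinates) aborts with the step and coordinate in the
message rather than returning garbage.

## Known limitations

* No minimum-image convention; the box field of a frame is carried but
  unused by the detectors.
* The metadynamics engine integrates the CVs directly (the toy potential's
  coordinates *are* the CV space); it does not simulate atoms, and biased
  runs are limited to 2 CVs.
* mmCIF and binary trajectory formats (DCD/XTC) are not read; multi-model
  PDB and XYZ are the interchange formats.
* The NOE comparison does not model spin diffusion or relaxation; it is a
  distance-class bookkeeping tool.
* MM/PBSA components are consumed, never computed: no Poisson–Boltzmann
  solver, surface-area term or normal-mode analysis is included.
* 1-based atom indexing throughout, as idiomatic in R; file serial numbers
  are preserved as labels only.
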