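---
title: "Validating NMR-restraint-guided models of helical complexes"
author: "helixcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating NMR-restraint-guided models of helical complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcheck)
```

## The problem this package addresses

Small α-helical peptide complexes in fast association/dissociation
exchange often defy classical NOE-based structure determination: line
broadening and resonance overlap leave too few distance restraints. A
widely used alternative is to (i) predict backbone torsions and
per-residue rigidity from chemical shifts, (ii) restrain molecular
dynamics / simulated annealing to those torsions, and (iii) validate the
resulting model against every independent observable: ensemble precision,
dihedral agreement, chemical-shift-perturbation maps, titration
attenuation and residual dipolar couplings. `helixcheck` implements steps
(i) and (iii) — the restraint preparation and the entire validation
tool-chain — together with synthetic-data generators that exercise every
stage. Running the simulations themselves (force fields, thermostats,
annealing schedules) is deliberately out of scope: the package consumes
their output as multi-model PDB ensembles and trajectories.

## Data model

Coordinates live in a `Structure`: an atom table (chain, residue number
and name, atom name, element) plus an `natoms × 3 × nmodels` array in Å.
One class serves three roles — single structure, ensemble (models =
replicas) and trajectory (models = frames) — because every metric in the
package is defined on superposed coordinate sets and never needs more.
All models share one topology; that invariant is enforced at
construction and at PDB parse time. Atom subsets are expressed as
`AtomSelection` objects (`chain : residue-range : atom-names`, default
backbone N, CA, C) which resolve deterministically in file order.

PDB reading and writing delegate to `bio3d` behind this interface, with
a pre-scan that reports malformed `ATOM` records by line number and
rejects models with inconsistent atom counts. Only `ATOM` records are
read; alternate locations other than blank/`A` are dropped; residue
numbering is taken as given. Tables (torsion predictions, peaks, RDCs)
are plain data.frames read from comma- or whitespace-delimited text with
a header, since such tables typically originate as spreadsheet exports.

## Restraint preparation

`classifyRigidResidues()` applies the standard rigidity cut on the
chemical-shift order parameter, RCI-S² ≥ 0.7 (inclusive; the threshold is
an argument). `dihedralRestraints()` then emits one φ and one ψ
flat-bottom restraint per rigid residue with the predicted angles as
targets and rk2 = rk3 = 32.0 kcal·mol⁻¹·rad⁻¹ on both walls — the
constants conventionally used when restraining backbone torsions in
AMBER-style refinements. Three classes of residues produce fewer than two
restraints: residues explicitly excluded by the caller (e.g. an
ambiguous inter-helix loop residue that should stay unrestrained),
residues whose prediction class is `None`, and the terminally undefined
angles (φ of the first tabulated residue, ψ of the last).

The flat-bottom half-width is **not** part of the published constants, so
it is a package decision: the predicted angle uncertainty (DPHI/DPSI)
with a floor of 10°. A narrower bottom would over-commit to prediction
noise; 10° is roughly the empirical accuracy of chemical-shift torsion
prediction in helices. Both the generic rendering and an AMBER `&rst`
namelist rendering are provided; they differ only in formatting.

## Superposition and RMSD metrics

All comparisons use the Kabsch algorithm (SVD of the cross-covariance,
with the determinant correction that forbids reflections). Conventions
that matter:

- **Fit vs calc selections.** The transform is estimated on a *fit*
  selection and the reported RMSD may be evaluated on a different *calc*
  selection — e.g. matching a complex over both chains but reporting the
  RMSD of one subunit, which is how subunit mobility relative to a
  scaffold is quantified.
- **Pairwise ensemble RMSD** reports mean, SD and SEM over the
  n(n−1)/2 unordered pairs, with SEM = SD/√(n_pairs). The pairs sharing
  a model are correlated, so this SEM understates sampling error for
  small ensembles; it is nevertheless the convention used when quoting
  ensemble precision, and it is what the package reproduces.
- **Rolling RMSD** compares frame t with frame t − lag after
  superposition; the lag is given in frames, and a time lag (e.g. 1 ns)
  is converted by the caller through the trajectory's frame spacing.
  Rigid-body motion cancels exactly (tested); conformational drift does
  not.
- **Dihedral RMSD to targets** pools φ and ψ deviations equally and wraps
  every difference to (−180°, 180°], so a 179°/−179° pair contributes 2°.
  Equal pooling is a choice — no weighting convention is standard — and
  is documented here so ratios between candidate topologies are
  reproducible.

`annealingConvergence()` composes these: it drops dissociated replicas
(fewer than 10 inter-chain heavy-atom contacts under 5 Å in the final
structure — the count is explicit and configurable because "lost most
contacts" is otherwise not reproducible), averages each ensemble
(plain coordinate means, deliberately not re-idealised), superposes the
two averages, and reports between-average global/subunit RMSDs plus
pooled pairwise statistics across all retained replicas.

## Interface mapping

Compound CSP uses Δδ = [(Δδ_H)² + (Δδ_N/6.5)²]^1/2; 6.5 is the
conventional ¹⁵N scale (configurable). Differences are absolute, so the
result is symmetric in which spectrum is labelled free. Titration
attenuation is I/I₀ with I₀ from the designated reference condition,
reported as exactly 1 for the reference itself; residues with I₀ = 0 or
flagged overlapped/missing are `undetermined` and never enter any
statistic. Peak matching across conditions is by residue number only —
overlapped pairs must be flagged in the input, as they are in practice
when two amides coincide in the spectrum.

Quartile classification uses type-7 quantiles (linear interpolation
between order statistics) with ties at a boundary going to the *lower*
class, and an orientation flag so that q4 always means "strongest
effect" whether the score increases (CSP) or decreases (attenuation)
with effect size. Both conventions are decisions: published figures
rarely state their quartile method, so classifications near boundaries
may differ from any particular published colouring by one class. The
classification is rank-based and therefore invariant under monotone
transforms of the scores (property-tested).

## RDC validation

With amide N–H unit vectors v̂ᵢ, couplings are linear in the five
independent elements of the symmetric traceless Saupe matrix:
D_i = D_max·v̂ᵢᵀ·S·v̂ᵢ. `fitAlignmentTensor()` solves the 5-parameter
least-squares problem by QR; with five independent vectors the fit
interpolates, and the design matrix rank is checked so degenerate vector
sets fail loudly. D_max defaults to 1 — the fit is scale-invariant, so
the tensor is reported in product form carrying the Hz scale.

Q is reported as rms(D_calc − D_obs)/rms(D_obs) (the normalisation used
by common RDC-validation tools); the alternative normalisation by the
tensor magnitude, √(2·Da²·(4 + 3R²)/5), is available as `qForm = "da"`.
Amide protons absent from backbone-only models are constructed
geometrically (1.02 Å from N along the in-plane bisector opposite the
C′(i−1)–N and CA–N bonds); this idealisation perturbs Q by a few
hundredths at most, which is why validation targets quoted against
built protons deserve a correspondingly widened tolerance.

Dipolar waves: along a regular helix sequential RDCs oscillate with the
~3.6-residue period. With the period *fixed*, the model
D(n) = A_v + A_II·cos(2πn/period + φ) is linear in its cosine/sine
expansion, so it is fitted exactly by least squares — no nonlinear
optimisation, no convergence failures. A_II and its uncertainty come
from the coefficient covariance by the delta method. The optional second
harmonic is off by default. A_v, the mean coupling level of the helix,
is the robust parameter; A_II from a single-harmonic fit can differ from
treatments that model helix geometry explicitly.

## Helix geometry

The helix axis is the dominant principal component of CA positions after
a 4-point sliding-window average; the smoothing removes the helical
wobble that would otherwise tilt the principal axis of a short helix.
Published crossing angles are often measured with interactive tools
whose axis algorithm is unspecified, so agreement within ±3° is the
realistic comparison tolerance. The crossing angle is taken between
direction vectors *without* absolute value — antiparallel helices give
180° — and directions are oriented N→C. Helix/coil assignment from
dihedrals uses the window φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] with a
minimum run of 4 — a reproducible stand-in for by-eye assignments.
Contour lengths use L = 4 Å·n_coil + 1.5 Å·n_helix (maximum extension
per coil residue vs axial rise per helical residue).

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its seed. They emulate the
*statistical structure* the analyses assume:

- `buildIdealHelix()` / `buildBundle()`: exact-geometry backbones
  (standard bond lengths/angles, ω = 180°) at fixed torsions and bundles
  at controlled crossing angles — the ground truth for the geometry
  tests.
- `perturbEnsemble()` / `synthTrajectory()`: isotropic Gaussian
  coordinate noise, plus an optional per-atom random-walk drift for
  trajectories.
- `synthRdc()`: back-calculated couplings from a known tensor plus
  Gaussian noise.
- `synthTitration()`: two-state fast exchange. The bound fraction comes
  from the exact (numerically stable) solution of the 1:1 binding
  quadratic; observed shifts are the population average; intensities
  decay as exp(−k·f_bound·Δδ_bound), a deliberately simple proxy that
  concentrates attenuation on the interface, which is all the quartile
  pipeline needs. Defaults: 0.3 mM protein, molar ratios 40:1…7:1, and
  K_d = 50 µM — a typical weak peptide–peptide affinity that yields
  partial saturation across that schedule.

They do **not** emulate force-field physics (correlated backbone
fluctuations, anisotropic motions), realistic exchange-regime lineshapes,
spectral noise/peak-picking errors, or alignment-medium physics.
Passing tests therefore demonstrate the *correctness of the computations
and conventions*, not the accuracy of any particular force field or
experimental set-up.

## Numerical choices and degenerate inputs

- Torsions follow the IUPAC sign convention (trans = 180°), checked
  against two independent implementations; all angle outputs are wrapped
  to [−180°, 180°), all circular differences to (−180°, 180°].
- Kabsch fits require ≥3 atoms and warn on (near-)collinear fit sets;
  proper rotations are enforced via the determinant sign correction.
- Quartile classification requires ≥4 scored residues; all-equal scores
  collapse into q1 by the ties-low rule.
- The tensor fit requires ≥5 usable vectors and a full-rank design;
  exactly 5 vectors interpolate (residuals 0) regardless of noise.
- The binding quadratic is evaluated as 2PL/(s + √(s² − 4PL)) to avoid
  catastrophic cancellation at large ligand excess.

## Test design and problem sizes

The suite builds all fixtures in code at run time. Oracles are
independent of the implementation they check: bio3d for torsions and
optimal-fit RMSD, an independently coded type-7 quantile, a bisection
equilibrium solver, closed forms where they exist (e.g. the residual
expectation of a 5-parameter linear fit, E[rmsd²] = σ²(n − 5)/n, checked
over 500 seeds). Stochastic assertions use fixed seeds and 3–4 standard
error bands computed from the simulations themselves. Problem sizes —
helices of 10–25 residues, ensembles of 4–50 models, trajectories of
5–60 frames, 120–500 replicate simulations — were chosen so each
statistical check has the power it needs while the whole suite stays
interactive (tens of seconds).

## Known limitations

- The ensemble SEM convention (SD over pairs / √n_pairs) ignores pair
  correlation, as noted above.
- Helix-axis angles on helices shorter than ~6 residues are sensitive to
  the smoothing window; the ±3° comparison tolerance reflects this.
- The single-harmonic dipolar wave is a descriptive fit; it does not
  model helix tilt/rotation explicitly.
- The attenuation generator is a qualitative exchange-broadening proxy;
  quantitative relaxation analysis is out of scope.
- Peak matching is by residue index; no ppm-space peak tracking is
  attempted.
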