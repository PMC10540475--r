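---
title: "Methods: quantum-descriptor QSAR for basic pKa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum-descriptor QSAR for basic pKa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkaqsar)
```

## The model and its assumptions

`pkaqsar` predicts the basic pKa of a nitrogen compound from six
descriptors of the acid–base pair, combined linearly:

pKa = 0.1074 ΔE − 0.1422 ΔHL_Gap − 0.9132 χ_M + 0.0151 %NPSA
− 1.4887 ΔALIE_N + 3.0608 BaseT − 30.7139

The underlying assumptions are worth stating explicitly:

* **Fixed charge convention.** The base carries net charge 0 and the
  conjugate acid +1; ionic bases must be neutralized with a counterion
  before descriptor computation. `validate_pair()` enforces this, because
  ΔE is meaningless across inconsistent charge states.
* **Closed-shell species.** Occupations are restricted to
  [0, 0.5] ∪ [1.5, 2]; the HOMO is the highest orbital with occupation
  > 0.5 and the LUMO the lowest with occupation ≤ 0.5. Genuinely
  fractional occupations are rejected rather than silently averaged.
* **Vertical electronic response.** χ_M = (VIP + VEA)/2 uses single-point
  energies of the N−1 and N+1 electron states at the *base's* fixed
  geometry. When full records with geometries are supplied,
  `charged_state_triple()` verifies coordinate agreement to 1e−8 bohr;
  adiabatic IP/EA and Koopmans approximations are deliberately out of
  scope.
* **Signs as defined.** Descriptors keep their natural signs (ΔE > 0 for
  bases that are costly to deprotonate, χ_M enters with a negative
  coefficient); nothing is re-signed internally.

All internal quantities are hartree/bohr; conversions
(1 hartree = 627.509474 kcal/mol = 27.211386245988 eV,
1 Å = 1.8897259886 bohr) are applied once, at descriptor assembly, from
the single table `pka_units`.

## Inputs

Running DFT is upstream of this package. Species results enter through a
documented plain-text key/value properties format (`read_properties()`),
chosen over binary wavefunction files so that records are human-writable
and diff-friendly; a best-effort parser for common quantum-output text
(`read_qc_output()`) eases transcription but the canonical format is the
contract. Volumetric fields (density, ESP, per-orbital densities) enter as
Gaussian cube files, including the orbital-cube negative-atom-count
dialect and the negative-voxel-count angstrom dialect. Where a workflow
would export orbital information from binary checkpoint files, we
standardize on cubes plus a small orbital manifest
(`read_orbital_manifest()`): cube is the one volumetric format every
quantum-chemistry tool writes.

## The molecular surface and %NPSA

The molecular surface is the ρ = 0.001 au isodensity contour, extracted
by marching tetrahedra: each grid cell is split into the six tetrahedra
sharing its main diagonal (a Kuhn decomposition — deterministic and
orientation-consistent), and each tetrahedron contributes 0, 1 or 2
triangles depending on which of its corners lie inside the contour. Grid
values exactly at the isovalue count as inside (a 1e−12 shift is
subtracted before comparison), which resolves ties deterministically.
Degenerate triangles (area ≤ 1e−12 bohr²) are dropped.

**Vertex placement.** Edge crossings are located by inverse interpolation
of the density along the tetrahedron edge. For strictly positive endpoint
values the interpolation is performed in log-density; otherwise linearly.
The reason is quantitative: electron densities decay exponentially, and a
linear chord through an exponential tail systematically overshoots the
contour, biasing the surface outward. On the analytic Gaussian-sphere
fixture at the protocol's 0.25 bohr grid spacing, linear placement leaves
a ~5% area error while log-density placement reduces it to ~0.4%, with
monotone convergence under refinement (0.5 → 0.25 → 0.125 bohr gives
errors of roughly 1.5%, 0.38%, 0.09%). Log placement is exact on
exponential tails and agrees with linear placement to first order
elsewhere, so nothing is lost for slowly varying fields.

**%NPSA.** The electrostatic potential is mapped onto surface vertices by
trilinear interpolation (exact for fields affine in the grid coordinates).
A triangle is nonpolar when the mean |ESP| over its three vertices is
below the polarity threshold; %NPSA is the nonpolar fraction of total
area. Surface-analysis programs differ in their polar/nonpolar
conventions and the convention behind the reference values is not
published, so the threshold is an explicit, documented parameter:
**10 kcal/mol** by default, exposed as `polarity_threshold` (and
`--polarity-threshold` on the command line). If reference descriptor
values for real molecules became available, this default is the first
thing to calibrate. Grid construction in the fixtures mirrors the stated
surface protocol — 0.25 bohr spacing, boxes padded well beyond the
contour (the protocol's 1.7 × van der Waals extension plays that role for
real molecules).

If the density still exceeds the isovalue on the grid boundary the
surface cannot close; the extraction warns, flags the surface as open,
and its area must be read as a lower bound.

## Average local ionization energy

The ALIE field is the density-weighted mean of |orbital energies|,

I(r) = Σᵢ nᵢ ρᵢ(r) |εᵢ| / Σᵢ nᵢ ρᵢ(r),

computed voxel-wise from congruent per-orbital density grids. Two
documented choices:

* **Occupation weighting.** The textbook expression omits occupations; we
  weight each ρᵢ by nᵢ so doubly occupied orbitals count correctly. With
  all-equal occupations the weights cancel and the plain form is
  recovered verbatim.
* **Atomic condensation.** "ALIE on the nitrogen" requires an atomic
  partition of space, and the partition behind the reference values is
  unstated (Hirshfeld and fuzzy-Becke schemes are common). We default to
  the nearest-nucleus (Voronoi) partition — deterministic and
  parameter-free: every voxel with total density ≥ 1e−12 au is assigned
  to its nearest nucleus and ALIE_N is the total-density-weighted mean of
  the field over the nitrogen's voxels. The alternative of evaluating the
  field at the nuclear position is available as `mode = "nucleus"`
  (`--alie-mode nucleus`). For single-orbital densities the field is
  constant wherever defined, so every partition agrees — a property the
  tests exploit. Numerical agreement with values produced under a fuzzy
  partition cannot be guaranteed; this is a known limitation.

Voxels below the 1e−12 au density floor are undefined (NA) rather than
zero, so empty space never dilutes an atomic average. ΔALIE_N is the base
value minus the conjugate-acid value, in eV.

## Regression engine and validation statistics

Fitting is ordinary least squares via QR (`qsar_fit()`, a formula/data
interface returning a classed object with `print`, `summary`, `coef`,
`predict`, `residuals` and `plot` methods). The statistic conventions are
stated because sources often leave them implicit:

* R² = 1 − SSE/SST;
* s = √(SSE/(n − k − 1)) (standard error of estimate);
* F = (R²/k) / ((1 − R²)/(n − k − 1));
* RMSE = √(SSE/n), MAE = mean |residual|;
* Q²loo = 1 − PRESS/SST with PRESS from the exact hat-matrix identity
  e₍ᵢ₎ = eᵢ/(1 − hᵢᵢ), which the tests verify equals naive n-refit
  cross-validation to 1e−10;
* stability = R² − Q²loo. The reference work reports a stability value
  without a formula; this difference is the natural reading and is
  documented as an assumption.

With n = 130, k = 6 and R² = 0.9905 these conventions imply F ≈ 2137,
and the rounding band of R² (±0.00005) brackets the reported
F = 2141.9289 — supporting the convention choice, which is as sharp a
check as the printed precision allows. The training descriptor matrix
itself requires DFT on 130 structures and is not reproducible at the
desk; the engine is therefore validated on synthetic data (exact recovery
at zero noise; coefficient recovery within 3 standard errors in ≥ 95% of
200 replicates at the training scale n = 130, σ = 0.3).

Designs are screened for collinearity (`correlation_screen()`, default
cap |r| = 0.7744, the largest inter-descriptor correlation tolerated in
the training pool); rank-deficient fits fail loudly naming the collinear
columns. Descriptor selection (`select_descriptors()`) enumerates all
subsets up to `max_k` (pool capped at 20 columns) and ranks by Q²loo,
ties broken by smaller subset then larger F — a transparent stand-in for
iterative add/remove selection that is exhaustive, hence strictly
stronger, at these pool sizes. Genetic-algorithm search and
applicability-domain (leverage/Williams) analyses are out of scope.

## External validation data

The two reference tables ship as versioned CSVs under `inst/extdata/`
(40 free compounds, ids 131–170; 6 CB7 complexes, ids C1–C6) with
provenance headers. Metrics are recomputed from the per-row cells, never
copied. Three data notes, surfaced rather than silently corrected:

1. The free-compound table's footer prints a reference-predictor MAE of
   0.60, inconsistent with its own per-row errors, which average 0.79 (the
   value also stated in the running text); recomputation here yields 0.79.
2. The C2 experimental shift (3.96) implies a free pKa of 4.64 where the
   free table lists 4.60 for the same compound.
3. Printed predicted shifts reflect unrounded internal predictions: the
   cross-table difference of rounded predictions can differ by up to 0.04
   (e.g. C1: 9.36 − 5.26 = 4.10 vs the printed 4.06).

In each case the printed column is treated as authoritative. Predictions
and errors are reported at 2 decimals to match the tables; full precision
is kept internally.

## Synthetic fixtures: what they do and do not show

Every test input is generated in code, deterministically in (parameters,
seed):

* **Gaussian sphere** ρ(r) = A·exp(−αr²): closed-form isosurface radius
  √(ln(A/c)/α) and area, attached to the fixture as metadata so tests
  never hardcode derived numbers.
* **Hemisphere-ESP sphere**: a logistic ESP profile crossing the polarity
  threshold exactly at the equator, making the analytic %NPSA 50.
* **Disjoint orbitals**: two well-separated single-orbital atoms, for
  which atomic ALIE equals |ε| of the local orbital under any partition.
* **Linear descriptor datasets**: descriptors drawn from documented
  ranges matching the real magnitudes (ΔE ~ U(280, 380) kcal/mol, gaps
  and χ_M of a few eV, %NPSA ∈ [40, 95], BaseT ~ Bernoulli(0.5)), so that
  with the published coefficients the noiseless response lands in the
  0–12 pKa range of the validation tables; default n = 130 and noise
  σ = 0.3 mirror the training regime.

These fixtures exercise the numerics — interpolation, triangulation,
condensation, least squares — under controlled truth. They do **not**
emulate real molecular electron densities (no shell structure, no ESP
sign changes around heteroatoms, no conformational variety), so passing
tests certify the algorithms, not the chemistry of any particular
compound. The real-molecule accuracy claim rests on the packaged external
validation tables.

## Numerical choices and degenerate inputs

* Isovalue ties: values equal to the contour are inside (1e−12 shift).
* Degenerate triangles ≤ 1e−12 bohr² are dropped; total area is the sum
  of retained triangle areas by construction.
* Density floor 1e−12 au for "voxel carries density" everywhere (ALIE
  definedness, Voronoi assignment).
* Coincident surface vertices are merged on a 1e−9 bohr rounding key, so
  shared edges reference shared vertices.
* Orbital grids must agree in origin/axes/shape to 1e−10 before ALIE.
* Fits require n > k + 1 and full column rank; violations are errors, not
  warnings.
* Cube and properties files round-trip at full double precision (17
  significant digits).

Problem sizes in the default test run are chosen to keep the full suite
around ten seconds: sphere fixtures use 14-bohr boxes at 0.25–0.5 bohr
spacing in unit tests and the full 24-bohr protocol box (0.125–0.5 bohr)
in the end-to-end checks; ALIE oracle grids stay at or below 15³; Monte
Carlo uses 100–200 replicates.

## Known limitations

* The polar/nonpolar ESP threshold and the atomic partition are
  documented stand-ins for unpublished conventions; both are exposed as
  parameters rather than baked in.
* Surface-restricted ALIE extrema, solvent-accessible surfaces, and
  host–guest descriptor computation (DFT on the complexes) are out of
  scope.
* The published coefficients are frozen; refitting real data requires the
  user to supply their own descriptor table.
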