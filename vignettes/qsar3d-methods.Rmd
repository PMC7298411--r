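---
title: "Field-based 3D-QSAR and reactivity descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR and reactivity descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

## The modelling problem

A congeneric series of ligands — here thienopyridine inhibitors of the
IKKβ kinase, varied at two ring positions — spans a range of inhibitory
potencies (IC50). Field-based 3D-QSAR asks which *regions of space
around the aligned series* explain that variation: it converts each
molecule into a long vector of probe interaction energies on a shared
grid and regresses activity on those vectors. Because grid columns are
many and extremely collinear, the regression is partial least squares
(PLS), and the honest figure of merit is the leave-one-out
cross-validated coefficient q², not the training r².

The analysis assumes: (i) a single bioactive-like conformation per
compound, rigidly placed in a common frame; (ii) activity differences
dominated by steric/electrostatic (CoMFA) or similarity-index (CoMSIA)
field differences; (iii) a response on a log scale,
`pIC50 = -log10(IC50 [mol/L])`, which makes free-energy-like
differences approximately additive.

## Alignment

The reference frame is a template conformation (by default the most
active compound). Every other molecule is matched to the template over
their maximum common substructure (MCS) of heavy atoms — computed as a
maximum clique in the modular product of the element-labelled bond
graphs — and rigidly superposed over the matched atoms by least squares
(Kabsch, SVD with the determinant correction so the rotation is proper).
Ties among equal-size MCS mappings go to the mapping with the smallest
post-superposition RMSD, then to atom-index order, so the result is
deterministic. Molecules sharing fewer than 3 heavy atoms with the
template are rejected per molecule rather than failing the series.
A Gaussian-volume overlap score (atom-centred Gaussians, width tied to
the van-der-Waals radius) is reported as an alignment quality measure
but is not optimised.

This is a deliberate simplification of flexible feature-overlap
alignment: conformational search and internal-strain scoring are out of
scope. It is exact in the regime the package targets — series sharing a
rigid scaffold conformation — and approximate otherwise. One practical
consequence: a purely topological MCS can map a substituent at one site
onto the same substituent at another site, which is geometrically wrong
for a series that is *already* in a common frame. The pipeline therefore
skips re-alignment for synthetic input, whose generator guarantees the
frame by construction.

## Fields and their parameters

The grid is the union bounding box of all aligned atoms plus a margin,
discretised at a fixed spacing (points per axis:
`ceiling(extent/spacing) + 1`).

| parameter | default | units | notes |
|---|---|---|---|
| grid spacing | 0.6 | Å | the modelled protocol's value; unusually fine versus the conventional 2.0 Å, so desk-scale runs and the test suite use 2.0 via the config knob |
| margin | 4.0 | Å | conventional |
| steric cutoff | ±30 | kcal/mol | conventional truncation; a grid point inside an atom gets the cutoff, not infinity |
| probe | sp³ C, +1 e | — | conventional CoMFA probe; ε = 0.107 kcal/mol, r = 1.70 Å |
| Coulomb constant | 332.0 | kcal·Å/(mol·e²) | with distance-dependent dielectric D(r) = r |
| CoMSIA attenuation α | 0.3 | Å⁻² | conventional CoMSIA default |
| min-sigma (CoMFA) | 2.00 | kcal/mol | column filter, boundary inclusive |
| min-sigma (CoMSIA) | 0.02 | index units | see below |

The bare Coulomb field is reported untruncated (332 kcal/mol for unit
charges at 1 Å is the contract); during CoMFA assembly it is truncated
at ±30 and, at grid points where a compound's steric field hit the
cutoff (i.e. inside the molecular envelope), that compound's
electrostatic value is replaced by the column mean over the
non-truncated compounds — the standard CoMFA convention, which prevents
meaningless in-core electrostatics from dominating the regression.

Lennard-Jones parameters are a bundled Tripos-like per-element table
(well depth ε, vdW radius) with Lorentz–Berthelot-style combining
(radii add, well depths combine geometrically). Hydrophobic atom
weights are a crude atomic logP-contribution table; donor/acceptor
weights are 0/1 flags (N/O acceptors; N/O bearing H donors). All tables
are deliberately simple, replaceable data, not chemistry claims.

CoMSIA similarity indices are dimensionless and roughly two orders of
magnitude smaller than CoMFA energies in kcal/mol, so applying the
2.00 kcal/mol filter to them removes every column. The pipeline
therefore uses a units-aware CoMSIA filter default of 0.02; both are
config knobs.

## PLS, validation and reports

Preprocessing: column filter (sd ≥ min-sigma, inclusive), then each
field block scaled to equal total variance (the CoMFA-standard block
scaling; per-column autoscaling would inflate noise columns), then
mean-centring of columns and response. The latent decomposition is
NIPALS for a single response; with as many components as the effective
rank it reproduces ordinary least squares, which is one of the suite's
anchor tests (the other anchor is agreement with an independent PLS
implementation).

Cross-validation leaves one compound out at a time and refits; column
filtering is applied once on the full training matrix and held fixed
across folds (the behaviour of the original tooling; per-fold filtering
would slightly pessimise q² and is not implemented). Reported
statistics: `q² = 1 − PRESS/Σ(y−ȳ)²`, `SEP = √(PRESS/(n−c−1))`,
`r² = 1 − RSS/TSS`, `SEE = √(RSS/(n−c−1))`,
`F = [r²/(1−r²)]·[(n−c−1)/c]`. The optimal number of components
maximises q² over 1..max (capped at n−2), ties within 1e-10 broken
toward fewer components; a perfect fit reports F as `Inf` rather than
failing. Field contributions are `Σ|βⱼ|σⱼ` per block on the
preprocessed scale, normalised to sum to 1; blocks emptied by the
filter appear at 0 so the report always shows the full field set.

Residuals are `experimental − predicted` everywhere, train and test
alike. (The published prediction table this package mirrors uses that
convention in its CoMFA columns but the opposite sign in its CoMSIA
columns; the package does not reproduce the flip.) Displayed pIC50
values are truncated — not rounded — at two decimals, matching the
published table's convention (12.7 μM → 4.8962 → "4.89"); full
precision is kept internally and the formatter is a flag.

Contour maps put the stdev·coefficient product of each retained column
back on the grid (filtered columns contribute zero); favoured and
disfavoured iso-levels are the 80th/20th percentiles of the nonzero
values, and each field exports as a Gaussian cube file.

The published headline statistics of the modelled study (q² 0.671/0.646,
r² 0.989/0.950, the 49/51 % and 13/25/22/20/20 % contributions) are not
reproducible from printed information alone — the full 3D structures of
the series and the original tooling's internals are unpublished — so
validation here is property-based: oracle equality of the LOO loop,
OLS collapse at full rank, recovery of planted structure, scrambling
controls, and analytic field identities.

## Reactivity descriptors

Global descriptors run through the Koopmans chain
(`I = −E_HOMO`, `A = −E_LUMO`; `μ = −(I+A)/2`, `χ = −μ`, `η = I−A`,
`S = 1/η`, `ω = μ²/2η`). The defining derivative forms
(∂E/∂N at fixed external potential) are represented only through these
finite-difference approximations; E, N and v(r) carry no direct data
fields. All energies are eV internally; hartree inputs convert at
27.211386 eV/hartree. η = 0 (degenerate frontier orbitals) makes S and
ω undefined and is an error, not a sentinel value.

Condensed Fukui functions are elementwise finite differences of atomic
electron populations. The population convention follows the data this
mirrors (q_k are *electron populations*, so f⁺ = q(N+1) − q(N)); a
`convention = "charge"` flag negates both differences for inputs that
are partial charges, since the two conventions flip sign. When the
population vectors conserve exactly one electron, Σf⁺ = Σf⁻ = 1, which
the fixtures guarantee by construction.

Report values are rounded half-even to 4 decimals; full precision is
retained internally. Driving the chain with the published (μ, η) pairs
of the ten-compound reference set reproduces the published S and ω for
the rows that are self-consistent; four rows' published ω (compounds 9,
29, 32, 39) differ by one unit in the 4th decimal from what their own
printed (μ, η) imply — upstream rounding of unrounded values — and the
package flags these (`reactivity_consistency()`) rather than correcting
either side. The published per-atom Fukui values of that study are not
recomputable because the underlying population analyses are
unpublished; the Fukui module is validated on conserving fixtures
instead.

## The synthetic generator

`make_aligned_series()` builds a planar fused bicyclic scaffold
(six-ring with ring nitrogen fused to a five-ring with sulfur — echoing
the thienopyridine chemotype) with idealised 1.40 Å bonds, and decorates
two ring positions from a small substituent vocabulary (H, Me, Et, Pr,
OH, NH₂, F, Cl) drawn deterministically from the seed. Scaffold
coordinates are shared exactly, so the series is aligned by
construction. Partial charges are a crude neutralised per-element table
— enough to make electrostatic fields vary, with no claim to realism.

`make_field_activity()` plants
`pIC50 = Xβ (rescaled) + ε, ε ~ N(0, noise_sd²)`. The coefficient
vector lives on up to 30 high-variance columns of one field block
(steric by default), restricted to columns meeting the 2.0 kcal/mol
filter so the planted model lies in the descriptor space the analysis
retains, and is constructed on the leading `planted_ncomp` (default 2)
principal directions of that region — making the declared planted
component count the construction's true latent dimension rather than a
label. Activities are linearly rescaled into 4.77–7.38 log units, the
observed range of the bundled series; this is cosmetic and recorded in
the emitted truth metadata along with β, the region, and the noise
draw, so recovery tests never re-derive the truth.

Default study conditions follow the modelled dataset: 46 compounds
(35 in recovery tests, the training-set size), noise sd 0.1 log units
on a ~2.6 log-unit activity range. What passing recovery tests shows:
the machinery identifies planted linear field-activity structure of
known dimension under realistic noise, and scrambling destroys it.
What it does not show: performance on real conformational ensembles,
alignment uncertainty, activity cliffs, or non-linear
structure-activity relations — none of which the generator emulates.

`make_orbital_fixtures()` samples frontier pairs in a plausible window
(HOMO −8..−4 eV, LUMO above it, below −0.2 eV) and population vectors
conserving exactly one electron, with ground-truth descriptors computed
directly from the defining formulas and attached.

## Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 non-collinear point pairs; collinear sets are an
  error (the rotation about the line is unconstrained).
* A grid point coinciding with a nucleus is clamped (squared distances
  floored at 1e-12 Å²) so steric values hit the cutoff instead of Inf.
* Column-filter boundary is inclusive with a 1e-12 guard, so a column
  at exactly the threshold is kept.
* NIPALS stops with an informative error when the requested component
  count exceeds the effective rank (weight or score norms below 1e-12).
* An all-zero contour (all coefficients zero) warns and reports NA
  levels rather than inventing percentiles.
* Duplicate compound ids are an error at table-reading time; rows with
  non-positive IC50 are dropped with a warning (the log transform is
  undefined there).
* Structure records whose coordinate block is all zeros are treated as
  2D and rejected per record.

Problem sizes in the tests and acceptance script — series of 6–46
compounds, grids at 2.0 Å spacing (hundreds to ~2000 points), 100
scrambling permutations — were chosen as the smallest sizes at which
every property under test is comfortably away from its decision
boundary.

## Known limitations

* Rigid alignment only; no conformational search, no strain term.
* The MCS is topological; it can legitimately differ from the
  geometric common frame when identical substituents occur at different
  sites.
* Charges: file-supplied charges win; the MMFF94 fallback shells out to
  Open Babel, and absent both, fields degrade to zero electrostatics.
* The hydrophobic weight table is element-level, far cruder than
  fragment-based logP schemes.
* CoMSIA donor/acceptor fields use indicator weights, not directional
  H-bond geometry.
* Quantum inputs are consumed, never computed: no DFT, no population
  analysis, no orbital isosurfaces.
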