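# qsar3d

Ligand-based 3D-QSAR for congeneric small-molecule series, with
conceptual-DFT reactivity descriptors. The package grew out of an
analysis of thienopyridine inhibitors of IKKβ (inhibitor-of-kappa-B
kinase subunit beta, the central kinase of canonical NF-κB signalling)
and ships that series' curated activity table, but every stage is
generic: any aligned congeneric series with activities can be modelled.

## What it computes

**Fields.** Aligned molecules are surrounded by a rectilinear grid
(default spacing 0.6 Å, margin 4 Å). CoMFA-style fields place an sp³
carbon probe (charge +1) at every point: steric energy is a 12-6
Lennard-Jones sum truncated at ±30 kcal/mol, electrostatic energy a
Coulomb sum `E(q) = Σᵢ 332·zᵢz_probe / (D(r)·r)` with distance-dependent
dielectric `D(r) = r`. CoMSIA-style fields are Gaussian similarity
indices `A(q) = −Σᵢ w_i exp(−α r²)` (α = 0.3 Å⁻²) for five properties:
steric (r³_vdW), electrostatic (partial charge), hydrophobic, H-bond
donor and acceptor.

**Model.** Activities are `pIC50 = −log₁₀ IC50[mol/L]`. Grid columns
with standard deviation below the minimum-sigma threshold
(2.00 kcal/mol) are filtered, field blocks are scaled to equal total
variance, and a NIPALS partial-least-squares model is fitted. Validation
follows the conventional CoMFA report: leave-one-out `q² = 1 −
PRESS/Σ(y−ȳ)²`, optimal component count (ONC) by maximal q², training
`r²`, `SEE = √(RSS/(n−c−1))`, `SEP = √(PRESS/(n−c−1))`,
`F = [r²/(1−r²)]·[(n−c−1)/c]`, per-field contribution fractions
`Σ|βⱼ|σⱼ` normalised per block, and stdev·coefficient contour maps
exported as Gaussian cube files.

**Reactivity descriptors.** From frontier orbital energies, via
Koopmans' theorem (`I = −E_HOMO`, `A = −E_LUMO`): chemical potential
`μ = −(I+A)/2`, electronegativity `χ = −μ`, hardness `η = I − A`,
softness `S = 1/η`, electrophilicity `ω = μ²/2η` (eV; S in eV⁻¹).
From atomic electron populations of the N, N±1 electron states:
condensed Fukui functions `f⁺(k) = q_k(N+1) − q_k(N)` (nucleophilic
attack) and `f⁻(k) = q_k(N) − q_k(N−1)` (electrophilic attack), with
the argmax atoms flagged as the preferred attack sites.

A seeded synthetic-data generator builds aligned series on a fused
bicyclic (thienopyridine-like) scaffold whose activity is a planted
linear function of field values plus Gaussian noise, so the whole
pipeline is testable without any external structures.

## Worked example

```r
library(qsar3d)

spec <- synthetic_series_spec(n_compounds = 35, noise_sd = 0.1, seed = 1)
mols <- make_aligned_series(spec)
act  <- make_field_activity(mols, spec)      # planted pIC50 table
m    <- qsar_pls(attr(act, "blocks"), act, ncomp = 2)
summary(m)
#> Statistical parameters (COMFA)
#>   Optimum Number of Components            2
#>   Cross-Validated Coefficient (q2)        0.954
#>   Non-Cross-Validated Coefficient (r2)    0.972
#>   Standard Error of Estimate              0.130
#>   Standard Error of Prediction            0.166
#>   Fisher Statistic Value                  551.30
#>   Fraction of Field Contribution
#>     steric          84.5 %
#>     electrostatic   15.5 %
```

The planted influential block was steric: the model recovers it as the
dominant contribution (84.5 %) with cross-validated q² = 0.954 despite
0.1 log units of noise, and the q²/r² gap shows the usual optimism of
the training fit. `prediction_table(m)` lists per-compound experimental,
predicted and residual (experimental − predicted) values;
`model_contours(m, dir = "maps")` writes the favoured/disfavoured
contour cubes.

Descriptors from frontier energies (here the energies implied by
μ = −3.5320 eV, η = 3.5277 eV — the most active compound of the bundled
series):

```r
fix <- make_orbital_fixtures(1, seed = 1, plant = data.frame(
  compound_id = "44", e_homo = -5.29585, e_lumo = -1.76815))
descriptor_table(fix)
#>   compound_id      mu    eta softness  omega max_omega
#> 1     synth01 -5.8507 2.1746   0.4599 7.8707      TRUE
#> 2          44 -3.5320 3.5277   0.2835 1.7682     FALSE
```

Row "44" reproduces the published softness (0.2835 eV⁻¹) and
electrophilicity (1.7682 eV) of that compound to four decimals.

The bundled data are available as `thienopyridine_activity()` (46
compounds, IC50 in μM, 35/11 train/test split),
`thienopyridine_predictions()` (published experimental and predicted
pIC50) and `reactivity_reference()` (published global descriptors of
the ten-compound quantum subset). An end-to-end run from a flat config
is `run_qsar()` / `run_cdft()`, also reachable from a shell via
`Rscript inst/cli/qsar3d.R <synth|fit|cdft> ...`.

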