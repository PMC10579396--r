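# cdc42rd

A mass-conserving bulk-surface reaction-diffusion model of the Cdc42 cell
polarization machinery of budding yeast (*Saccharomyces cerevisiae*), with
the analysis pipeline built around it: homogeneous steady states under
protein copy-number conservation, spherical-harmonic linear stability
analysis, stability diagrams over copy-number space, mutant and
functional-submodule scenarios, log-uniform parameter-space sampling with
phenotype viability filtering, and an axisymmetric nonlinear simulator of
spontaneous and stimulus-induced polarization.

## The model in brief

The cell is a sphere of radius *R*: cytosolic species *c* = (c_D, c_B, c_F)
(Cdc42-GDP, Bem1, the GEF Cdc24) diffuse in the bulk, membrane species
*m* = (m_d, m_t, m_tg, m_g, m_b, m_bf, m_f) diffuse on the surface, and the
compartments exchange mass only through attachment-detachment fluxes *f* at
the boundary:

    dc/dt = D_c lap(c),     -D_c n . grad(c) |_{r=R} = f(m, c|_R),
    dm/dt = D_m lap_S(m) + g(m, c|_R).

The mass-action kinetics *f*, *g* encode the Cdc42 GTPase cycle with an
explicit transient GAP-Cdc42 complex (the carrier of *GAP saturation*),
Bem1-mediated mutual recruitment of Cdc42 and its GEF (the wild-type
mechanism), effective self-recruitment of Cdc42 (vesicle transport and
effector-mediated delivery), and basal GEF cycling. The dynamics conserve
the copy numbers of Cdc42, GAPs, Bem1 and GEF, and these four totals are the
model's primary control parameters. Lateral instability of the homogeneous
steady state — a positive growth rate sigma_l for some spherical-harmonic
mode l >= 1, computed from the dispersion relation
lambda_max(J_l(sigma)) = sigma with the bulk slaved through
h_l(sigma) = kappa i_l'(kappa R)/i_l(kappa R) — is the criterion for
spontaneous polarization.

## Worked example

Classify the reference parameter set (produced by `analysis/01_screen.R`,
stored in `results/reference_params.json`) at wild-type copy numbers:

```r
library(cdc42rd)

cfg  <- load_config("results/reference_params.json")
base <- solve_homogeneous(cfg$parameters, cfg$copy_numbers, cfg$geometry)
base
#> Homogeneous steady state (converged)
#>   cytosol  [um^-3]: c_D=0.1581, c_B=1.916, c_F=0.1697
#>   membrane [um^-2]: m_d=4.265, m_t=34.86, m_tg=24.41, m_g=1.054, m_b=11.43, m_bf=12.44, m_f=0.15
#>   residuals: |f| <= 1.78e-15, |g| <= 7.11e-15

cl <- classify(cfg$parameters, cfg$copy_numbers, cfg$geometry, "WT")
cl
#> Linear stability classification: laterally_unstable
#>   fastest mode l* = 3, sigma = 0.03817 1/s
head(cl$modes, 3)
#>   l    lambda0      sigma unstable oscillatory converged
#> 1 1 0.02013944 0.02019179     TRUE       FALSE      TRUE
#> 2 2 0.03242734 0.03247611     TRUE       FALSE      TRUE
#> 3 3 0.03813531 0.03817220     TRUE       FALSE      TRUE
```

The point is *laterally unstable*: perturbations of low spherical-harmonic
modes grow (fastest l = 3 at 0.038/s, a ~30 s e-folding time), so this cell
polarizes spontaneously. At steady state most Cdc42 sits on the membrane
(m_t = 34.9/µm² active), and a large fraction of the GAPs is sequestered in
GAP-Cdc42 complexes (m_tg = 24.4 vs m_g = 1.1/µm²) — the enzyme-saturation
ingredient of the Bem1-independent (latent) mechanism. Removing Bem1
(`scenario = "bem1_delta"`) restricts instability to a low-GAP band below a
critical GAP/Cdc42 ratio; `critical_gap_threshold()` locates that boundary
and a GEF-activity boost (`gef_boost`) raises it.

## The analysis workflow

The numbered scripts under `analysis/` run the full study and write tables
under `results/`:

1. `01_screen.R` — sample 10^4 log-uniform parameter sets, filter them by
   the four mutant-phenotype predicates (WT polarizes; bem1Δ does not;
   bem1Δ bem3Δ does; WT tolerates 5x less Cdc42), select the log-mean
   reference set and the submodule-dissection representative.
2. `02_stability_diagrams.R` — wild-type vs Bem1-deletion stability
   diagrams, the critical GAP/Cdc42 threshold, and its GEF-boost ladder.
3. `03_submodule_dissection.R` — disable the three functional submodules
   (polar activation, polar GAP saturation, Cdc42 transport) one and two at
   a time: any two intact submodules polarize, a single one does not.
4. `04_simulations.R` — nonlinear bulk-surface simulations: seeded-mode
   growth rates vs the dispersion relation, spontaneous polarization to a
   single polar zone, the immobile-Cdc42 mechanism (polarized activity over
   a uniform total density), and stimulus-induced polarization outside the
   spontaneous regime.

Run them in order from the repository root:
`Rscript analysis/01_screen.R` etc.

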