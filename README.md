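# dcvax

Dendritic-cell (DC) vaccines against cancer work by injecting ex-vivo
matured, antigen-loaded DCs that travel to the spleen and prime cytotoxic
CD8+ T cells. How well this works depends on intracellular events inside
the DC — above all on NF-κB signaling, which controls the maturation
markers (IL-6, IL-8, IL-12, CD70) that drive T-cell priming. `dcvax` is an
R package for simulating and analysing this chain end to end, aimed at
systems-biology and immunotherapy modellers who want to ask: *which
molecular knobs inside the vaccine DC raise the memory T-cell yield?*

At its core is a 25-state, 46-parameter ODE/DDE system in three coupled
stages:

* **Bio-distribution** — four organ compartments (blood, lung, liver,
  spleen) with volume-scaled first-order trafficking:
  `d/dt DC_Spleen = mu_BS (Q_Blood/Q_Spleen) DC_Blood − mu_S0 DC_Spleen`,
  liver terminal.
* **DC maturation** — 17 intracellular species: stimulus-driven TRAF2/IRAK1
  activation, the IKK module, the NF-κB/IκBα negative-feedback core with
  moiety conservation `NFκB + NFκB·IκBα = N_tot`, and NF-κB-driven
  transcription/translation of IL-8 (with basal term and secretion), IL-6,
  IL-12 and CD70. Electroporation with constitutively active IKKβ (caIKK)
  is modelled as a reduced IKKβ degradation rate, 0.840 → 0.216 h⁻¹.
* **T-cell differentiation** — four pools (naive → early effector →
  short-lived effector / memory) driven by the delayed signal
  `S(t−τ)/(K₄+S(t−τ))`, with `S = Q_Spleen·DC_spleen·(IL6+IL8+IL12+CD70)`,
  τ = 24 h, a clonal burst factor A = 10, and
  `dM/dt = k_diff2_EE·EE + 0.1·k_deg_SLE·SLE`.

Around the model, the package provides synthetic generators for the four
calibration assay families, a staged hybrid calibration pipeline (Latin
hypercube starts → pattern search → L-BFGS-B refinement of a
max-normalized weighted least-squares cost), practical-identifiability
diagnostics (estimate correlations, bootstrap confidence intervals), Sobol
global sensitivity analysis of the memory readout, and the in-silico
perturbation experiments (vaccine-arm comparison, single and pairwise
fold-scans of molecular parameters).

## Worked example

```r
library(dcvax)

# compare a conventional vaccine with caIKK-electroporated DCs
cmp <- compare_vaccines()
cmp
#> <dcvax_vaccine_comparison> caIKK vs normal:
#>   memory fold-change: 3.673
#>   SLE fold-change:    3.683

# what does boosting IkBa-mRNA turnover (e.g. via microRNAs) buy?
sc <- perturb_scan_single("k_deg_mIkBa")
sc[sc$fold == 10, c("fold", "fold_change")]
#> # A tibble: 1 × 2
#>    fold fold_change
#>   <dbl>       <dbl>
#> 1    10        3.00

# combine IKKb stabilisation with IkBa-mRNA destabilisation
pair <- perturb_scan_pairwise("k_deg_IKKb", "k_deg_mIkBa",
                              grid1 = c(0.1, 1, 10), grid2 = c(0.1, 1, 10))
pair$gain_percent
#> [1] 159.8553
```

The first result says the caIKK arm multiplies steady-state memory T cells
about 3.7-fold over a conventional vaccine. The second says a 10-fold
faster IκBα-mRNA turnover (less inhibitor, more free NF-κB) triples the
memory yield on top of the caIKK baseline. The third says modulating both
NF-κB regulators together beats the better single modulation by ~160% —
combination is super-additive because the two perturbations multiply in
the inhibitor-loss/feedback-strength ratio that sets free NF-κB.

Trajectories, datasets, Sobol results and scans all have `autoplot()`
methods and broom-style `tidy()`/`glance()` tidiers; a thin CLI over the
same functions ships in `inst/cli/dcvax.R`
(`simulate`, `generate-data`, `sobol`, `perturb`, `compare` subcommands).

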