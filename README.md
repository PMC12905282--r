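# cooprbp

Quantitative analyses of cooperative RNA-binding-protein assembly on
GU/GT-repeat nucleic acids.

Multivalent RNA-binding proteins such as TDP-43 load onto long GU-rich RNA
(or GT-rich ssDNA) stretches cooperatively: once one protein unit is bound,
the next binds far more tightly. Whether that cooperativity holds — and how
it trades off against protein–protein contacts such as the head-to-tail
N-terminal-domain (NTD) interaction of TDP-43 — is read out with four
complementary assays. This package reimplements the quantitative core of
each as tested, reusable R code, together with synthetic-data generators
that produce ground-truth-labelled inputs for every stage:

* **ITC** (`fit_isotherm`) — one-set and two-sets-of-sites binding-heat
  models. Cumulative heat after each injection:
  `Q = Mt·V0·Σ_s [ n_s·ΔH_s·K_s·X / (1 + K_s·X) ]`, with X the free-ligand
  root of the mass balance, converted to per-injection heats with the
  displaced-volume correction
  `q_i = Q_i + dV_i/V0·(Q_i + Q_{i-1})/2 − Q_{i-1}`. The **cooperativity
  index** K_D1/K_D2 (weaker over tighter site, ≥ 1) quantifies how much more
  tightly the second protein loads onto the same oligonucleotide.
* **NMR CSP** (`csp_profile`, `peak_height_ratio`) — per-residue combined
  amide shift perturbation `Δδ = (0.5[(ΔδH)² + (0.14·ΔδN)²])^0.5`, flagged
  against a 3× standard-deviation threshold; peak-height ratios for
  interface-broadening and competition analyses.
* **SAXS** (`guinier_fit`, `dimensionless_kratky`, `correlation_volume_mw`,
  `pair_distribution`, `chi_square`, `select_stable_frames`) — Guinier
  Rg/I(0), dimensionless Kratky diagnostics, correlation-volume molecular
  weight, regularized P(r) inversion with automatic Dmax selection, reduced
  χ² between curves with the analytic scale factor
  `c = Σ(I_exp·I_theor/σ²) / Σ(I_theor²/σ²)`, and SEC-SAXS stable-frame
  averaging. A Debye bead-model simulator (`gen_saxs`, `open_chain`,
  `looped_chain`) provides extended-versus-compacted ground truth.
* **Imaging** (`detect_spots`, `filter_spots`, `mixing_score`,
  `aggregate_scores`) — the microtubule-bench mixing score (spot detection,
  tubular-shape filters >20 px² and <300 px² with width-to-length < 0.3,
  cytoplasm-normalised enrichment, pooled regression R²) and nuclear
  aggregate scores (background-subtracted relative intensity, poly-A mRNA
  enrichment).

## Worked example

A cooperative titration in which each oligonucleotide saturates two protein
monomers (total stoichiometry 0.5 per monomer), with the second site
100-fold tighter, at 1% heat noise:

```r
library(cooprbp)

protocol <- default_protocol()        # 0.2 mL cell, 15 uM protein,
                                      # 37 x 1 uL of 100 uM oligonucleotide
truth <- two_sets_model(n1 = 0.25, n2 = 0.25,
                        K1 = 1e6, K2 = 1e8,  # KD 1 uM and 10 nM
                        dH1 = -8, dH2 = -12)
iso <- gen_itc(truth, protocol, noise_sd = 1.2e-11, seed = 7)
fit <- fit_isotherm(iso, protocol, model_kind = "two_sets")
fit
#> ITC fit: two_sets model
#>   set 1: n = 0.250 (±0.013)  KD = 1.03e-06 M  dH = -7.570 kcal/mol  c = 3.65
#>   set 2: n = 0.254 (±0.004)  KD = 1.06e-08 M  dH = -12.039 kcal/mol  c = 358
#>   cooperativity index KD1/KD2 = 96.8
#>   RSS = 30.2, total n = 0.504
```

The fit recovers the total stoichiometry (0.504 ≈ 0.5 oligonucleotide per
monomer: two monomers per oligonucleotide) and a cooperativity index of
~97 (truth: 100) — the "very high K_D1/K_D2" signature of cooperative
loading. `thermodynamics(fit)` adds ΔG = −RT ln K and TΔS = ΔH − ΔG per
set; `plot(fit)` overlays the fitted curve on the observed heats.

On the SAXS side, an extended 16-bead chain versus its loop-closed
(compacted) counterpart:

```r
cur <- gen_saxs(open_chain(16), seq(0.004, 0.25, length.out = 300),
                snr = 60, seed = 1)
guinier_fit(cur)
#> Guinier fit: Rg = 54.365 A, I0 = 256.1 (25 points, qmax*Rg = 1.291, R2 = 0.98487)
pair_distribution(cur)
#> P(r): Dmax = 190.73 A, Rg = 56.07 A, back-transform chi2 = 0.882, lambda = 3.51
```

against exact coordinates Rg = 55.5 Å and Dmax = 190 Å; the looped chain of
the same bead count yields a much smaller Dmax — the geometric signature of
chain compaction.

A two-channel mixing score on a generated field of elongated spots whose
per-spot enrichments are correlated at ρ = 0.8:

```r
img <- gen_images(image_scenario(rho = 0.8, seed = 1))
mixing_pipeline(img)
#> Mixing score: R2 = 0.5989 (slope 0.789, intercept 0.381, n = 120 spots)
```

consistent with the expected R² ≈ ρ² = 0.64 up to sampling error.

## Documentation

The methods vignette (`vignettes/cooperative-binding-analyses.Rmd`) walks
through each model, its assumptions, the tunable parameters, what the
synthetic generators do and do not emulate, and the numerical choices
(Guinier truncation-bias correction, P(r) regularisation and Dmax scoring,
segmentation thresholds).
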