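# rhodokin

Kinetic analysis of branched rhodopsin photocycles from time-resolved
UV-Vis and FTIR difference spectra, with a caged-substrate enzyme-turnover
module. Built for spectroscopists working on enzymerhodopsins (light-
activated guanylyl cyclases and similar photoreceptor-enzyme fusions) who
need to turn transient difference-absorbance matrices into intermediate
lifetimes, species spectra, and catalytic rates — and for anyone who wants
a fully synthetic, parameter-controlled test bed for that analysis chain.

## The model

The photocycle is a closed four-state first-order scheme over the dark
state D and the intermediates K, L, M:

    D --(k_ex, light)--> K --k_KL--> L --k_LM--> M --k_MD--> D
                                     L --k_LD--> D            (branch)

with lifetimes τ = 1/k. Presets carry the published constants: the slow-
cycling C259S mutant at 20 °C (τ_L = 40 ms, τ_M = 3.13 s), the wild type
(τ_L = 30 ms, τ_M = 570 ms; M decay 5.5× faster), and a −10 °C variant
(L decay 50× slower, M decay 10× slower, branch fraction
k_LM/(k_LM + k_LD) = 0.5).

Measured (or simulated) data follow the bilinear model
ΔA(t, λ) = Σ_s c_s(t) · ε_s(λ): concentration profiles times species-
associated difference spectra. The analysis chain is the field-standard
one:

1. **SVD** of the ΔA matrix with autocorrelation-based rank selection;
2. **global multi-exponential fitting** with shared time constants by
   variable projection (per-channel amplitudes solved exactly; seeded
   multi-start over log-spaced lifetimes), yielding decay-associated
   difference spectra (DADS);
3. **target analysis**: the exact linear map DADS → SADS under an assumed
   kinetic topology (sequential Bateman cascade, or the branched L/M
   decay), plus a joint multi-dataset comparison of sequential vs
   branched topologies by AICc;
4. **marker-band machinery**: trace extraction at stated wavenumbers,
   signed peak detection with topographic prominence, steady-state
   detection, and onset-similarity between marker kinetics;
5. **caged-substrate turnover**: dark activity, uncaging, burst of
   pre-bound substrate, light-gated binding-limited turnover, optional
   product feedback inhibition, mass balance — simulated and fitted.

Because no raw spectral data accompany the study this package models, a
first-class synthetic-data module renders flash and continuous-
illumination datasets (UV-Vis and FTIR, Gaussian bands, Gaussian noise,
slow baseline drift) from any scheme and illumination protocol, and every
analysis is validated by parameter recovery against that generator.

## Worked example

Recover the photocycle lifetimes and species spectra from a synthetic
single-turnover experiment at 1 % noise:

```r
library(rhodokin)

ds  <- simulate_uvvis_single_turnover(scheme_c259s_20C(), sigma_rel = 0.01, seed = 1)
fit <- global_exponential_fit(ds, n_components = 2, seed = 1)
fit$time_constants
#> [1] 0.03998434 3.12711989

sp <- dads_to_sads(fit, topology = "sequential")
ds$axis[apply(sp$sads, 1, which.max)]
#> [1] 450 350
```

The fitted constants reproduce the generator's 40 ms (L) and 3.13 s (M)
lifetimes to a fraction of a percent, and the species-associated spectra
peak at 450 nm (L) and 350 nm (M), with the dark-state bleach at 545 nm.
The analogous FTIR experiment at −10 °C (`recover_ftir_species_m10()`)
selects two components after illumination stop and places the amide-I
marker bands of the recovered L and M spectra at 1647 and 1630 cm⁻¹.

The numbered scripts under `analysis/` run the full studies and write
their tables to `results/`:

| script | what it shows |
| --- | --- |
| `01_photocycle_kinetics.R` | preset lifetimes, 5.5× M-decay ratio, photostationary mixtures |
| `02_lifetime_recovery.R` | 20-seed lifetime recovery for all three variants, 50× temperature factor |
| `03_species_spectra.R` | SADS recovery: 450/350/545 nm and 1647/1630 cm⁻¹ |
| `04_topology_comparison.R` | sequential vs branched model comparison on joint data |
| `05_enzyme_turnover.R` | constant-slope phases, turnover fit, M/product onset identity |

## Layout

- `R/` — the package: kinetics, synthetic data, preprocessing,
  decomposition, markers, enzyme model, pipeline/config IO
- `analysis/` — numbered narrative drivers over the package
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/photocycle-methods.Rmd` — the models, assumptions,
  identifiability discussion, and numerical choices
- `scripts/acceptance.R` — end-to-end reproduction script
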