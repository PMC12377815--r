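# huxmtc

Simulation and calibration of a Huxley-type muscle–tendon complex (MTC)
model that unifies mechanical behaviour and metabolic energy expenditure,
aimed at muscle physiologists and musculoskeletal modellers who want a
cross-bridge-level alternative to Hill-type energetics.

The contractile element is a two-state cross-bridge model: the fraction
`n(x, t)` of attached cross-bridges over normalized bond length `x`
evolves along characteristics as

    Dn/Dt = f(x) (q(γ) F̃_isom(l̃_CE) − n) − g(x) n,   dx/dt = −u,

with piecewise-linear attachment/detachment rates `f, g` (Gaussian-smoothed
at their kinks, plus an extra detachment offset `g₃` that caps eccentric
force), first-order calcium dynamics `γ(t)` driven by block-pulse
stimulation, a Hill-sigmoid active state `q(γ)`, a quartic force–length
curve `F̃_isom`, and quadratic series/parallel elastic elements. CE force
is the normalized first moment of `n`; CE length is integrated as a
quasi-state of the differentiated force balance. Metabolic power is the
weighted rate of cross-bridge unbinding, split at `x = 0.8` to give
"free" mechanical detachment during lengthening its own weight, plus a
calcium-pumping cost `c₃ γ`:

    P_met = c₁·S·∫_{x<0.8} g n dx + c₂·S·∫_{x≥0.8} g n dx + c₃ γ.

The package provides the model core, experimental-protocol generators
(stimulus trains, sinusoidal work loops, isometric series), an adaptive
compiled simulator, a three-stage calibration pipeline (static elastic
properties → rate/activation dynamics → energetic coefficients via
pseudo-inverse least squares), a cross-validation harness, and a
synthetic-fixture module that emulates mouse soleus fibre-bundle
experiments so the whole pipeline is testable without laboratory data.
See `vignettes/huxmtc-methods.Rmd` for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(huxmtc)

pars <- default_parameters()
l0 <- pars$elastic$l_ce_opt + pars$elastic$see_slack * 1.04
inp <- make_length_trajectory(movement_protocol(
  kind = "sinusoid", amplitude = 0.25e-3, frequency = 2,
  offset_length = l0, stim_phase = "concentric", n_cycles = 2))
sim <- simulate_mtc(inp, pars)
sim
#> MTC simulation: 3001 samples over 1.5 s
#>   peak CE force 7.63 mN | steps 8055 | re-grids 151
#>   max |force-balance residual| 1.11e-05 x F_max
s <- summary(sim, window = c(0.1, 0.6))
cat(sprintf("cycle work %.3g uJ | mean P_met %.3g W/kg | efficiency %.3g\n",
            1e6 * s$work_mtc, s$mean_p_total, s$efficiency))
#> cycle work 1.41 uJ | mean P_met 7.83 W/kg | efficiency 0.601
```

A 0.25 mm, 2 Hz concentric work loop (5 pulses at 100 Hz, stimulation
spanning the shortening half-cycle) produces 1.4 µJ of external work per
cycle; mean metabolic power over the cycle is dominated by the
calcium-pumping term under the package's dimensional reading of the
unbinding integrals (see the vignette — the absolute cross-bridge/calcium
split is an explicitly open choice, while coefficient calibration and all
concentric-vs-eccentric comparisons are independent of it). The
force-balance residual line confirms the quasi-state integration held the
series-elastic force balance to ~1e-5 of maximum force.

Calibration on a synthetic animal:

```r
b <- sample_bundle(seed = 42)                      # ground-truth bundle
trials <- generate_trials(b, default_protocols(reduced = TRUE))
kinds <- sapply(trials, function(tr) tr$trial_kind)
sf  <- fit_static(trials[kinds == "static_fl"][[1]], b$pars, b$l_rest)
dyn <- fit_dynamic(trials[kinds %in% c("dynamic", "force_frequency")], sf,
                   n_starts = 5, seed = 1)
en  <- fit_energetics(trials[kinds == "metabolic"], dyn$pars)
```

On noiseless fixtures the static stage recovers its generating parameters
to ~1e-14 relative, the energetic stage recovers `(c₁, c₂, c₃)` to
linear-algebra precision, and the dynamic stage reproduces force traces
below 1% relative RMSE even when individual rate parameters differ from
the truth (the activation and cross-bridge dynamics form two systems in
series, so distinct parameter sets can yield near-identical forces).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/huxmtc", package = "huxmtc"))')" \
  simulate --params params.json --input trial.csv --out result.csv
```

Subcommands: `simulate`, `make-fixtures`, `fit`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch: it samples a
synthetic bundle from the seed, generates its noisy trial suite, runs all
three calibration stages, and simulates concentric and eccentric work
loops, logging the fitted values and summary scalars it computes along the
way before writing the JSON result file.
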