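# awaredyn

Dynamics of perceptual awareness under informational masking.

## The problem

When a regularly repeating pure-tone target is hidden inside a random
multi-tone masker, listeners often fail to detect it even though the target
is well above the sensory threshold — *informational masking*. Most studies
summarise performance with static indices (hit rate, d′) that ignore how the
percept builds up over the trial. `awaredyn` treats detection as a
time-to-event outcome: the transition from "no percept" to "percept" is
described by its hazard rate, and the influence of masker uncertainty,
masker–target similarity and target repetition rate on that hazard is
estimated with mixed-effect survival models.

The package is aimed at auditory psychophysicists and statisticians who
want to generate the stimuli of this paradigm, simulate detection behaviour
with a known generative truth, or run the survival analysis chain on trial
records of their own.

## The model

Detection times `T` (measured from target onset, right-censored at the
12 s trial end) follow a Cox proportional-hazards model with a
subject-specific random effect (gamma shared frailty):

    h(t | x, ξ) = h₀(t) · exp(β₁x₁ + ⋯ + βₚxₚ + ξ),   w = e^ξ ~ Gamma(mean 1, var v)

where the covariates are the factorial condition variables:

* masker **uncertainty** `H = fpo · ln Δ` (nats): `fpo` masker frequencies
  per octave, inter-tone intervals uniform with range `Δ` ms;
* masker–target **similarity** (masker minus target tone duration, ms);
* target repetition **rate** (Hz).

The fitted model yields per-term chi-square tests, estimated marginal means
on the log-hazard scale with Tukey-adjusted all-pairwise comparisons and a
compact letter display, Cox–Snell diagnostics, and per-condition hazard
`h(t|x)` and detection-probability `F(t|x)` curves. A synthetic-behaviour
module generates records from a Weibull frailty model with known
parameters, and an evidence-accumulation module implements the
first-passage model `Xₙ₊₁ = Xₙ + r(T − Xₙ) + εₙ₊₁` used for qualitative
comparison with the fitted hazards.

## Worked example

```r
library(awaredyn)

# masker uncertainty of the densest Experiment-I masker
masker_entropy(fpo = 64, iti_min = 100, iti_max = 1500)
#> [1] 463.6306

# simulate a 14-subject cohort and run the survival chain
cfg     <- generative_config()          # Experiment-I grid, known effects
records <- generate_dataset(cfg, seed = 1)
d       <- surv_data(drop_first_block(categorize(records, "I")))
fit     <- cox_frailty_fit(d, ~ similarity + uncertainty)
fit
#> Cox PH fit (Breslow ties), 1845 trials, 777 events
#> gamma frailty variance: 0.506
#>                      coef         se          z
#> similarity-40  -0.9114928 0.10931333  -8.338350
#> similarity0    -1.5945574 0.11144401 -14.308147
#> similarity40   -1.4932240 0.11863945 -12.586235
#> similarity80   -1.2057206 0.13907221  -8.669745
#> uncertainty116 -0.3986071 0.08059351  -4.945896
#> uncertainty464 -1.2833400 0.09917302 -12.940415

anova_effects(d, ~ similarity + uncertainty)$table
#>          term    chisq       df            p
#> 1     frailty 130.0984 1.000000 3.899538e-30
#> 2  similarity 179.5719 4.002394 9.259773e-38
#> 3 uncertainty 192.7121 2.001656 1.428752e-42
```

Coefficients are log-hazard ratios against the reference cell (similarity
−80 ms, uncertainty 29 nats): every other similarity level and both higher
uncertainty levels slow detection, e.g. detection proceeds at
`exp(−1.28) ≈ 0.28` times the reference hazard under the highest masker
uncertainty. The generating values here were `−0.9, −1.7, −1.5, −1.2` and
`−0.4, −1.3` with frailty variance `0.3`. `tukey_cld(emmeans_log_hazard(fit))`
groups the condition cells into letter classes, and
`predict_curves(fit, cells)` traces `h(t|x)` and `F(t|x)`; the time at which
`F` reaches 0.63 is the segregation time constant (`segregation_tau()`).

## Analysis workflow

The `analysis/` scripts run the full study pipeline end to end and write
their tables under `results/`:

1. `01_stimuli.R` — schedules, condition statistics, example tone events.
2. `02_simulate_behavior.R` — synthetic cohort with saved generative truth.
3. `03_detection_performance.R` — categorisation, d′, mixed-effect summary.
4. `04_survival_analysis.R` — frailty fit, term tests, EMMs/CLD,
   diagnostics, detection curves and segregation time constants.
5. `05_accumulator.R` — evidence-accumulation parameter sweeps and
   empirical hazard curves.

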