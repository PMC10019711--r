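---
title: "Methods: stimuli, survival models and synthetic detection behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimuli, survival models and synthetic detection behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The paradigm

In the multi-tone informational-masking paradigm a listener monitors a 12 s
random cloud of pure tones (the masker) for a regularly repeating pure-tone
stream (the target). The masker raises the target's detection threshold far
beyond what peripheral (energetic) overlap explains: the uncertainty of the
masker and its similarity to the target interfere with central processing.
`awaredyn` treats target detection as a state transition — from "no percept"
to "percept" — and analyses the time this transition takes with survival
models, so that the *dynamics* of perceptual awareness, not just the final
detection rate, become the object of study.

Three factorial experiments are represented. Each session has 243 trials
(162 with a target, 81 catch trials) in 6 blocks of 41 or 40 trials; each of
the 27 condition cells of an experiment is paired exactly once with each of
the six target frequencies. The manipulated variables are:

* **Masker uncertainty** — entropy of the masker tone distribution,
  `H = fpo * ln(delta)` in nats, where `fpo` is the number of masker
  frequencies per octave and `delta` (ms) the width of the uniform
  inter-tone-interval distribution. The interval range is taken in
  milliseconds and the logarithm is natural: this is the only convention
  that reproduces the published uncertainty table, and `masker_entropy()`
  is tested against all twelve cells of it.
* **Masker-target temporal similarity** — masker tone duration minus target
  tone duration (ms); negative values mean the target tone is the longer.
* **Target repetition rate** — 1–20 Hz depending on the experiment.

# Stimulus generation

`build_trial()` constructs each trial from first principles:

* Masker frequencies sit on a log-spaced grid between 239 and 5000 Hz with
  `fpo` frequencies per octave. The published description fixes the
  endpoints and the density but not the count; we include both endpoints
  and use `round(fpo * log2(5000/239)) + 1` grid points, which honours
  both statements.
* Each grid frequency is an independent renewal process: the gap between
  successive tone **onsets** is uniform on `[iti_min, iti_max]` ms with
  `iti_min = 100` ms. Reading "inter-tone interval" as onset-to-onset
  guarantees that tones within a channel never overlap (the longest tone is
  100 ms) and matches the renewal framing behind the entropy measure. The
  first onset in a channel is uniform on `[0, iti_max]`, a stationary-like
  start; the source description leaves this open.
* A **protected region** of one equivalent rectangular bandwidth
  (`ERB = 24.7 * (4.37 * f_kHz + 1)` Hz) on each side of the target
  frequency is kept free of masker tones, minimising energetic masking.
  On catch trials a *virtual* target frequency is drawn from the same
  six-frequency set and its protected region applied, so target and catch
  maskers are statistically indistinguishable to the listener.
* The target stream starts 600 ms after masker onset and repeats at the
  condition's rate for as long as `onset + duration <= 12` s.
* `render_audio()` sums equal-amplitude sinusoids with 10 ms raised-cosine
  ramps. Digital level is normalised deterministically — per-tone amplitude
  `0.9 / (maximum instantaneous polyphony)` — which guarantees the mixture
  never clips; hardware SPL calibration is outside the package's scope.
* The training block uses 1 kHz, 100 ms targets at 1 or 2 Hz over maskers
  with 20 or 60 ms tones and mean inter-tone intervals of 600 or 800 ms.
  The density of the training maskers is not specified in the source
  design; we fix `fpo = 16`, a mid-range value.

Catch-trial allocation is the one schedule quantity the design leaves open:
only the 162 target trials are pinned to the 27 x 6 balance. We allocate
the 81 catch trials as 3 per condition cell so that false-alarm rates are
defined and balanced per masker condition.

# Synthetic detection behaviour

Real behavioural records are not distributed with the package, so
`generate_dataset()` produces trial records with the statistical structure
the analysis assumes:

* **Latent detection time** (from target onset, seconds) follows a Weibull
  proportional-hazards model with subject frailty:
  `S(t | x, w) = exp(-w e^{x'b} (t/lambda)^k)`, drawn by inverse-CDF. The
  default baseline (`k = 2`, `lambda = 6.5` s) has an increasing hazard —
  awareness builds up as target tones accumulate — and a seconds-scale mean
  detection time, consistent with the paradigm. A parametric baseline is a
  deliberate choice: a semiparametric baseline is not identifiable for a
  generator.
* **Frailty** `w` is mean-1 gamma with variance `v` (default 0.3) on the
  hazard scale; this is the standard shared-frailty convention and is
  equivalent to an additive subject effect `xi = log w` on the log-hazard
  scale.
* **Effects** are supplied as per-level log-hazard increments with the
  reference level at zero. The default Experiment-I map ranks conditions
  as observed in this paradigm: hazards highest at similarity -80 ms
  (target tones much longer than masker tones) and lowest at high masker
  uncertainty.
* **Right censoring**: latent times past the 11.4 s of target presence are
  misses. **Guesses**: with probability `p_guess` (default 0.02) a target
  response is replaced by a uniform draw below the experiment's guess
  cut-off, exercising the dismissal rule downstream. **False alarms**:
  catch trials respond at the first event of a Poisson process (default
  0.024 s^-1, i.e. about a quarter of catch trials), matching the
  magnitude of observed false-alarm rates.

The generator reproduces the *model* the analysis assumes, not a listener:
it has no attention lapses, no learning across blocks, no non-proportional
hazards and no trial-to-trial dependence beyond the shared frailty. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct under the assumed model, not that the model fits any particular
listener.

# Analysis pipeline

* **Categorisation** (`categorize()`): detecting a regularity requires at
  least two target tones, so responses faster than two periods of the
  fastest rate — 1600 / 700 / 1100 ms from trial start for Experiments
  I / II / III — are guesses. Guesses are *dismissed*: they leave both the
  d-prime counts (numerator and denominator) and the survival data, rather
  than being recoded as misses.
* **First block** is dropped (`drop_first_block()`) to avoid residual
  learning effects.
* **Outlier screening** (`flag_far_outliers()`) replaces qualitative
  inspection with a reproducible rule: subjects whose false-alarm rate
  exceeds the across-subject mean by two standard deviations are flagged.
* **d-prime** uses the log-linear edge correction
  `(count + 0.5) / (N + 1)`, which keeps rates strictly inside (0, 1) and
  is symmetric; `d' = z(HR) - z(FAR)` is computed per masker-uncertainty
  cell only, because catch trials carry no target properties. The
  mixed-effect summary (`lmm_dprime()`) is a REML random-intercept model
  with between-within denominator degrees of freedom.
* **Survival data** (`surv_data()`): time origin at target onset (600 ms
  into the trial) — the hazard of detecting a target is undefined before
  the target exists — with administrative censoring at 11400 ms. Catch
  trials never enter.
* **Cox PH with gamma frailty** (`cox_frailty_fit()`): penalized partial
  likelihood via the `survival` package, Breslow ties (millisecond times
  make ties rare, and Breslow matches the baseline estimator used for the
  curves), frailty variance by profile marginal likelihood. Treatment
  contrasts against the lowest similarity / uncertainty / rate cell pin
  the reference estimated marginal mean at exactly 0 with SE 0.
* **Term tests** (`anova_effects()`): sequential likelihood-ratio
  chi-squares between nested penalized fits that share the full model's
  profiled frailty variance; degrees of freedom are differences in total
  *effective* df and are non-integer in general. The frailty term itself
  is tested on 1 df from the integrated (marginal) likelihood against the
  no-frailty fit.
* **EMMs and letters** (`emmeans_log_hazard()`, `tukey_cld()`): cell means
  of the linear predictor averaged over the balanced factor grid, SEs by
  the delta method; pairwise p-values adjusted by the studentized-range
  (Tukey) method for a family of k estimates with asymptotic df; letters
  by the insert-and-absorb algorithm, whose output is checked in the tests
  against a brute-force clique cover of the non-significance graph.
* **Diagnostics** (`cox_snell()`): `r_i = H_hat(t_i | x_i, xi_i)`; for a
  well-specified model the Nelson-Aalen cumulative hazard of the residuals
  follows the identity line.
* **Curves** (`predict_curves()`): the detection CDF `F(t) = 1 - S(t)` and
  the hazard from Gaussian-kernel-smoothed Breslow increments (default
  bandwidth: 1/15 of the observed time span; kernel smoothing is biased at
  the extreme edges of the time range, so comparisons are made on the
  interior). Frailty is integrated out through the gamma Laplace transform
  by default (`S(t|x) = (1 + v H0(t) e^{x'b})^{-1/v}`), giving
  population-averaged curves; conditional (`xi = 0`) curves are available,
  since group-level figures can be drawn under either convention.
* **Segregation time constant** (`segregation_tau()`): the smallest `t`
  with `F(t) >= 0.63`, linearly interpolated between evaluation points
  (no interpolation rule is prescribed at the source; linear is the
  obvious choice on a fine grid) and censored when the level is never
  reached within the trial.

# Evidence accumulation

The supplementary first-passage model iterates
`X[n+1] = X[n] + r (T - X[n]) + eps[n+1]`, `eps ~ N(0, sigma^2)`, from
`X[0] = x0`. Activity saturates at `T < threshold`, so crossings are purely
noise-driven. Three open choices are fixed as follows: the threshold, never
stated numerically, defaults to 1.0 and is exposed as a parameter; updates
map to time as one update per target tone (`step_dt = 1/rate`), the natural
bridge to repetition-rate effects, with a plain fixed-step mode available;
crossings are detected at integer steps without within-step interpolation.
Empirical hazards are raw binned estimates
(`events / (at-risk x bin width)`); no smoothing is applied unless the user
asks for it elsewhere, since it is unknown whether the original curves were
smoothed.

# Numerical and testing choices

Simulation sizes are chosen to make Monte-Carlo noise small relative to the
tested tolerances while keeping the default test run fast: distributional
checks use 1e5 draws (3 standard errors), accumulator comparisons 1e4
trials, parameter recovery 100 replicates of a 14-subject, 243-trial
session, test size calibration 200 simulated datasets, and diagnostics
2000-plus observations. The recovery study generates with effects in
[-1, 1] on the log-hazard scale and frailty variance 0.3, runs the *full*
pipeline (categorisation, first-block removal, guess dismissal, fitting),
and requires per-coefficient |bias| < 0.05, RMSE < 0.2 and 95% Wald
coverage of at least 90%. Degenerate inputs are handled explicitly: a
zero-width interval distribution is rejected (the entropy needs a positive
range), an all-censored sample yields a flat survival curve, an empty risk set
truncates the empirical hazard with a flag, and times beyond the last event
clamp the predicted curves with a flag.

# Known limitations

* The printed coefficient tables of the original study cannot be
  reproduced numerically: they require the human behavioural records,
  which are not distributed. The package reproduces the *machinery* and
  validates it by parameter recovery on synthetic data.
* The non-integer degrees of freedom reported for interaction terms in
  frailty models depend on a penalized-df convention that is not spelled
  out at the source; the convention used here (differences of total
  effective df) is documented, not asserted to be identical.
* `emmeans`-style back-transformation to the response scale is not
  implemented; all marginal means are on the log-hazard scale, as in the
  original tables.
* The audio path renders at digital full scale; no SPL calibration.
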