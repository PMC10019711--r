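#' Guess cut-off for an experiment
#'
#' Detecting a regularity requires hearing at least two target tones, so any
#' response faster than two periods of the fastest repetition rate (counted
#' from trial start) is treated as a guess: 1600 ms for Experiment I, 700 ms
#' for Experiment II, 1100 ms for Experiment III.
#'
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @return Cut-off in ms from trial start.
#' @export
guess_cutoff <- function(experiment) {
  experiment <- match.arg(experiment, c("I", "II", "III"))
  c(I = 1600, II = 700, III = 1100)[[experiment]]
}

#' Subject frailties
#'
#' Multiplicative subject-specific random effects on the hazard: mean-1 gamma
#' with variance `v` (shape `1/v`, scale `v`), degenerating to 1 when `v = 0`.
#'
#' @param n Number of subjects.
#' @param v Frailty variance (>= 0).
#' @return Numeric vector of `n` frailties.
#' @export
sample_frailty <- function(n, v) {
  if (v < 0) stop("frailty variance must be >= 0")
  if (v == 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / v, scale = v)
}

#' Latent detection times from the Weibull proportional-hazards model
#'
#' Inverse-CDF draws from the conditional survival function
#' `S(t | x, w) = exp(-w * exp(x'b) * (t / scale)^shape)`, i.e.
#' `t = scale * (-log(U) / (w * exp(lp)))^(1 / shape)`. Times are measured
#' from target onset.
#'
#' @param n Number of draws.
#' @param lp Linear predictor `x'b` (recycled).
#' @param w Frailty (recycled).
#' @param shape,scale Weibull baseline parameters (time unit = seconds).
#' @return Numeric vector of latent detection times in seconds.
#' @export
sample_detection_time <- function(n, lp, w = 1, shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  u <- stats::runif(n)
  scale * (-log(u) / (w * exp(lp)))^(1 / shape)
}

#' Generative configuration for synthetic detection behaviour
#'
#' Bundles the pieces the generator needs: the experiment grid, per-level
#' log-hazard effects, the gamma frailty variance, a Weibull baseline for the
#' latent detection time (from target onset), a catch-trial false-alarm rate
#' and a guess probability.
#'
#' The default scenario emulates a cohort of 14 subjects on the Experiment-I
#' grid with effects that qualitatively rank conditions as observed in the
#' paradigm: hazards are highest when the target tone is much longer than the
#' masker tone (similarity -80 ms) and decrease as masker uncertainty grows.
#' The baseline (shape 2, scale 6.5 s) has an increasing hazard -- awareness
#' builds up over repeated target tones -- and a seconds-scale mean detection
#' time.
#'
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @param n_subjects Number of subjects.
#' @param beta Named list of named numeric vectors: one element per covariate
#'   factor (`"similarity"`, `"uncertainty"`, `"rate"`), each mapping a level
#'   label to its log-hazard effect (reference level 0).
#' @param frailty_variance Gamma frailty variance (>= 0).
#' @param baseline_shape,baseline_scale Weibull baseline parameters (seconds).
#' @param fa_rate Catch-trial false alarms per second (Poisson process).
#' @param p_guess Probability a target-trial response is replaced by a
#'   sub-cut-off guess.
#' @return A `generative_config` list.
#' @export
generative_config <- function(experiment = "I",
                              n_subjects = 14,
                              beta = NULL,
                              frailty_variance = 0.3,
                              baseline_shape = 2,
                              baseline_scale = 6.5,
                              fa_rate = 0.024,
                              p_guess = 0.02) {
  experiment <- match.arg(experiment, c("I", "II", "III"))
  if (frailty_variance < 0) stop("frailty variance must be >= 0")
  if (fa_rate < 0) stop("fa_rate must be >= 0")
  if (p_guess < 0 || p_guess >= 1) stop("p_guess must lie in [0, 1)")
  if (is.null(beta)) {
    if (experiment != "I")
      stop("default beta map is defined for Experiment I; supply beta")
    beta <- list(
      similarity = c("-80" = 0, "-40" = -0.9, "0" = -1.7,
                     "40" = -1.5, "80" = -1.2),
      uncertainty = c("29" = 0, "116" = -0.4, "464" = -1.3)
    )
  }
  structure(list(experiment = experiment, n_subjects = n_subjects,
                 beta = beta, frailty_variance = frailty_variance,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 fa_rate = fa_rate, p_guess = p_guess),
            class = "generative_config")
}

# linear predictor from the beta map for one record table
beta_linear_predictor <- function(records, beta) {
  lp <- numeric(nrow(records))
  for (fac in names(beta)) {
    lev <- as.character(records[[fac]])
    eff <- beta[[fac]][lev]
    if (anyNA(eff))
      stop("covariate pattern absent from beta map: ", fac, " = ",
           paste(unique(lev[is.na(eff)]), collapse = ", "))
    lp <- lp + unname(eff)
  }
  lp
}

#' Generate a synthetic trial-record table
#'
#' Simulates every subject through a freshly randomised schedule of the
#' configured experiment. Target trials get a latent detection time from the
#' Weibull shared-frailty proportional-hazards model; responses later than the
#' 12 s trial end are misses (right-censored). With probability `p_guess` the
#' response is replaced by a uniform draw below the experiment's guess
#' cut-off. Catch trials respond at the first event of a Poisson false-alarm
#' process, if it falls within the trial.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed; the full table is deterministic given the seed.
#' @return Data frame of trial records (`subject`, schedule columns,
#'   `response_time` in ms from trial start or `NA`), with the configuration
#'   and the true per-subject frailties attached as attributes.
#' @export
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(seed)
  w <- sample_frailty(config$n_subjects, config$frailty_variance)
  sched_seeds <- sample.int(.Machine$integer.max, config$n_subjects)
  cutoff <- guess_cutoff(config$experiment)
  onset_ms <- 600
  horizon_s <- 12 - onset_ms / 1000

  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    sched <- build_schedule(config$experiment, sched_seeds[s])
    sched$uncertainty <- as.character(round(sched$entropy))
    rec <- sched[setdiff(names(sched), "seed")]
    rec$subject <- sprintf("S%02d", s)
    rec$response_time <- NA_real_

    tgt <- rec$target_present
    lp <- beta_linear_predictor(rec[tgt, ], config$beta)
    lat <- sample_detection_time(sum(tgt), lp, w[s],
                                 config$baseline_shape, config$baseline_scale)
    resp <- ifelse(lat <= horizon_s, onset_ms + lat * 1000, NA_real_)
    rec$response_time[tgt] <- resp

    # catch trials: first arrival of the false-alarm process within 12 s
    n_catch <- sum(!tgt)
    if (config$fa_rate > 0 && n_catch > 0) {
      arrival <- stats::rexp(n_catch, rate = config$fa_rate)
      rec$response_time[!tgt] <- ifelse(arrival <= 12, arrival * 1000,
                                        NA_real_)
    }

    # sub-cut-off guesses on target trials
    if (config$p_guess > 0) {
      g <- tgt & stats::runif(nrow(rec)) < config$p_guess
      rec$response_time[g] <- stats::runif(sum(g), 0, cutoff)
    }
    rec
  })
  out <- do.call(rbind, subjects)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "frailty") <- w
  attr(out, "experiment") <- config$experiment
  out
}
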