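#' Log-spaced frequency sequence
#'
#' Frequencies with a constant ratio between neighbours, endpoints included.
#' The six-frequency target set of the masking experiments is
#' `log_spaced_frequencies(489, 2924, 6, round_hz = TRUE)`.
#'
#' @param f_lo,f_hi Lower and upper endpoint in Hz (`f_hi > f_lo > 0`).
#' @param n Number of frequencies (at least 2).
#' @param round_hz Round to the nearest integer Hz (used for the target set).
#' @return Numeric vector of `n` frequencies in Hz.
#' @export
#' @examples
#' log_spaced_frequencies(489, 2924, 6, round_hz = TRUE)
log_spaced_frequencies <- function(f_lo, f_hi, n, round_hz = FALSE) {
  if (n < 2) stop("n must be at least 2")
  if (!(f_hi > f_lo && f_lo > 0)) stop("need f_hi > f_lo > 0")
  f <- exp(seq(log(f_lo), log(f_hi), length.out = n))
  if (round_hz) round(f) else f
}

#' Target tone frequency set
#'
#' The six equiprobable log-spaced target frequencies between 489 and 2924 Hz.
#' @return Integer-valued numeric vector of length 6 (Hz).
#' @export
target_frequencies <- function() {
  log_spaced_frequencies(489, 2924, 6, round_hz = TRUE)
}

#' Equivalent rectangular bandwidth
#'
#' Auditory-filter bandwidth approximation `24.7 * (4.37 * f + 1)` with the
#' centre frequency `f` in kHz.
#'
#' @param f_khz Centre frequency in kHz (positive).
#' @return Bandwidth in Hz.
#' @export
#' @examples
#' erb(1)   # about 132.6 Hz at 1 kHz
erb <- function(f_khz) {
  if (any(f_khz <= 0)) stop("frequency must be positive")
  24.7 * (4.37 * f_khz + 1)
}

#' Protected region around a target frequency
#'
#' Masker-free band centred on the target: one ERB on each side, evaluated at
#' the target frequency (in kHz), for a total extension of two ERB.
#'
#' @param f_t Target frequency in Hz.
#' @return Numeric vector `c(lower, upper)` in Hz.
#' @export
protected_region <- function(f_t) {
  bw <- erb(f_t / 1000)
  c(f_t - bw, f_t + bw)
}

#' Masker frequency grid
#'
#' Frequencies equally spaced on a log scale between `f_lo` and `f_hi` at a
#' density of `fpo` frequencies per octave, endpoints included:
#' `round(fpo * log2(f_hi / f_lo)) + 1` grid points.
#'
#' @param fpo Frequencies per octave (integer, >= 1).
#' @param f_lo,f_hi Band edges in Hz; the experiments use 239-5000 Hz.
#' @return Numeric vector of grid frequencies in Hz.
#' @export
masker_frequency_grid <- function(fpo, f_lo = 239, f_hi = 5000) {
  if (fpo < 1) stop("fpo must be >= 1")
  n <- round(fpo * log2(f_hi / f_lo)) + 1
  log_spaced_frequencies(f_lo, f_hi, n)
}

#' Draw tone onsets for one masker frequency channel
#'
#' Renewal process: the first onset is uniform on `[0, iti_max]`, successive
#' onset-to-onset gaps are i.i.d. uniform on `[iti_min, iti_max]` (ms), and the
#' sequence is truncated at the trial end. Because the minimum gap (100 ms)
#' is at least as long as the longest tone, tones in a channel never overlap.
#'
#' @param iti_min,iti_max Gap bounds in ms (`iti_max > iti_min >= 0`).
#' @param trial_duration Trial length in seconds.
#' @return Numeric vector of onsets in seconds (possibly empty). Uses the
#'   current R random number stream.
#' @export
draw_channel_onsets <- function(iti_min, iti_max, trial_duration = 12) {
  if (iti_max < iti_min || iti_min < 0) stop("need iti_max >= iti_min >= 0")
  if (trial_duration <= 0) return(numeric(0))
  # expected count plus slack; extend in the (rare) case the draw falls short
  onset <- stats::runif(1, 0, iti_max) / 1000
  onsets <- numeric(0)
  while (onset <= trial_duration) {
    onsets <- c(onsets, onset)
    onset <- onset + stats::runif(1, iti_min, iti_max) / 1000
  }
  onsets
}

#' Factorial condition grid of an experiment
#'
#' The 27 condition cells of one experiment with derived stimulus statistics.
#' Times in ms, rate in Hz; the inter-tone bounds follow from the mean
#' inter-tone interval with a fixed 100 ms minimum,
#' `miti = (iti_min + iti_max) / 2`.
#'
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @return Data frame of 27 rows: `masker_dur`, `target_dur`, `rate`, `fpo`,
#'   `miti`, `iti_min`, `iti_max`, `similarity`, `entropy`, `std`.
#' @export
experiment_conditions <- function(experiment) {
  experiment <- match.arg(experiment, c("I", "II", "III"))
  grid <- switch(experiment,
    I = expand.grid(masker_dur = c(20, 60, 100),
                    target_dur = c(20, 60, 100),
                    fpo = c(4, 16, 64),
                    rate = 1,
                    miti = 800),
    II = expand.grid(masker_dur = c(20, 60, 100),
                     rate = c(5, 10, 20),
                     fpo = c(4, 16, 64),
                     target_dur = 20,
                     miti = 800),
    III = expand.grid(fpo = c(16, 32, 64),
                      miti = c(200, 600, 1200),
                      rate = c(1, 2, 5),
                      masker_dur = 20,
                      target_dur = 60))
  grid$iti_min <- 100
  grid$iti_max <- 2 * grid$miti - grid$iti_min
  grid$similarity <- grid$masker_dur - grid$target_dur
  grid$entropy <- grid$fpo * log(grid$iti_max - grid$iti_min)
  grid$std <- grid$fpo / (grid$miti / 1000)
  grid[c("masker_dur", "target_dur", "rate", "fpo", "miti",
         "iti_min", "iti_max", "similarity", "entropy", "std")]
}

#' Experiment trial schedule
#'
#' Builds the full 243-trial schedule of one experiment: 162 target trials
#' (each of the 27 condition cells paired exactly once with each of the six
#' target frequencies) and 81 catch trials (each cell three times). Trials are
#' randomly ordered and distributed into 6 blocks of 41 or 40 trials. Catch
#' trials carry a virtual target frequency whose protected region is applied
#' so target and catch maskers are statistically indistinguishable.
#'
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @param master_seed Integer seed; equal seeds give identical schedules.
#' @return Data frame with one row per trial: `trial_id`, `block`,
#'   `target_present`, `target_freq` (virtual for catch trials), the condition
#'   columns of the factorial grid, derived stimulus statistics (`similarity`,
#'   `entropy`, `std`) and a per-trial `seed` for tone-event materialisation.
#' @export
build_schedule <- function(experiment, master_seed) {
  experiment <- match.arg(experiment, c("I", "II", "III"))
  conds <- experiment_conditions(experiment)
  set.seed(master_seed)

  # target trials: 27 cells x 6 frequencies, balanced pairing
  freqs <- target_frequencies()
  tgt <- conds[rep(seq_len(nrow(conds)), each = length(freqs)), ]
  tgt$target_freq <- rep(freqs, nrow(conds))
  tgt$target_present <- TRUE

  # catch trials: 27 cells x 3, virtual target frequency for the protected
  # region drawn at random
  ctch <- conds[rep(seq_len(nrow(conds)), each = 3), ]
  ctch$target_freq <- sample(freqs, nrow(ctch), replace = TRUE)
  ctch$target_present <- FALSE

  sched <- rbind(tgt, ctch)
  sched <- sched[sample.int(nrow(sched)), ]
  sizes <- sample(c(41, 41, 41, 40, 40, 40))
  sched$block <- rep(seq_len(6), times = sizes)
  sched$trial_id <- seq_len(nrow(sched))
  sched$seed <- sample.int(.Machine$integer.max, nrow(sched))
  rownames(sched) <- NULL
  sched <- sched[c("trial_id", "block", "target_present", "target_freq",
                   setdiff(names(conds), "trial_id"), "seed")]
  attr(sched, "experiment") <- experiment
  attr(sched, "master_seed") <- master_seed
  sched
}

#' Training-block trials
#'
#' Open-ended training trials: maskers with tone duration 20 or 60 ms and mean
#' inter-tone interval 600 or 800 ms; targets at 1 kHz, 100 ms tones,
#' repetition rate 1 or 2 Hz drawn at random per trial; one third of trials
#' are catch trials.
#'
#' @param n_trials Number of trials to emit.
#' @param seed Integer seed.
#' @return Data frame in the same layout as [build_schedule()] (block = 1).
#' @export
build_training_block <- function(n_trials, seed) {
  set.seed(seed)
  miti <- sample(c(600, 800), n_trials, replace = TRUE)
  out <- data.frame(
    trial_id = seq_len(n_trials),
    block = 1L,
    target_present = stats::runif(n_trials) > 1 / 3,
    target_freq = 1000,
    masker_dur = sample(c(20, 60), n_trials, replace = TRUE),
    target_dur = 100,
    rate = sample(c(1, 2), n_trials, replace = TRUE),
    fpo = 16,
    miti = miti,
    iti_min = 100,
    iti_max = 2 * miti - 100
  )
  out$similarity <- out$masker_dur - out$target_dur
  out$entropy <- out$fpo * log(out$iti_max - out$iti_min)
  out$std <- out$fpo / (out$miti / 1000)
  out$seed <- sample.int(.Machine$integer.max, n_trials)
  attr(out, "experiment") <- "training"
  out
}

#' Materialise the tone events of one trial
#'
#' Draws every masker channel outside the protected region as an independent
#' renewal process and lays down the regular target stream (when present)
#' starting 600 ms after masker onset, emitting tones while
#' `onset + duration <= trial_duration`. All tones share the same relative
#' amplitude (0 dB target-to-masker ratio).
#'
#' @param masker List with `tone_duration` (ms), `fpo`, `iti_min`, `iti_max`
#'   (ms).
#' @param target List with `tone_duration` (ms), `rate` (Hz), `frequency`
#'   (Hz, one of [target_frequencies()]), optional `start` (ms, default 600);
#'   or `NULL` for a catch trial.
#' @param protect_freq Frequency whose protected region is carved out of the
#'   masker grid. Defaults to the target frequency; must be supplied for catch
#'   trials (the virtual target frequency).
#' @param trial_duration Trial length in seconds.
#' @param seed Optional integer seed for reproducible event draws.
#' @return Data frame of tone events: `onset_s`, `duration_s`, `frequency_hz`,
#'   `role` (`"target"`/`"masker"`), `amplitude`.
#' @export
build_trial <- function(masker, target = NULL, protect_freq = NULL,
                        trial_duration = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(protect_freq)) {
    if (is.null(target)) stop("catch trials need a (virtual) protect_freq")
    protect_freq <- target$frequency
  }
  if (!protect_freq %in% target_frequencies())
    stop("target frequency must belong to the six-frequency set")

  region <- protected_region(protect_freq)
  grid <- masker_frequency_grid(masker$fpo)
  grid <- grid[grid < region[1] | grid > region[2]]

  mask_dur <- masker$tone_duration / 1000
  ev <- lapply(grid, function(f) {
    on <- draw_channel_onsets(masker$iti_min, masker$iti_max, trial_duration)
    on <- on[on + mask_dur <= trial_duration]
    if (!length(on)) return(NULL)
    data.frame(onset_s = on, duration_s = mask_dur, frequency_hz = f,
               role = "masker", amplitude = 1)
  })
  ev <- do.call(rbind, ev)

  if (!is.null(target)) {
    start <- if (is.null(target$start)) 0.6 else target$start / 1000
    tdur <- target$tone_duration / 1000
    on <- seq(start, trial_duration, by = 1 / target$rate)
    on <- on[on + tdur <= trial_duration]
    ev <- rbind(ev, data.frame(onset_s = on, duration_s = tdur,
                               frequency_hz = target$frequency,
                               role = "target", amplitude = 1))
  }
  if (is.null(ev))
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     frequency_hz = numeric(0), role = character(0),
                     amplitude = numeric(0))
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  ev
}

#' Materialise tone events for every trial of a schedule
#'
#' @param schedule A schedule from [build_schedule()] or
#'   [build_training_block()].
#' @return Data frame of tone events across trials with `trial_id` and
#'   `block` columns prepended.
#' @export
materialize_schedule <- function(schedule) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    tr <- schedule[i, ]
    masker <- list(tone_duration = tr$masker_dur, fpo = tr$fpo,
                   iti_min = tr$iti_min, iti_max = tr$iti_max)
    target <- if (tr$target_present)
      list(tone_duration = tr$target_dur, rate = tr$rate,
           frequency = tr$target_freq)
    ev <- build_trial(masker, target, protect_freq = tr$target_freq,
                      seed = tr$seed)
    if (nrow(ev)) cbind(trial_id = tr$trial_id, block = tr$block, ev)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# maximum number of simultaneously sounding tones in an event table
max_polyphony <- function(events) {
  if (!nrow(events)) return(0L)
  bounds <- rbind(data.frame(t = events$onset_s, d = 1L),
                  data.frame(t = events$onset_s + events$duration_s, d = -1L))
  bounds <- bounds[order(bounds$t, bounds$d), ]  # offsets before onsets at ties
  max(cumsum(bounds$d))
}

#' Render a trial to a waveform
#'
#' Sum of sinusoids, one per tone event, each with 10 ms raised-cosine on/off
#' ramps. All tones share the same peak amplitude; a global gain of
#' `0.9 / max polyphony` guarantees the mixture never clips.
#'
#' @param events Tone-event table from [build_trial()].
#' @param sample_rate Samples per second (44100 for the experiments).
#' @param duration Waveform length in seconds.
#' @return Numeric vector of samples in `[-1, 1]`.
#' @export
render_audio <- function(events, sample_rate = 44100, duration = 12) {
  n <- round(duration * sample_rate)
  x <- numeric(n)
  if (!nrow(events)) return(x)
  gain <- 0.9 / max(1L, max_polyphony(events))
  ramp <- 0.010
  for (i in seq_len(nrow(events))) {
    dur <- events$duration_s[i]
    m <- round(dur * sample_rate)
    t <- (seq_len(m) - 1) / sample_rate
    env <- rep(1, m)
    up <- t < ramp
    env[up] <- 0.5 * (1 - cos(pi * t[up] / ramp))
    dn <- t > dur - ramp
    env[dn] <- 0.5 * (1 - cos(pi * (dur - t[dn]) / ramp))
    tone <- events$amplitude[i] * gain * env *
      sin(2 * pi * events$frequency_hz[i] * t)
    i0 <- round(events$onset_s[i] * sample_rate)
    idx <- i0 + seq_len(m)
    keep <- idx <= n
    x[idx[keep]] <- x[idx[keep]] + tone[keep]
  }
  if (max(abs(x)) > 1 - 2^-15) stop("internal error: rendered mixture clips")
  x
}
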