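#' Evidence-accumulator configuration
#'
#' Parameters of the leaky evidence-accumulation model
#' `X[n+1] = X[n] + r * (T - X[n]) + eps[n+1]`, with i.i.d. Gaussian noise
#' `eps ~ N(0, sigma^2)`. Activity drifts towards the saturation level
#' `target_level` (T) at rate `r` and, since `T < threshold`, can cross the
#' detection threshold only thanks to the noise. One update per target tone
#' presentation is the default linkage to experimental conditions
#' (`step_dt = 1 / rate`).
#'
#' @param target_level Saturation level T (must be below `threshold`).
#' @param r Accumulation rate in (0, 1).
#' @param sigma Noise standard deviation (>= 0).
#' @param x0 Initial activity.
#' @param threshold Detection bound (default 1).
#' @param step_dt Seconds per update (default 1, i.e. a 1 Hz target).
#' @param max_time Trial horizon in seconds (default 12).
#' @return An `accumulator_params` list.
#' @export
accumulator_params <- function(target_level = 0.9, r = 0.7, sigma = 0.15,
                               x0 = 0, threshold = 1, step_dt = 1,
                               max_time = 12) {
  if (!(r > 0 && r < 1)) stop("r must lie in (0, 1)")
  if (sigma < 0) stop("sigma must be >= 0")
  if (target_level >= threshold) stop("target_level must be below threshold")
  if (step_dt <= 0 || max_time <= 0) stop("step_dt and max_time must be > 0")
  structure(list(target_level = target_level, r = r, sigma = sigma, x0 = x0,
                 threshold = threshold, step_dt = step_dt,
                 max_time = max_time),
            class = "accumulator_params")
}

#' Noise-free accumulator trajectory
#'
#' Closed form of the recursion with `sigma = 0`:
#' `X[n] = T + (x0 - T) * (1 - r)^n`.
#'
#' @param params An [accumulator_params()].
#' @param n_steps Number of updates.
#' @return Numeric vector `X[0], ..., X[n_steps]`.
#' @export
accumulator_closed_form <- function(params, n_steps) {
  n <- 0:n_steps
  params$target_level + (params$x0 - params$target_level) * (1 - params$r)^n
}

#' Simulate one accumulator path
#'
#' Iterates the recursion until the activity first reaches the threshold
#' (crossing is checked at integer steps, no within-step interpolation) or
#' until the trial horizon.
#'
#' @param params An [accumulator_params()].
#' @return List with the trajectory `x` (from `X[0]`), the first-passage
#'   `step` (`NA` if censored), the passage `time` in seconds (`NA` if
#'   censored) and the `censored` flag. Uses the current R random stream.
#' @export
simulate_path <- function(params) {
  n_max <- floor(params$max_time / params$step_dt)
  x <- numeric(n_max + 1)
  x[1] <- params$x0
  for (n in seq_len(n_max)) {
    x[n + 1] <- x[n] + params$r * (params$target_level - x[n]) +
      stats::rnorm(1, 0, params$sigma)
    if (x[n + 1] >= params$threshold) {
      return(list(x = x[seq_len(n + 1)], step = n, time = n * params$step_dt,
                  censored = FALSE))
    }
  }
  list(x = x, step = NA_integer_, time = NA_real_, censored = TRUE)
}

#' First-passage times of the accumulator
#'
#' Simulates `n_trials` independent replicates (vectorised over trials) and
#' records when each first crosses the threshold; replicates that never cross
#' within the horizon are censored at `max_time`.
#'
#' @param params An [accumulator_params()].
#' @param n_trials Number of replicates (>= 1).
#' @return Data frame with `time` (seconds; `max_time` for censored rows) and
#'   `censored`; `params` attached as an attribute.
#' @export
first_passage_times <- function(params, n_trials) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  n_max <- floor(params$max_time / params$step_dt)
  x <- rep(params$x0, n_trials)
  step <- rep(NA_integer_, n_trials)
  alive <- rep(TRUE, n_trials)
  for (n in seq_len(n_max)) {
    idx <- which(alive)
    if (!length(idx)) break
    x[idx] <- x[idx] + params$r * (params$target_level - x[idx]) +
      stats::rnorm(length(idx), 0, params$sigma)
    crossed <- idx[x[idx] >= params$threshold]
    step[crossed] <- n
    alive[crossed] <- FALSE
  }
  censored <- is.na(step)
  out <- data.frame(time = ifelse(censored, params$max_time,
                                  step * params$step_dt),
                    censored = censored)
  attr(out, "params") <- params
  out
}

#' Empirical hazard rate from binned first-passage times
#'
#' `h(bin) = events in bin / (at risk at bin start x bin width)`. Censored
#' observations leave the risk set at their censoring time. Bins whose risk
#' set is empty are dropped and the truncation is flagged.
#'
#' @param sample Data frame with `time` and `censored` (e.g. from
#'   [first_passage_times()]), or a numeric vector of event times.
#' @param breaks Increasing bin edges partitioning `(0, max_time]`.
#' @return Data frame with `t_lo`, `t_hi`, `n_events`, `n_risk`, `hazard`;
#'   attribute `truncated` is `TRUE` when empty-risk bins were dropped.
#' @export
empirical_hazard <- function(sample, breaks) {
  if (is.numeric(sample)) sample <- data.frame(time = sample,
                                               censored = FALSE)
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be increasing")
  nb <- length(breaks) - 1
  out <- data.frame(t_lo = breaks[-length(breaks)], t_hi = breaks[-1],
                    n_events = NA_real_, n_risk = NA_real_,
                    hazard = NA_real_)
  for (b in seq_len(nb)) {
    at_risk <- sum(sample$time >= out$t_lo[b])
    ev <- sum(!sample$censored & sample$time >= out$t_lo[b] &
                sample$time < out$t_hi[b])
    # events exactly at the final edge belong to the last bin
    if (b == nb) ev <- ev + sum(!sample$censored & sample$time == out$t_hi[b])
    out$n_events[b] <- ev
    out$n_risk[b] <- at_risk
    out$hazard[b] <- if (at_risk > 0)
      ev / (at_risk * (out$t_hi[b] - out$t_lo[b])) else NA_real_
  }
  truncated <- anyNA(out$hazard)
  out <- out[!is.na(out$hazard), ]
  attr(out, "truncated") <- truncated
  out
}
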