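#' Masker uncertainty (entropy)
#'
#' Entropy of the masker tone distribution in nats. Each of the `fpo`
#' frequency channels per octave is an independent renewal process whose
#' inter-tone interval is uniform on a range of width `delta = iti_max -
#' iti_min` (ms), so the masker entropy is `fpo * ln(delta)`.
#'
#' @param fpo Frequencies per octave.
#' @param iti_min,iti_max Inter-tone interval bounds in ms.
#' @return Entropy in nats.
#' @export
#' @examples
#' masker_entropy(32, 100, 1500)   # 231.82 nats
masker_entropy <- function(fpo, iti_min, iti_max) {
  delta <- iti_max - iti_min
  if (any(delta <= 0)) stop("need iti_max > iti_min")
  fpo * log(delta)
}

#' Masker-target temporal similarity
#'
#' Masker tone duration minus target tone duration, in ms. Negative values
#' mean the target tone is longer than the masker tone.
#'
#' @param masker_duration,target_duration Tone durations in ms (positive).
#' @return Similarity in ms.
#' @export
similarity <- function(masker_duration, target_duration) {
  if (any(masker_duration <= 0) || any(target_duration <= 0))
    stop("durations must be positive")
  masker_duration - target_duration
}

#' Masker spectro-temporal density
#'
#' Masker tones per second per octave: `fpo / miti` with the mean inter-tone
#' interval in seconds.
#'
#' @param fpo Frequencies per octave.
#' @param miti Mean inter-tone interval in ms.
#' @return Density in tones per second per octave.
#' @export
spectro_temporal_density <- function(fpo, miti) {
  if (any(miti <= 0)) stop("miti must be positive")
  fpo / (miti / 1000)
}

#' Segregation time constant
#'
#' Time at which a detection-time cumulative distribution reaches a given
#' level (0.63 by convention), with linear interpolation between evaluation
#' points. When the curve never reaches the level within its support the
#' result is censored.
#'
#' @param time Evaluation times (seconds, increasing).
#' @param cdf Non-decreasing CDF values in `[0, 1]` at `time`.
#' @param level Crossing level, default 0.63.
#' @return List with `tau` (seconds, `NA` when censored), `censored` flag and
#'   `level`.
#' @export
segregation_tau <- function(time, cdf, level = 0.63) {
  if (length(time) != length(cdf)) stop("time and cdf lengths differ")
  if (is.unsorted(time)) stop("time must be increasing")
  if (any(diff(cdf) < -1e-12)) stop("cdf must be non-decreasing")
  if (any(cdf < -1e-12 | cdf > 1 + 1e-12)) stop("cdf values must lie in [0, 1]")
  if (max(cdf) < level)
    return(list(tau = NA_real_, censored = TRUE, level = level))
  i <- which(cdf >= level)[1]
  if (i == 1 || cdf[i] == level) {
    tau <- time[i]
  } else {
    # linear interpolation on the segment crossing the level
    tau <- time[i - 1] + (level - cdf[i - 1]) *
      (time[i] - time[i - 1]) / (cdf[i] - cdf[i - 1])
  }
  list(tau = tau, censored = FALSE, level = level)
}
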