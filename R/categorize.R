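#' Categorise trial records
#'
#' Classifies every trial as hit, miss, false alarm, correct rejection or
#' guess. A hit is a target trial with a response between the experiment's
#' guess cut-off and the 12 s trial end; a target-trial response faster than
#' the cut-off is a guess and is dismissed from valid responses (it enters
#' neither the d-prime counts nor the survival data); a target trial without
#' a valid response is a miss; a catch trial with any response is a false
#' alarm, otherwise a correct rejection.
#'
#' @param records Trial-record table (see [generate_dataset()]): needs
#'   `target_present` and `response_time` (ms from trial start, `NA` if none).
#' @param experiment `"I"`, `"II"` or `"III"` (sets the cut-off). Defaults to
#'   the table's `experiment` attribute.
#' @return `records` with a `category` factor column; the cut-off (ms) is
#'   attached as attribute `cutoff`.
#' @export
categorize <- function(records, experiment = attr(records, "experiment")) {
  if (is.null(experiment)) stop("experiment must be supplied")
  cutoff <- guess_cutoff(experiment)
  rt <- records$response_time
  responded <- !is.na(rt) & rt <= 12000
  cat <- ifelse(records$target_present,
                ifelse(!responded, "miss",
                       ifelse(rt < cutoff, "guess", "hit")),
                ifelse(responded, "false_alarm", "correct_rejection"))
  records$category <- factor(cat, levels = c("hit", "miss", "false_alarm",
                                             "correct_rejection", "guess"))
  attr(records, "cutoff") <- cutoff
  attr(records, "experiment") <- experiment
  records
}

#' Discard first-block trials
#'
#' Detection performance is lower in the first block (residual learning), so
#' block-1 trials are dropped before analysis. Idempotent.
#'
#' @param records Trial-record table with a `block` column.
#' @return The table without block-1 rows.
#' @export
drop_first_block <- function(records) {
  out <- records[records$block != 1, ]
  rownames(out) <- NULL
  out
}

#' Per-subject detection performance (d-prime) by masker uncertainty
#'
#' Hit and false-alarm rates per subject and masker-uncertainty condition,
#' edge-corrected as `(count + 0.5) / (N + 1)` so rates stay strictly inside
#' (0, 1), and the sensitivity index `d' = z(HR) - z(FAR)` with `z` the
#' standard normal quantile function. False alarms are only defined per
#' masker condition (a catch trial has no target properties), so d-prime is
#' computed per uncertainty cell; dismissed guesses are excluded from both
#' numerator and denominator of the hit rate.
#'
#' @param categorized Output of [categorize()].
#' @return Data frame: `subject`, `uncertainty`, counts, `hr`, `far`,
#'   `dprime`.
#' @export
dprime_by_uncertainty <- function(categorized) {
  if (is.null(categorized$category)) stop("run categorize() first")
  if (is.null(categorized$uncertainty))
    categorized$uncertainty <- as.character(round(categorized$entropy))
  split_by <- interaction(categorized$subject, categorized$uncertainty,
                          drop = TRUE)
  cells <- lapply(split(categorized, split_by), function(d) {
    hits <- sum(d$category == "hit")
    guesses <- sum(d$category == "guess")
    n_target <- sum(d$target_present) - guesses
    fa <- sum(d$category == "false_alarm")
    n_catch <- sum(!d$target_present)
    if (n_target <= 0 || n_catch <= 0)
      return(data.frame(subject = d$subject[1],
                        uncertainty = d$uncertainty[1],
                        hits = hits, n_target = n_target, fa = fa,
                        n_catch = n_catch, hr = NA_real_, far = NA_real_,
                        dprime = NA_real_))
    hr <- (hits + 0.5) / (n_target + 1)
    far <- (fa + 0.5) / (n_catch + 1)
    data.frame(subject = d$subject[1], uncertainty = d$uncertainty[1],
               hits = hits, n_target = n_target, fa = fa, n_catch = n_catch,
               hr = hr, far = far,
               dprime = stats::qnorm(hr) - stats::qnorm(far))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Mixed-effect summary of d-prime
#'
#' Random-intercept linear mixed model (REML) for d-prime with masker
#' uncertainty as the fixed effect and subject as the random intercept;
#' reports the F test for uncertainty with between-within degrees of freedom.
#'
#' @param dp d-prime table from [dprime_by_uncertainty()].
#' @return List with the fitted `lme` model and `F`, `df1`, `df2`, `p` for
#'   the uncertainty effect.
#' @export
lmm_dprime <- function(dp) {
  dp <- dp[!is.na(dp$dprime), ]
  if (length(unique(dp$subject)) < 2 || length(unique(dp$uncertainty)) < 2)
    stop("need at least 2 subjects and 2 uncertainty conditions")
  dp$uncertainty <- factor(dp$uncertainty)
  fit <- nlme::lme(dprime ~ uncertainty, random = ~ 1 | subject, data = dp,
                   method = "REML")
  an <- stats::anova(fit)
  row <- an["uncertainty", ]
  list(model = fit, F = row$`F-value`, df1 = row$numDF, df2 = row$denDF,
       p = row$`p-value`)
}

#' Outlier screening by false-alarm rate
#'
#' Reproducible stand-in for qualitative outlier inspection: flags subjects
#' whose overall false-alarm rate exceeds the across-subject mean by more
#' than two standard deviations.
#'
#' @param categorized Output of [categorize()].
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flag_far_outliers <- function(categorized) {
  per <- split(categorized, categorized$subject)
  far <- vapply(per, function(d) {
    nc <- sum(!d$target_present)
    if (nc == 0) return(NA_real_)
    sum(d$category == "false_alarm") / nc
  }, numeric(1))
  thr <- mean(far, na.rm = TRUE) + 2 * stats::sd(far, na.rm = TRUE)
  names(far)[!is.na(far) & far > thr]
}

#' Assemble the survival dataset
#'
#' Target trials only, with time measured from target onset (600 ms into the
#' trial) and administrative right-censoring at 11400 ms: hits contribute an
#' event at `response_time - 600`, misses a censored time of 11400 ms.
#' Dismissed guesses and catch trials never enter. Covariate factors are
#' releveled so the lowest similarity / uncertainty / rate is the reference
#' cell.
#'
#' @param categorized Output of [categorize()].
#' @return Data frame with `time` (ms from target onset), `event` (0/1),
#'   `subject` and covariate factors (`similarity`, `uncertainty`, `rate`).
#' @export
surv_data <- function(categorized) {
  if (is.null(categorized$category)) stop("run categorize() first")
  d <- categorized[categorized$target_present &
                     categorized$category != "guess", ]
  d$event <- as.integer(d$category == "hit")
  d$time <- ifelse(d$event == 1, d$response_time - 600, 11400)
  num_levels <- function(x) factor(x, levels = sort(unique(as.numeric(x))))
  d$similarity <- num_levels(d$similarity)
  d$uncertainty <- num_levels(d$uncertainty)
  d$rate <- num_levels(d$rate)
  d$subject <- factor(d$subject)
  rownames(d) <- NULL
  d
}
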