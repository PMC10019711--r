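#' Kaplan-Meier and Nelson-Aalen estimators
#'
#' Product-limit survival and Nelson-Aalen cumulative-hazard step functions
#' under right censoring (thin wrapper around [survival::survfit()]).
#'
#' @param times Positive event/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List with the step `table` (`time`, `n_risk`, `n_event`, `surv`,
#'   `cumhaz`) and step functions `surv_fun`, `cumhaz_fun`.
#' @export
km_nelson_aalen <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          ctype = 1, stype = 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, cumhaz = sf$cumhaz)
  list(table = tab,
       surv_fun = stats::stepfun(tab$time, c(1, tab$surv)),
       cumhaz_fun = stats::stepfun(tab$time, c(0, tab$cumhaz)))
}

# build the coxph formula for a fixed-effect RHS plus optional gamma frailty
frailty_formula <- function(rhs, subject, frailty_variance) {
  frail <- if (is.null(frailty_variance)) {
    sprintf('survival::frailty(%s, distribution = "gamma")', subject)
  } else if (frailty_variance > 0) {
    sprintf('survival::frailty(%s, distribution = "gamma", theta = %.12g)',
            subject, frailty_variance)
  }
  terms <- c(rhs, frail)
  if (!length(terms)) terms <- "1"
  stats::as.formula(paste("survival::Surv(time, event) ~",
                          paste(terms, collapse = " + ")))
}

#' Cox proportional-hazards fit with gamma shared frailty
#'
#' Fits the detection-time model: proportional hazards in the condition
#' factors with a multiplicative mean-1 gamma random effect per subject on
#' the hazard. The penalized partial likelihood is maximised via
#' [survival::coxph()] with Breslow tie handling; the frailty variance is
#' chosen by the profile marginal likelihood (or held fixed). With the
#' frailty variance fixed at 0 the model reduces exactly to plain Cox PH.
#'
#' @param data Survival table from [surv_data()] (columns `time`, `event`,
#'   the covariate factors, and the subject id).
#' @param fixed One-sided formula of fixed effects, e.g.
#'   `~ similarity * uncertainty`; `~ 1` fits the null model.
#' @param subject Name of the grouping column for the frailty.
#' @param frailty_variance `NULL` to estimate the variance, `0` for plain Cox
#'   PH, or a positive value to hold it fixed.
#' @return A `frailty_fit`: coefficients with standard errors, coefficient
#'   covariance, frailty variance and per-subject log-frailties, Breslow
#'   baseline cumulative hazard, penalized and integrated log-likelihoods,
#'   effective degrees of freedom per term, and the underlying `coxph` model.
#' @export
cox_frailty_fit <- function(data, fixed = ~ similarity * uncertainty,
                            subject = "subject", frailty_variance = NULL) {
  if (sum(data$event) < 1) stop("need at least one event")
  rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  if (rhs == "1") rhs <- NULL
  use_frailty <- is.null(frailty_variance) || frailty_variance > 0
  form <- frailty_formula(rhs, if (use_frailty) subject, frailty_variance)
  fit <- survival::coxph(form, data = data, ties = "breslow",
                         model = TRUE, x = TRUE)
  # uncentered Breslow baseline; survfit warns about interactions even though
  # the centered = FALSE correction does not involve the covariate means
  bh <- suppressWarnings(survival::basehaz(fit, centered = FALSE))
  hist1 <- if (use_frailty) fit$history[[1]]
  theta <- if (!use_frailty) 0
           else if (is.null(frailty_variance)) hist1$theta
           else frailty_variance
  cf <- stats::coef(fit)
  vc <- fit$var
  if (length(cf)) dimnames(vc) <- list(names(cf), names(cf))
  # plain coxph carries no effective-df vector; null models a length-1 loglik
  pll <- fit$loglik[length(fit$loglik)]
  dfv <- if (!is.null(fit$df)) fit$df else length(cf)
  structure(list(
    model = fit,
    coefficients = cf,
    se = if (length(cf)) sqrt(diag(as.matrix(vc))) else numeric(0),
    vcov = vc,
    frailty_variance = theta,
    frail = fit$frail,
    basehaz = bh,
    loglik = fit$loglik,
    penalized_loglik = pll,
    integrated_loglik = if (use_frailty) hist1$c.loglik else pll,
    df = dfv,
    edf = sum(dfv),
    fixed = fixed,
    subject = subject,
    xlevels = fit$xlevels,
    n = fit$n, nevent = fit$nevent
  ), class = "frailty_fit")
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat("Cox PH fit (Breslow ties),", x$n, "trials,", x$nevent, "events\n")
  cat("gamma frailty variance:", format(x$frailty_variance, digits = 4), "\n")
  if (length(x$coefficients)) {
    print(data.frame(coef = x$coefficients, se = x$se,
                     z = x$coefficients / x$se))
  } else cat("(no fixed-effect coefficients)\n")
  invisible(x)
}

#' Sequential likelihood-ratio tests for model terms
#'
#' Assesses each model term by a sequential likelihood-ratio chi-square
#' between nested penalized fits, adding terms in their natural order (main
#' effects, then interactions). All nested fits share the frailty variance
#' profiled on the full model, so the penalized partial log-likelihoods are
#' comparable; degrees of freedom are differences in total effective df and
#' may be non-integer. The frailty term itself is tested on 1 df by
#' comparing the integrated (marginal) likelihood of the full frailty model
#' against the full model without frailty.
#'
#' @param data Survival table from [surv_data()].
#' @param fixed One-sided formula for the full fixed-effect structure, e.g.
#'   `~ similarity * uncertainty`.
#' @param subject Frailty grouping column.
#' @param frailty Include the gamma frailty term (and its test)?
#' @return List with the per-term `table` (`term`, `chisq`, `df`, `p`), the
#'   full `fit`, and the sequence of nested fits.
#' @export
anova_effects <- function(data, fixed = ~ similarity * uncertainty,
                          subject = "subject", frailty = TRUE) {
  labels <- attr(stats::terms(fixed), "term.labels")
  if (!length(labels)) stop("fixed must contain at least one term")
  if (frailty) {
    full <- cox_frailty_fit(data, fixed, subject)
    theta <- full$frailty_variance
    full_nofrail <- cox_frailty_fit(data, fixed, subject,
                                    frailty_variance = 0)
  } else {
    full <- cox_frailty_fit(data, fixed, subject, frailty_variance = 0)
    theta <- 0
  }
  fv <- if (frailty) theta else 0
  fits <- vector("list", length(labels) + 1)
  fits[[1]] <- cox_frailty_fit(data, ~ 1, subject, frailty_variance = fv)
  for (k in seq_along(labels)) {
    rhs <- stats::reformulate(labels[seq_len(k)])
    fits[[k + 1]] <- cox_frailty_fit(data, rhs, subject,
                                     frailty_variance = fv)
  }
  ll <- vapply(fits, `[[`, numeric(1), "penalized_loglik")
  edf <- vapply(fits, `[[`, numeric(1), "edf")
  chisq <- pmax(0, 2 * diff(ll))
  df <- pmax(diff(edf), 1e-8)
  tab <- data.frame(term = labels, chisq = chisq, df = df,
                    p = stats::pchisq(chisq, df, lower.tail = FALSE))
  if (frailty) {
    fr_chisq <- max(0, 2 * (full$integrated_loglik -
                              full_nofrail$penalized_loglik))
    tab <- rbind(data.frame(term = "frailty", chisq = fr_chisq, df = 1,
                            p = stats::pchisq(fr_chisq, 1,
                                              lower.tail = FALSE)),
                 tab)
  }
  rownames(tab) <- NULL
  list(table = tab, fit = full, nested = fits)
}

#' Cox-Snell residuals
#'
#' `r_i = H_hat(t_i | x_i, xi_i)`: the fitted cumulative hazard at each
#' observed time, conditional on the estimated frailty. For a well-specified
#' model the residuals behave like a censored unit-exponential sample, so
#' their Nelson-Aalen cumulative hazard should follow the identity line.
#'
#' @param fit A [cox_frailty_fit()].
#' @return Data frame with `residual` and `event`; censored observations
#'   carry their censoring flag.
#' @export
cox_snell <- function(fit) {
  stopifnot(inherits(fit, "frailty_fit"))
  ev <- fit$model$y[, "status"]
  data.frame(residual = ev - stats::residuals(fit$model, type = "martingale"),
             event = ev)
}

# linear predictors for new covariate cells (fixed effects only)
cell_linear_predictor <- function(fit, newdata) {
  if (!length(fit$coefficients)) return(rep(0, nrow(newdata)))
  mm <- stats::model.matrix(fit$fixed, newdata, xlev = fit$xlevels)
  mm <- mm[, names(fit$coefficients), drop = FALSE]
  drop(mm %*% fit$coefficients)
}

#' Predicted hazard and detection-probability curves
#'
#' For each covariate cell, evaluates the survival function from the Breslow
#' baseline, the detection-time CDF `F(t) = 1 - S(t)`, and the hazard from
#' Gaussian-kernel-smoothed baseline increments scaled by `exp(x'b)`. With
#' `marginal = TRUE` (default) the subject frailty is integrated out via the
#' gamma Laplace transform, `S(t|x) = (1 + v H0(t) exp(x'b))^(-1/v)`; with
#' `marginal = FALSE` curves are conditional on a frailty of 1 (`xi = 0`).
#'
#' @param fit A [cox_frailty_fit()].
#' @param newdata Data frame of covariate cells (factor columns matching the
#'   fixed-effect formula).
#' @param times Evaluation times, same unit as the fitted times; defaults to
#'   200 points spanning the observed event times. Times beyond the last
#'   event are clamped to it and flagged in attribute `extrapolated`.
#' @param marginal Integrate the frailty out (population-averaged curves)?
#' @param bandwidth Gaussian kernel bandwidth for hazard smoothing; default
#'   is 1/15 of the observed time span.
#' @return Long data frame: `cell`, `time`, `hazard`, `surv`, `cdf`.
#' @export
predict_curves <- function(fit, newdata, times = NULL, marginal = TRUE,
                           bandwidth = NULL) {
  stopifnot(inherits(fit, "frailty_fit"))
  bh <- fit$basehaz
  tmax <- max(bh$time)
  if (is.null(times)) times <- seq(0, tmax, length.out = 200)
  extrapolated <- times > tmax
  times <- pmin(times, tmax)
  if (is.null(bandwidth)) bandwidth <- diff(range(bh$time)) / 15

  H0fun <- stats::stepfun(bh$time, c(0, bh$hazard))
  H0 <- H0fun(times)
  dH0 <- diff(c(0, bh$hazard))
  h0 <- vapply(times, function(t) {
    sum(dH0 * stats::dnorm((t - bh$time) / bandwidth)) / bandwidth
  }, numeric(1))

  lp <- cell_linear_predictor(fit, newdata)
  v <- fit$frailty_variance
  cells <- if (!is.null(rownames(newdata)) &&
               !identical(rownames(newdata), as.character(seq_len(nrow(newdata)))))
    rownames(newdata)
  else apply(newdata, 1, paste, collapse = ":")

  out <- do.call(rbind, lapply(seq_along(lp), function(i) {
    r <- exp(lp[i])
    if (marginal && v > 0) {
      surv <- (1 + v * H0 * r)^(-1 / v)
      haz <- h0 * r / (1 + v * H0 * r)
    } else {
      surv <- exp(-H0 * r)
      haz <- h0 * r
    }
    data.frame(cell = cells[i], time = times, hazard = haz, surv = surv,
               cdf = 1 - surv)
  }))
  rownames(out) <- NULL
  attr(out, "extrapolated") <- any(extrapolated)
  out
}
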