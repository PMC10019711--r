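make_records <- function(rt, target, block = 1, subject = "S01",
                         uncertainty = "29", similarity = -80, rate = 1) {
  data.frame(subject = subject, trial_id = seq_along(rt), block = block,
             target_present = target, response_time = rt,
             similarity = similarity, uncertainty = uncertainty, rate = rate)
}

test_that("trial categorization follows the cut-off rules", {
  rec <- make_records(rt = c(500, NA, 5000, 800, NA),
                      target = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cc <- categorize(rec, "I")
  expect_equal(as.character(cc$category),
               c("guess", "miss", "hit", "false_alarm", "correct_rejection"))
  expect_equal(attr(cc, "cutoff"), 1600)

  # Experiment II cut-off admits the same 800 ms response as a hit
  cc2 <- categorize(make_records(800, TRUE), "II")
  expect_equal(as.character(cc2$category), "hit")
  expect_error(categorize(rec, "IV"))

  # hit contributes its time from target onset to the survival data
  sd1 <- surv_data(cc)
  expect_equal(nrow(sd1), 2)  # guess dismissed
  expect_equal(sd1$time[sd1$event == 1], 5000 - 600)
  expect_equal(sd1$time[sd1$event == 0], 11400)
})

test_that("first-block removal is exact and idempotent", {
  sched <- build_schedule("I", 5)
  sched$response_time <- NA
  sched$subject <- "S01"
  n1 <- sum(sched$block == 1)
  out <- drop_first_block(sched)
  expect_equal(nrow(out), 243 - n1)
  expect_true(n1 %in% c(40, 41))
  expect_identical(drop_first_block(out), out)
})

test_that("d-prime uses log-linear edge correction and the normal quantile", {
  counts_rec <- function(hits, n_tgt, fa, n_catch, subject = "S01") {
    data.frame(subject = subject, uncertainty = "29",
               target_present = c(rep(TRUE, n_tgt), rep(FALSE, n_catch)),
               category = c(rep("hit", hits), rep("miss", n_tgt - hits),
                            rep("false_alarm", fa),
                            rep("correct_rejection", n_catch - fa)))
  }
  dp <- dprime_by_uncertainty(counts_rec(84, 100, 16, 100))
  hr <- (84 + 0.5) / 101; far <- (16 + 0.5) / 101
  expect_equal(dp$dprime, qnorm(hr) - qnorm(far))
  expect_equal(dp$dprime, 1.96, tolerance = 0.01)

  # HR = FAR gives zero; swapping hit and false-alarm counts flips the sign
  expect_equal(dprime_by_uncertainty(counts_rec(30, 100, 30, 100))$dprime, 0)
  expect_equal(dprime_by_uncertainty(counts_rec(16, 100, 84, 100))$dprime,
               -dp$dprime)

  # perfect 10/10 hit rate is pulled to 10.5/11
  dp10 <- dprime_by_uncertainty(counts_rec(10, 10, 1, 10))
  expect_equal(dp10$hr, 10.5 / 11)

  # guesses leave both numerator and denominator
  withg <- counts_rec(40, 99, 10, 100)
  withg$category[withg$category == "miss"][1:9] <- "guess"
  dpg <- dprime_by_uncertainty(withg)
  expect_equal(dpg$n_target, 90)
  expect_equal(dpg$hr, 40.5 / 91)
})

test_that("mixed model on d-prime reduces to one-way ANOVA without subject variance", {
  set.seed(77)
  dp <- expand.grid(subject = sprintf("S%02d", 1:12),
                    uncertainty = c("29", "116", "464"))
  e <- rnorm(nrow(dp), sd = 0.3)
  e <- e - stats::ave(e, dp$subject)  # exactly zero between-subject variance
  dp$dprime <- c("29" = 2, "116" = 1.4, "464" = 0.8)[dp$uncertainty] + e
  res <- lmm_dprime(dp)
  f_aov <- summary(stats::aov(dprime ~ uncertainty, dp))[[1]]$`F value`[1]
  expect_equal(res$F, f_aov, tolerance = 0.1)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 22)  # between-within: (12-1)*(3-1)

  # translation invariance
  dp2 <- dp; dp2$dprime <- dp2$dprime + 3
  expect_equal(lmm_dprime(dp2)$F, res$F, tolerance = 1e-6)
})

test_that("product-limit and Nelson-Aalen estimators match hand computation", {
  km <- km_nelson_aalen(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))

  none <- km_nelson_aalen(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none$surv_fun(c(0.5, 2.5, 5)) == 1))

  # five-point fixture with censoring: increments d/n at risk
  na5 <- km_nelson_aalen(c(1, 2, 2, 3, 4), c(1, 0, 1, 1, 0))
  expect_equal(na5$cumhaz_fun(c(1, 2, 3, 4)),
               cumsum(c(1 / 5, 1 / 4, 1 / 2, 0))[c(1, 2, 3, 3)],
               tolerance = 1e-12)
})

test_that("plain Cox coefficients match brute-force partial-likelihood maximization", {
  d <- data.frame(time = c(1.1, 2.3, 3.7, 4.2, 5.9, 7.5),
                  event = c(1, 1, 0, 1, 1, 1),
                  x = c(1, 0, 1, 0, 1, 0),
                  subject = "S01")
  fit <- cox_frailty_fit(d, ~ x, frailty_variance = 0)
  b_oracle <- brute_force_cox1(d$time, d$event, d$x)
  expect_equal(unname(fit$coefficients), b_oracle, tolerance = 1e-5)

  # score of the partial likelihood vanishes at the solution
  eps <- 1e-6
  score <- (breslow_loglik(fit$coefficients + eps, d$time, d$event, d$x) -
            breslow_loglik(fit$coefficients - eps, d$time, d$event, d$x)) /
    (2 * eps)
  expect_lt(abs(score), 1e-4)

  # replication invariance under Breslow ties
  d2 <- rbind(d, d); d2$subject <- "S01"
  fit2 <- cox_frailty_fit(d2, ~ x, frailty_variance = 0)
  expect_equal(unname(fit2$coefficients), unname(fit$coefficients),
               tolerance = 1e-6)
})

test_that("null-model baseline equals the Nelson-Aalen estimator", {
  set.seed(8)
  d <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.8),
                  subject = rep(c("a", "b"), 20))
  fit <- cox_frailty_fit(d, ~ 1, frailty_variance = 0)
  na <- km_nelson_aalen(d$time, d$event)
  expect_equal(fit$basehaz$hazard[fit$basehaz$time %in% na$table$time],
               na$table$cumhaz, tolerance = 1e-10)
  expect_length(fit$coefficients, 0)
  expect_equal(fit$basehaz$hazard, sort(fit$basehaz$hazard))  # non-decreasing
})

test_that("the frailty fit collapses to plain Cox as the variance tends to 0", {
  beta_sim <- c("-80" = 0, "0" = -0.8)
  beta_unc <- c("29" = 0, "464" = -0.5)
  d <- make_ph_data(8, 6, beta_sim, beta_unc, frailty_v = 0.4, seed = 3)
  plain <- cox_frailty_fit(d, ~ similarity + uncertainty,
                           frailty_variance = 0)
  tiny <- cox_frailty_fit(d, ~ similarity + uncertainty,
                          frailty_variance = 1e-8)
  expect_equal(tiny$coefficients, plain$coefficients, tolerance = 1e-4)
  expect_equal(tiny$frailty_variance, 1e-8)
})

test_that("sequential term tests are nested and count contrasts correctly", {
  beta_sim <- c("-80" = 0, "-40" = -0.3, "0" = -0.6, "40" = -0.5,
                "80" = -0.4)
  beta_unc <- c("29" = 0, "116" = -0.3, "464" = -0.8)
  d <- make_ph_data(6, 4, beta_sim, beta_unc, seed = 9)
  an <- anova_effects(d, ~ similarity * uncertainty, frailty = FALSE)
  tab <- an$table
  expect_equal(tab$term,
               c("similarity", "uncertainty", "similarity:uncertainty"))
  # plain Cox: effective df are the contrast counts (3x5 interaction -> 8)
  expect_equal(tab$df, c(4, 2, 8), tolerance = 1e-6)
  expect_true(all(tab$chisq >= 0))
  # adding terms never decreases the penalized log-likelihood
  ll <- vapply(an$nested, `[[`, numeric(1), "penalized_loglik")
  expect_true(all(diff(ll) >= -1e-8))

  # with frailty: the frailty row is first, tested on 1 df
  an_f <- anova_effects(d, ~ similarity + uncertainty, frailty = TRUE)
  expect_equal(an_f$table$term[1], "frailty")
  expect_equal(an_f$table$df[1], 1)
})

test_that("Cox-Snell residuals from a well-specified fit are unit exponential", {
  beta_sim <- c("-80" = 0, "0" = -0.7)
  beta_unc <- c("29" = 0, "464" = -0.6)
  d <- make_ph_data(10, 25, beta_sim, beta_unc, frailty_v = 0.3, seed = 14)
  expect_gte(nrow(d), 1000)
  fit <- cox_frailty_fit(d, ~ similarity + uncertainty)
  cs <- cox_snell(fit)
  expect_true(all(cs$residual >= 0))
  # censored rows carry the cumulative hazard at censoring with flag 0
  expect_true(all(cs$event %in% c(0, 1)))
  na <- km_nelson_aalen(pmax(cs$residual, 1e-12), cs$event)
  slope <- stats::coef(stats::lm(cumhaz ~ 0 + time, na$table))
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("predicted curves satisfy CDF axioms and proportional hazards", {
  beta_sim <- c("-80" = 0, "0" = -0.7)
  beta_unc <- c("29" = 0, "464" = -0.6)
  d <- make_ph_data(6, 12, beta_sim, beta_unc, seed = 15)
  fit <- cox_frailty_fit(d, ~ similarity + uncertainty,
                         frailty_variance = 0)
  nd <- expand.grid(similarity = c("-80", "0"), uncertainty = c("29", "464"))
  cur <- predict_curves(fit, nd, times = seq(0, 9, by = 0.05),
                        marginal = FALSE)
  for (cl in unique(cur$cell)) {
    f <- cur$cdf[cur$cell == cl]
    expect_equal(f[1], 0, tolerance = 1e-9)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f <= 1 + 1e-12))
  }
  # conditional hazards scale exactly with exp(x'b)
  h_ref <- cur$hazard[cur$cell == "-80:29"]
  h_alt <- cur$hazard[cur$cell == "0:29"]
  ratio <- exp(unname(fit$coefficients["similarity0"]))
  expect_equal(h_alt, h_ref * ratio, tolerance = 1e-9)
})

test_that("smoothed hazard of exponential data under the null model is flat", {
  set.seed(16)
  rho <- 1
  d <- data.frame(time = rexp(5000, rho), event = 1, subject = "S01")
  d$event[d$time > 3] <- 0
  d$time <- pmin(d$time, 3)
  fit <- cox_frailty_fit(d, ~ 1, frailty_variance = 0)
  cur <- predict_curves(fit, data.frame(x = 1), times = seq(0.5, 2, by = 0.1),
                        marginal = FALSE)
  # interior of the time range, away from kernel boundary bias
  expect_true(all(abs(cur$hazard - rho) / rho < 0.15))
})

test_that("high-FAR subjects are flagged by the two-sigma rule", {
  set.seed(17)
  rec <- do.call(rbind, lapply(1:8, function(s) {
    fa <- if (s == 8) 35 else rbinom(1, 40, 0.1)
    data.frame(subject = sprintf("S%02d", s),
               target_present = c(rep(TRUE, 60), rep(FALSE, 40)),
               category = c(rep("hit", 60), rep("false_alarm", fa),
                            rep("correct_rejection", 40 - fa)))
  }))
  expect_equal(flag_far_outliers(rec), "S08")
})
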