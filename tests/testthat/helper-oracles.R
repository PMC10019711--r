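# Independent oracles used across tests.

# Breslow-ties Cox partial log-likelihood, written straight from the
# definition: each event contributes lp_i - log(sum of exp(lp) over the risk
# set at its time).
breslow_loglik <- function(beta, time, event, x) {
  x <- as.matrix(x)
  lp <- drop(x %*% beta)
  sum(vapply(which(event == 1), function(i) {
    lp[i] - log(sum(exp(lp[time >= time[i]])))
  }, numeric(1)))
}

# Brute-force maximiser for a single covariate: dense grid then local
# refinement. Independent of coxph.
brute_force_cox1 <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  interval = c(b0 - 0.02, b0 + 0.02), maximum = TRUE,
                  tol = 1e-12)$maximum
}

# Maximal cliques of an undirected graph (adjacency matrix, no self loops)
# by plain Bron-Kerbosch. Small k only.
max_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      out[[length(out) + 1]] <<- sort(r)
      return()
    }
    for (v in p) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

# Random EMM-like fixture: k cell means with a random positive-definite
# covariance, wrapped in the emm_lh class tukey_cld() expects.
make_emm_fixture <- function(k, seed, spread = 1) {
  set.seed(seed)
  a <- matrix(rnorm(k * k, sd = 0.3), k)
  V <- a %*% t(a) + diag(0.05, k)
  structure(list(grid = data.frame(cell = paste0("c", seq_len(k))),
                 emmean = rnorm(k, sd = spread),
                 se = sqrt(diag(V)), vcov = V,
                 L = diag(k)),
            class = "emm_lh")
}

# Small survival dataset from a plain exponential PH model with a factor
# covariate; used by several fitting tests.
make_ph_data <- function(n_subj, trials_per_cell, beta_sim, beta_unc,
                         frailty_v = 0, rate0 = 0.3, censor = 10,
                         seed = 1) {
  set.seed(seed)
  sim_lev <- names(beta_sim)
  unc_lev <- names(beta_unc)
  grid <- expand.grid(similarity = sim_lev, uncertainty = unc_lev,
                      stringsAsFactors = FALSE)
  d <- grid[rep(seq_len(nrow(grid)), each = n_subj * trials_per_cell), ]
  d$subject <- rep(rep(sprintf("S%02d", seq_len(n_subj)),
                       each = trials_per_cell), nrow(grid))
  w <- if (frailty_v > 0)
    stats::setNames(sample_frailty(n_subj, frailty_v),
                    sprintf("S%02d", seq_len(n_subj)))
  else stats::setNames(rep(1, n_subj), sprintf("S%02d", seq_len(n_subj)))
  lp <- beta_sim[d$similarity] + beta_unc[d$uncertainty]
  t <- stats::rexp(nrow(d), rate = rate0 * w[d$subject] * exp(lp))
  d$event <- as.integer(t <= censor)
  d$time <- pmin(t, censor)
  d$similarity <- factor(d$similarity, levels = sim_lev)
  d$uncertainty <- factor(d$uncertainty, levels = unc_lev)
  d$subject <- factor(d$subject)
  d
}
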