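#' Estimated marginal means on the log-hazard scale
#'
#' Model-based cell means of the linear predictor: for each cell of the
#' requested factor grid, the mean of `x'b` averaged with equal weights over
#' the levels of any remaining model factors (the balanced reference grid).
#' Standard errors come from the delta method on the coefficient covariance.
#' Under treatment contrasts the reference cell sits exactly at 0 with SE 0,
#' matching the parameterisation of the condition tables.
#'
#' @param fit A [cox_frailty_fit()].
#' @param specs Character vector of factor names defining the grid; defaults
#'   to every factor in the fixed-effect formula (the full interaction grid).
#' @return An `emm_lh` list: `grid` (factor levels), `emmean`, `se`, the full
#'   covariance `vcov` of the cell means, and the linear map `L`.
#' @export
emmeans_log_hazard <- function(fit, specs = NULL) {
  stopifnot(inherits(fit, "frailty_fit"))
  facs <- fit$xlevels
  if (!length(facs)) {
    grid <- data.frame(.cell = "(all)")
    L <- matrix(0, 1, 0)
    return(structure(list(grid = grid, emmean = 0, se = 0,
                          vcov = matrix(0, 1, 1), L = L), class = "emm_lh"))
  }
  if (is.null(specs)) specs <- names(facs)
  if (!all(specs %in% names(facs))) stop("unknown factor in specs")
  ref_grid <- expand.grid(facs, stringsAsFactors = TRUE)
  mm <- stats::model.matrix(fit$fixed, ref_grid, xlev = facs)
  mm <- mm[, names(fit$coefficients), drop = FALSE]

  grid <- expand.grid(facs[specs], stringsAsFactors = TRUE)
  key_ref <- interaction(ref_grid[specs], drop = FALSE)
  key_grid <- interaction(grid, drop = FALSE)
  L <- t(vapply(seq_len(nrow(grid)), function(i) {
    rows <- key_ref == key_grid[i]
    if (!any(rows)) stop("empty cell in reference grid: ", key_grid[i])
    colMeans(mm[rows, , drop = FALSE])
  }, numeric(ncol(mm))))
  colnames(L) <- names(fit$coefficients)

  est <- drop(L %*% fit$coefficients)
  V <- L %*% fit$vcov %*% t(L)
  structure(list(grid = grid, emmean = est, se = sqrt(pmax(0, diag(V))),
                 vcov = V, L = L), class = "emm_lh")
}

#' @export
print.emm_lh <- function(x, ...) {
  print(cbind(x$grid, emmean = x$emmean, se = x$se))
  invisible(x)
}

# insert-and-absorb letter assignment from a k x k logical matrix of
# significant differences (Piepho-style compact letter display)
cld_from_significance <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    hit <- vapply(cols, function(s) i %in% s && j %in% s, logical(1))
    if (!any(hit)) next
    for (idx in which(hit)) {
      s <- cols[[idx]]
      cols[[idx]] <- setdiff(s, i)
      cols <- c(cols, list(setdiff(s, j)))
    }
    # absorb: drop any column contained in another
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && !drop[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b))
        drop[a] <- TRUE
    }
    cols <- cols[!drop]
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  alphabet <- c(letters, LETTERS)
  vapply(seq_len(k), function(i) {
    paste(alphabet[which(vapply(cols, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Tukey-adjusted all-pairwise comparisons with compact letter display
#'
#' All pairwise contrasts of estimated marginal means, with p-values adjusted
#' by the studentized-range (Tukey) method for a family of `k` estimates
#' (asymptotic: `df = Inf`), and letters assigned by the insert-and-absorb
#' algorithm. Cells sharing a letter are not significantly different at
#' `alpha`; cells sharing no letter are.
#'
#' @param emm An [emmeans_log_hazard()] grid.
#' @param alpha Significance level for grouping.
#' @return List with `contrasts` (pairs, estimate, SE, z, adjusted p),
#'   `letters` (per cell, aligned with `emm$grid`), `summary` (grid, emmean,
#'   SE, 95% asymptotic limits, group letters, sorted by emmean), and
#'   `alpha`.
#' @export
tukey_cld <- function(emm, alpha = 0.05) {
  stopifnot(inherits(emm, "emm_lh"))
  k <- length(emm$emmean)
  if (k < 2) stop("need at least 2 cells to compare")
  pairs <- utils::combn(k, 2)
  est <- emm$emmean[pairs[1, ]] - emm$emmean[pairs[2, ]]
  se <- sqrt(pmax(0, emm$vcov[cbind(pairs[1, ], pairs[1, ])] +
                     emm$vcov[cbind(pairs[2, ], pairs[2, ])] -
                     2 * emm$vcov[cbind(pairs[1, ], pairs[2, ])]))
  z <- ifelse(se > 0, est / se, 0)
  p_adj <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                         lower.tail = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[t(pairs)] <- p_adj < alpha
  sig <- sig | t(sig)
  letters_vec <- cld_from_significance(sig)

  cell_label <- function(i) paste(unlist(emm$grid[i, , drop = TRUE]),
                                  collapse = ":")
  contrasts <- data.frame(
    cell1 = vapply(pairs[1, ], cell_label, character(1)),
    cell2 = vapply(pairs[2, ], cell_label, character(1)),
    estimate = est, se = se, z = z, p_adj = p_adj)

  summary <- cbind(emm$grid,
                   emmean = emm$emmean, se = emm$se,
                   asymp_lcl = emm$emmean - stats::qnorm(0.975) * emm$se,
                   asymp_ucl = emm$emmean + stats::qnorm(0.975) * emm$se,
                   group = letters_vec)
  summary <- summary[order(summary$emmean), ]
  list(contrasts = contrasts, letters = letters_vec, summary = summary,
       alpha = alpha)
}
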