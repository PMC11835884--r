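# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (dense matrices, explicit
# enumeration) and must stay free of the package's own computational paths.

# Gaussian log-density of y ~ N(X beta, Sigma) via dense Cholesky
brute_mvn_loglik <- function(y, mean, Sigma) {
  ch <- chol(Sigma)                       # Sigma = U'U
  z <- forwardsolve(t(ch), y - mean)      # z = U'^-1 r, so |z|^2 = r' Sigma^-1 r
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# dense covariance of one tree's rows: sigma2 * (AR1-by-branch + lambda * J)
brute_tree_cov <- function(branch, year, sigma2, sigma_u2, rho) {
  n <- length(year)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (branch[i] == branch[j]) R[i, j] <- rho^abs(year[i] - year[j])
    }
  }
  sigma2 * R + sigma_u2
}

# direct-summation competition indices (paper-literal reference area)
brute_competition <- function(subject_dbh, comp_dbh, comp_dist, radius,
                              s_convention = "diameter") {
  ci <- 0
  bas <- 0
  bal <- 0
  s <- if (s_convention == "diameter") pi / 4 * radius^2 else pi * radius^2
  for (j in seq_along(comp_dbh)) {
    ci <- ci + (comp_dbh[j] / subject_dbh) / comp_dist[j]
    ba_j <- pi / 4 * (comp_dbh[j] / 100)^2 * 1e4 / s
    bas <- bas + ba_j
    if (comp_dbh[j] > subject_dbh) bal <- bal + ba_j
  }
  c(ci = ci, bas = bas, bal = bal)
}

# all-orders hierarchical partitioning: average R2 increments over every
# permutation of the groups (feasible for <= 5 groups)
brute_hp <- function(frame, groups) {
  g <- length(groups)
  y <- frame$log_inc
  r2_of <- function(terms) {
    if (!length(terms)) return(0)
    X <- branchgrowth:::.design_matrix(frame, terms)
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- .permutations(g)
  indep <- numeric(g)
  for (p in seq_len(nrow(perms))) {
    terms_in <- character(0)
    r2_prev <- 0
    for (k in perms[p, ]) {
      terms_in <- c(terms_in, groups[[k]])
      r2_now <- r2_of(terms_in)
      indep[k] <- indep[k] + (r2_now - r2_prev)
      r2_prev <- r2_now
    }
  }
  indep / nrow(perms)
}

.permutations <- function(g) {
  if (g == 1) return(matrix(1))
  sub <- .permutations(g - 1)
  out <- NULL
  for (k in seq_len(g)) {
    block <- cbind(k, matrix(setdiff(seq_len(g), k)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# cumulative-basal-area social classification by direct arithmetic
brute_status <- function(dbh) {
  o <- order(dbh, decreasing = TRUE)
  ba <- pi / 4 * dbh[o]^2
  cum <- cumsum(ba)
  lab <- character(length(dbh))
  for (i in seq_along(o)) {
    midpoint <- cum[i] - ba[i] / 2
    iv <- ceiling(5 * midpoint / cum[length(cum)])
    lab[o[i]] <- switch(iv, "dominant", "unassigned", "intermediate",
                        "unassigned", "suppressed")
  }
  lab
}

# small hand-built stand object (positions/dbh given per plot)
make_stand <- function(trees, radius = 8, years = 2000:2005,
                       felling_year = max(years) + 1L) {
  cfg <- stand_config(n_plots = length(unique(trees$plot_id)),
                      targets_per_plot = 1, trees_per_plot = 5,
                      competition_radius = radius,
                      years = years, felling_year = felling_year)
  plots <- data.frame(plot_id = unique(trees$plot_id), area_ha = 0.06,
                      radius_m = radius, side_m = cfg$side_m)
  structure(list(plots = plots, trees = trees, config = cfg, seed = 0L),
            class = "bg_stand")
}

# constant-diameter chronology for hand stands
flat_chronology <- function(trees, years, dbh = NULL) {
  do.call(rbind, lapply(seq_len(nrow(trees)), function(i) {
    data.frame(tree_id = trees$tree_id[i], year = years,
               dbh0_cm = if (is.null(dbh)) trees$dbh_felling_cm[i] else
                 dbh[i])
  }))
}

# a fitted-model shell with known parameters (for predict/scenario oracles)
manual_model <- function(beta, sigma2, sigma_u2 = 0, rho = 0,
                         response = "length",
                         terms = c("age", "size", "bh", "dheight", "bas",
                                   "climate", "bas:climate")) {
  structure(
    list(design = growth_design(response, terms = terms),
         estimation = "manual", coefficients = beta,
         se = beta * NA, sigma2 = sigma2, sigma_u2 = sigma_u2, rho = rho,
         ar1 = rho != 0, loglik = NA_real_, aic = NA_real_,
         n_obs = NA_integer_, n_groups = NA_integer_,
         p = length(beta), k = length(beta) + 1,
         converged = TRUE, boundary = FALSE, ranef = NULL,
         grouping = "tree_id", frame_means = NULL, fitted = NULL),
    class = "growth_model"
  )
}
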