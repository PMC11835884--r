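test_that("metric suite matches the hand-computed three-point fixture", {
  m <- compute_metrics(c(10, 20, 30), c(12, 18, 33), p = 0)
  expect_equal(m$me, -1)
  expect_equal(m$mae, 7 / 3)
  expect_equal(m$rmse, sqrt(17 / 2))
  expect_equal(m$r2, 1 - 17 / 200)
  expect_equal(m$mpe_percent, -5)
  expect_equal(m$mape_percent, 100 * (0.2 + 0.1 + 0.1) / 3)
  expect_equal(m$fi, m$r2)          # Eq. identity: FI == R2
  expect_gte(m$mae, abs(m$me))

  perfect <- compute_metrics(1:5, 1:5, p = 0)
  expect_equal(perfect$me, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$fi, 1)

  null_model <- compute_metrics(c(1, 2, 3, 6), rep(3, 4), p = 0)
  expect_equal(null_model$r2, 0)

  expect_error(compute_metrics(1:3, 1:3, p = 2), "n > p")
  expect_warning(compute_metrics(c(0, 1, 2), c(0.1, 1, 2), p = 0), "zero")
  withit <- compute_metrics(1:4, 2:5, p = 0, loglik = -10)
  expect_equal(withit$aic, 20)
})

test_that("leave-one-tree-out: fold accounting and the noise-free limit", {
  p <- reference_params("length", "basic")
  fr <- simulate_replicate_frame(p, n_trees = 12, branches_per_tree = 4,
                                 series_years = 4:5, seed = 41)
  d <- growth_design("length")
  cv <- loocv(fr, d)
  expect_equal(cv$n_folds, 12)
  expect_equal(nrow(cv$predictions), nrow(fr))

  p0 <- reference_params("length", "basic")
  p0$sigma2 <- 0
  fr0 <- simulate_replicate_frame(p0, n_trees = 6, branches_per_tree = 4,
                                  series_years = 4:5, seed = 43)
  cv0 <- loocv(fr0, d)
  expect_lt(cv0$metrics_log$mae, 1e-8)

  expect_error(loocv(fr[fr$tree_id %in% c("T001", "T002"), ], d), ">= 3")
})

test_that("holdout error exceeds in-sample error in expectation", {
  p <- reference_params("length", "basic")
  d <- growth_design("length")
  gap <- numeric(20)
  for (s in 1:20) {
    fr <- simulate_replicate_frame(p, n_trees = 8, branches_per_tree = 3,
                                   series_years = 3:4, seed = 500 + s)
    fit <- fit_ols(fr, d)
    in_mae <- mean(abs(fr$log_inc - fit$fitted))
    cv <- loocv(fr, d)
    gap[s] <- cv$metrics_log$mae - in_mae
  }
  expect_gt(mean(gap), 0)
})

test_that("forward selection finds signal and respects the null", {
  # one true predictor (age) among pure-noise candidates. With an exact
  # alpha = 0.05 entry test per step, a noise candidate sneaks in after the
  # true one with probability 1 - 0.95^4 ~ 0.19, so "exactly the true
  # predictor" is expected in ~81/100 runs; the true predictor itself must
  # always be found.
  exact <- 0
  found <- 0
  for (s in 1:100) {
    set.seed(700 + s)
    n <- 1000
    fr <- data.frame(age = stats::rnorm(n), size = stats::rnorm(n),
                     bh = stats::rnorm(n), dheight = stats::rnorm(n),
                     bas = stats::rnorm(n),
                     log_inc = NA)
    fr$log_inc <- 1 + 0.5 * fr$age + stats::rnorm(n)
    sel <- forward_select(fr, candidates = c("age", "size", "bh",
                                             "dheight", "bas"))
    if (identical(sel$terms, "age")) exact <- exact + 1
    if (sel$terms[1] == "age") found <- found + 1
  }
  expect_equal(found, 100)
  expect_gte(exact, 70)

  # all-noise null: with two candidates at alpha = 0.05 per step the
  # no-entry probability is 0.95^2 ~ 0.90
  none <- 0
  for (s in 1:100) {
    set.seed(900 + s)
    n <- 1000
    fr <- data.frame(age = stats::rnorm(n), size = stats::rnorm(n),
                     log_inc = stats::rnorm(n))
    sel <- forward_select(fr, candidates = c("age", "size"))
    if (length(sel$terms) == 0) none <- none + 1
  }
  expect_gte(none, 85)

  # a duplicated candidate is barred as collinear once its twin is in
  set.seed(77)
  fr <- data.frame(age = stats::rnorm(200), log_inc = NA)
  fr$size <- fr$age
  fr$log_inc <- 2 * fr$age + stats::rnorm(200, 0, 0.5)
  sel <- forward_select(fr, candidates = c("age", "size"))
  expect_equal(length(sel$terms), 1)
  expect_true(any(grepl("singular", sel$trace$action)))

  # interaction hierarchy is never violated
  p <- reference_params("length", "mixed")
  frh <- simulate_replicate_frame(p, n_trees = 10, branches_per_tree = 5,
                                  series_years = 4:6, seed = 45)
  selh <- forward_select(frh)
  if ("bas:climate" %in% selh$terms) {
    expect_true(all(c("bas", "climate") %in% selh$terms))
  }
})

test_that("climate lag selection recovers a lag-1 signal and breaks ties", {
  d <- growth_design("length", terms = c("age", "climate"))
  make_builder <- function(clim_series, y_from_lag, noise_sd, seed) {
    # one plot, 30 years; y in year t responds to climate at t - y_from_lag
    function(lag) {
      set.seed(seed)
      yrs <- 11:40
      clim_t <- clim_series[yrs - lag]
      clim_y <- clim_series[yrs - y_from_lag]
      age <- stats::runif(30, 1, 30)
      data.frame(tree_id = rep(c("a", "b"), 15), branch_id = "b1",
                 year = yrs, age = age, climate = clim_t,
                 log_inc = 1 + 0.05 * age - 0.05 * clim_y +
                   stats::rnorm(30, 0, noise_sd))
    }
  }
  hits <- 0
  for (s in 1:50) {
    set.seed(1200 + s)
    clim <- stats::runif(40, 20, 100)
    res <- lag_select(make_builder(clim, y_from_lag = 1, noise_sd = 0.3,
                                   seed = 1200 + s), d)
    if (res$lag == 1) hits <- hits + 1
  }
  expect_gte(hits, 45)

  # (near-)constant climate: all lags tie, the smallest is returned. (An
  # exactly constant column would be collinear with the intercept and is a
  # singular-design error by contract.)
  res0 <- lag_select(make_builder(50 + 0.01 * (1:40), y_from_lag = 0,
                                  noise_sd = 0.1, seed = 3), d, tol = 1e-6)
  expect_equal(res0$lag, 0)
  expect_equal(nrow(res0$table), 3)
  expect_lt(diff(range(res0$table$aic)), 1e-6)

  # a builder that cannot support lag 2 yields a 2-row table and a warning
  short_builder <- function(lag) {
    if (lag >= 2) stop("series too short")
    make_builder(stats::runif(40, 20, 100), 0, 0.3, 11)(lag)
  }
  expect_warning(res_s <- lag_select(short_builder, d), "skipped")
  expect_equal(nrow(res_s$table), 2)
})

test_that("hierarchical partitioning: exactness, orthogonality, brute force", {
  p <- reference_params("length", "mixed")
  fr <- simulate_replicate_frame(p, n_trees = 10, branches_per_tree = 5,
                                 series_years = 4:6, seed = 47)

  # single group captures the full R2
  hp1 <- hierarchical_partition(fr, list(all = c("age", "size")))
  expect_equal(hp1$independent_pct, 100, tolerance = 1e-10)

  # independent contributions always sum to the full R2
  groups <- default_hp_groups()
  hp <- hierarchical_partition(fr, groups)
  X <- branchgrowth:::.design_matrix(fr, unlist(groups, use.names = FALSE))
  full <- stats::lm.fit(X, fr$log_inc)
  full_r2 <- 1 - sum(full$residuals^2) /
    sum((fr$log_inc - mean(fr$log_inc))^2)
  expect_equal(sum(hp$independent), full_r2, tolerance = 1e-8)
  expect_equal(attr(hp, "full_r2"), full_r2, tolerance = 1e-10)

  # orthogonal groups: independent equals marginal exactly
  n <- 64
  fro <- data.frame(age = rep(c(-1, 1), each = 32),
                    size = rep(c(-1, 1), times = 32))
  set.seed(48)
  fro$log_inc <- fro$age + 0.5 * fro$size + stats::rnorm(n, 0, 0.7)
  hpo <- hierarchical_partition(fro, list(a = "age", b = "size"))
  expect_equal(hpo$independent, hpo$marginal, tolerance = 1e-10)
  expect_equal(hpo$joint, c(0, 0), tolerance = 1e-10)

  # subset-lattice computation agrees with all-orders enumeration (g <= 5)
  g5 <- list(a = "age", b = "size", c = "bh", d = "dheight",
             e = c("bas", "climate"))
  hp5 <- hierarchical_partition(fr, g5)
  expect_equal(hp5$independent, brute_hp(fr, g5), tolerance = 1e-8)

  expect_error(
    hierarchical_partition(fr, stats::setNames(as.list(rep("age", 13)),
                                               paste0("g", 1:13))),
    "12 groups")

  # on data generated from the published length model with observed-range
  # covariates, branch age carries the largest independent share
  frq <- simulate_replicate_frame(reference_params("length", "basic"),
                                  n_trees = 54, seed = 49)
  hpq <- hierarchical_partition(frq, default_hp_groups())
  expect_equal(hpq$group[which.max(hpq$independent)], "branch age")
})

test_that("social status classification: hand case, ties, invariances", {
  # 6 trees, DBH 40,35,30,25,20,10: cumulative basal-area midpoints fall at
  # 16.5%, 45.6%, 67.5%, 83.3%, 93.8%, 99.0% -> intervals 1,3,4,5,5,5
  lab <- classify_social_status(c(40, 35, 30, 25, 20, 10))
  expect_equal(unname(lab),
               c("dominant", "intermediate", "unassigned",
                 "suppressed", "suppressed", "suppressed"))

  # order preservation within a plot
  set.seed(51)
  for (i in 1:10) {
    dbh <- stats::runif(sample(5:20, 1), 5, 45)
    l <- classify_social_status(dbh)
    if (any(l == "dominant") && any(l == "suppressed")) {
      expect_gte(min(dbh[l == "dominant"]), max(dbh[l == "suppressed"]))
    }
    expect_equal(unname(l), brute_status(dbh))
    # invariance to ordering and uniform rescaling
    o <- sample(length(dbh))
    expect_equal(unname(l)[o], unname(classify_social_status(dbh[o])))
    expect_equal(unname(l), unname(classify_social_status(dbh * 2.7)))
  }

  # equal diameters: the boundary rule alone decides; oracle agrees
  expect_equal(unname(classify_social_status(rep(25, 10))),
               brute_status(rep(25, 10)))

  expect_warning(l4 <- classify_social_status(c(30, 20, 10, 5)), "fewer")
  expect_true(all(l4 == "unassigned"))
})

test_that("calibration experiment: definitional k = 0 and BLUP shrinkage", {
  p <- reference_params("length", "mixed")   # sigma_u2 >> 0
  fr <- simulate_replicate_frame(p, n_trees = 12, branches_per_tree = 6,
                                 series_years = 4:5, seed = 53)
  d <- growth_design("length")
  model <- fit_mixed(fr, d)
  cc <- calibration_experiment(fr, d, k_values = 0:4, replicates = 50,
                               seed = 7, model = model)
  # k = 0 is the fixed-effects MAE on the full frame
  pred0 <- predict(model, fr, back_transform = TRUE)
  expect_equal(cc$mae_mean[cc$k == 0], mean(abs(fr$inc_natural - pred0)),
               tolerance = 1e-10)
  expect_equal(cc$mae_sd[cc$k == 0], 0)
  # calibrated beats uncalibrated at every k >= 1, and MAE does not increase
  expect_true(all(cc$mae_mean[cc$k >= 1] < cc$mae_mean[cc$k == 0]))
  # non-increasing in expectation: allow the Monte-Carlo standard error of
  # the replicate means on each pairwise difference
  se_pair <- sqrt(cc$mae_sd[-1]^2 + cc$mae_sd[-nrow(cc)]^2) /
    sqrt(cc$replicates[1])
  expect_true(all(diff(cc$mae_mean) < 2 * se_pair + 1e-9))
})
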