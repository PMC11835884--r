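# small reusable frame from the replicate generator
small_frame <- function(params, n_trees = 8, branches = 4, years = 4:6,
                        seed = 1) {
  simulate_replicate_frame(params, n_trees = n_trees,
                           branches_per_tree = branches,
                           series_years = years, seed = seed)
}

test_that("frame assembly: lags, non-positive increments, size convention", {
  cfg <- stand_config(n_plots = 2, years = 2014:2022)
  st <- run_pipeline(list(stand = cfg),
                     stages = c("simulate", "reconstruct", "compete"),
                     out_dir = tempfile(), seed = 5)
  d0 <- growth_design("length", climate_lag = 0)
  fr0 <- build_design(st$branches, st$chronology, st$competition,
                      st$climate, d0, tree_plot = st$stand$trees)
  expect_equal(nrow(fr0), nrow(st$branches))
  expect_equal(attr(fr0, "n_dropped"), 0)
  # cumulative-size covariate enters the year (metres for the length model)
  expect_equal(fr0$size,
               (st$branches$bl_cm - st$branches$dbl_cm) / 100)
  expect_true(all(fr0$size[fr0$age == 1] == 0))

  # the climate table starts 36 years before felling, so small lags still
  # resolve; a huge artificial lag cannot
  d2 <- growth_design("length", climate_lag = 2)
  fr2 <- build_design(st$branches, st$chronology, st$competition,
                      st$climate, d2, tree_plot = st$stand$trees)
  expect_equal(nrow(fr2), nrow(st$branches))
  clim_cut <- st$climate[st$climate$year >= 2014, ]
  fr2b <- build_design(st$branches, st$chronology, st$competition,
                       clim_cut, d2, tree_plot = st$stand$trees)
  expect_equal(sort(unique(fr2b$year)), 2016:2022)

  br_bad <- st$branches
  br_bad$dbl_cm[1] <- 0
  expect_warning(
    fr_bad <- build_design(br_bad, st$chronology, st$competition,
                           st$climate, d0, tree_plot = st$stand$trees),
    "non-positive")
  expect_equal(nrow(fr_bad), nrow(st$branches) - 1)

  expect_error(growth_design("length", terms = c("age", "bas:climate")),
               "both main effects")
})

test_that("OLS: exact interpolation, inference shapes, singularity", {
  p <- reference_params("length", "basic")
  p$sigma2 <- 0
  fr <- small_frame(p)
  d <- growth_design("length")
  m <- fit_ols(fr, d)
  expect_equal(unname(m$coefficients), unname(p$fixed), tolerance = 1e-8)
  expect_equal(m$k, 9)
  expect_equal(m$aic, -2 * m$loglik + 2 * 9)

  fr$size <- fr$age  # duplicated information
  expect_error(fit_ols(fr, d), "collinear")
})

test_that("balanced one-way REML equals the closed-form ANOVA estimator", {
  set.seed(31)
  g <- 20; m <- 5
  u <- stats::rnorm(g, 0, sqrt(2))
  fr <- data.frame(tree_id = rep(sprintf("T%02d", 1:g), each = m),
                   branch_id = rep(sprintf("T%02d_B1", 1:g), each = m),
                   year = rep(2001:(2000 + m), times = g),
                   log_inc = rep(u, each = m) + stats::rnorm(g * m, 0, 1))
  d <- growth_design("length", terms = character(0))  # intercept only
  fit <- fit_mixed(fr, d, estimation = "REML")
  ybar_g <- tapply(fr$log_inc, fr$tree_id, mean)
  msb <- m * stats::var(ybar_g)
  msw <- sum((fr$log_inc - rep(ybar_g, each = m))^2) / (g * (m - 1))
  expect_equal(fit$sigma_u2, max(0, (msb - msw) / m), tolerance = 1e-5)
  expect_equal(fit$sigma2, msw, tolerance = 1e-5)
})

test_that("degenerate variance: sigma_u2 ~ 0 when no tree effect exists", {
  p <- reference_params("length", "basic")   # sigma_u2 = 0
  fr <- small_frame(p, n_trees = 40, branches = 6, years = 6:8, seed = 13)
  fit <- fit_mixed(fr, growth_design("length"))
  expect_lt(fit$sigma_u2, 0.01 * fit$sigma2)
})

test_that("ML deviances nest: mixed model never fits worse than OLS", {
  p <- reference_params("length", "mixed")
  fr <- small_frame(p, seed = 17)
  d <- growth_design("length")
  ols <- fit_ols(fr, d)
  mx <- fit_mixed(fr, d, estimation = "ML")
  expect_gte(mx$loglik, ols$loglik - 1e-6)
})

test_that("the AR(1) objective at rho = 0 collapses to the iid objective", {
  p <- reference_params("length", "mixed")
  fr <- small_frame(p, seed = 19)
  X <- branchgrowth:::.design_matrix(fr, growth_design("length")$terms)
  prep <- branchgrowth:::.mixed_prepare(fr, X, fr$log_inc, "tree_id")
  for (lam in c(0.1, 0.7, 3)) {
    expect_equal(
      branchgrowth:::.mixed_nll(c(log(lam), atanh(0)), prep,
                                nrow(fr), ncol(X), TRUE, TRUE),
      branchgrowth:::.mixed_nll(log(lam), prep, nrow(fr), ncol(X), TRUE,
                                FALSE),
      tolerance = 1e-10)
  }
})

test_that("analytic ML log-likelihood equals a dense MVN evaluation", {
  p <- reference_params("length", "mixed")
  p$rho <- 0.35
  fr <- small_frame(p, n_trees = 4, branches = 3, years = 4:6, seed = 23)
  d <- growth_design("length")
  fit <- fit_mixed(fr, d, ar1 = TRUE, estimation = "ML")
  X <- branchgrowth:::.design_matrix(fr, d$terms)
  mu <- as.numeric(X %*% fit$coefficients)
  ll <- 0
  for (id in unique(fr$tree_id)) {
    ii <- fr$tree_id == id
    Sig <- brute_tree_cov(fr$branch_id[ii], fr$year[ii],
                          fit$sigma2, fit$sigma_u2, fit$rho)
    ll <- ll + brute_mvn_loglik(fr$log_inc[ii], mu[ii], Sig)
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("REML fit agrees with lme4 on a random-intercept model", {
  p <- reference_params("diameter", "mixed")
  fr <- small_frame(p, n_trees = 15, branches = 5, years = 5:7, seed = 29)
  d <- growth_design("diameter")
  fit <- fit_mixed(fr, d, estimation = "REML")
  fr$bc <- fr$bas * fr$climate
  lm4 <- suppressWarnings(lme4::lmer(
    log_inc ~ age + size + bh + dheight + bas + climate + bc + (1 | tree_id),
    data = fr, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$sigma_u2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(lm4)),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-6)
})

test_that("BLUP calibration follows the closed-form shrinkage", {
  beta <- reference_params("length", "mixed")$fixed
  mod <- manual_model(stats::setNames(
    beta, c("(Intercept)", "age", "size", "bh", "dheight", "bas", "climate",
            "bas:climate")),
    sigma2 = 0.2, sigma_u2 = 0.4)
  nd <- data.frame(tree_id = "T1", branch_id = "T1_B9", year = 2020,
                   age = 5, size = 1.5, bh = 12, dheight = 0.3, bas = 25,
                   climate = 60)
  base <- predict(mod, nd)
  # no calibration: population prediction
  expect_equal(predict(mod, nd, calibration = NULL), base)
  # one pair: u_hat = sigma_u2 / (sigma_u2 + sigma2) * r
  cal <- nd
  cal$log_inc <- base + 0.9
  expect_equal(predict(mod, nd, calibration = cal),
               base + 0.4 / 0.6 * 0.9, tolerance = 1e-12)
  # m independent pairs shrink with m sigma_u2 / (m sigma_u2 + sigma2)
  cal5 <- cal[rep(1, 5), ]
  cal5$branch_id <- paste0("B", 1:5)
  cal5$year <- 2011:2015
  expect_equal(predict(mod, nd, calibration = cal5),
               base + 5 * 0.4 / (5 * 0.4 + 0.2) * 0.9, tolerance = 1e-12)
  # sigma_u2 = 0: calibration is inert
  mod0 <- manual_model(mod$coefficients, sigma2 = 0.2, sigma_u2 = 0)
  expect_equal(predict(mod0, nd, calibration = cal), base)
  # unknown tree in the calibration set
  cal_bad <- cal
  cal_bad$tree_id <- "ghost"
  expect_error(predict(mod, nd, calibration = cal_bad), "ghost")
  # back-transformation, with and without the lognormal correction
  expect_equal(predict(mod, nd, back_transform = TRUE), exp(base))
  expect_equal(predict(mod, nd, back_transform = TRUE, smearing = TRUE),
               exp(base) * exp(0.1))
})

test_that("parameter recovery across replicates stays within 3 MC errors", {
  p <- reference_params("diameter", "basic")
  d <- growth_design("diameter")
  n_rep <- 30
  est <- matrix(NA_real_, n_rep, 8)
  for (r in seq_len(n_rep)) {
    fr <- simulate_replicate_frame(p, n_trees = 20, branches_per_tree = 6,
                                   series_years = 5:7, seed = 100 + r)
    est[r, ] <- fit_ols(fr, d)$coefficients
  }
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(est) - p$fixed) < 3 * mc_se + 1e-10))
})

test_that("scenario curves order by the interaction threshold and grid corner", {
  # with the published basic length coefficients the BAS slope
  # a5 + a7 * CMD is negative below CMD = 0.009738 / 5.033e-5 ~ 193.5 mm
  p <- reference_params("length", "basic")
  expect_lt(-p$fixed[["a5"]] / p$fixed[["a7"]], 194)
  expect_gt(-p$fixed[["a5"]] / p$fixed[["a7"]], 193)
  mod <- manual_model(stats::setNames(
    p$fixed, c("(Intercept)", "age", "size", "bh", "dheight", "bas",
               "climate", "bas:climate")), sigma2 = p$sigma2)
  fr <- small_frame(p, seed = 37)  # mean climate ~60 << 193.5
  sc <- scenario_curves(mod, fr, vars = "bas", age_range = c(5, 10))
  lowc <- sc$pred[sc$level == "low"]
  highc <- sc$pred[sc$level == "high"]
  expect_true(all(lowc > highc))

  # degenerate gradient: constant variable gives identical curves
  fr2 <- fr
  fr2$dheight <- 0.3
  sc2 <- scenario_curves(mod, fr2, vars = "dheight", age_range = 1:5)
  expect_equal(sc2$pred[sc2$level == "low"], sc2$pred[sc2$level == "high"])

  expect_error(scenario_curves(mod, fr, vars = "rd"), "absent")

  # interaction grid: maximum at the low-competition / low-stress corner
  # whenever a5 < 0, a6 < 0, a7 > 0 over the observed covariate box
  gr <- scenario_grid(mod, fr, age_range = 8)
  best <- gr[which.max(gr$pred), ]
  expect_equal(best$bas_level, "low")
  expect_equal(best$climate_level, "low")
})
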