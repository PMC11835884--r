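#' Configuration of a synthetic stand study
#'
#' Describes a felled-tree branch study: square plots with a competitor buffer,
#' a fixed number of target trees per plot (one per social status by default),
#' an annual window of increments, and AR(1) climate parameters per plot.
#'
#' @param n_plots number of plots.
#' @param plot_area_ha plot area in hectares (square plots).
#' @param targets_per_plot target (felled) trees per plot.
#' @param trees_per_plot total stems simulated per plot including the buffer
#'   ring; `NULL` derives it from `density_ha` over plot plus buffer.
#' @param density_ha stand density, stems per hectare. The default (480),
#'   together with the geometric-circle basal-area convention used by
#'   [run_pipeline()], puts the simulated stand basal area in the observed
#'   3.7-48.7 m2/ha range that the reference coefficients expect (see the
#'   methods vignette).
#' @param competition_radius competition radius in metres; competitors are also
#'   simulated in a buffer of this width around the plot.
#' @param years contiguous calendar years of the increment window.
#' @param felling_year year the target trees are felled (after the window).
#' @param climate_params named list; each element `c(mean=, sd=, ar1=)` for one
#'   climate variable. Defaults describe spring climatic moisture deficit
#'   (`cmd_mam_mm`) and spring reference evapotranspiration (`eref_mam_mm`).
#' @param status_mix proportions of dominant/intermediate/suppressed among
#'   target trees; must sum to 1.
#' @param dbh_range felling-year over-bark DBH range (cm) of simulated stems.
#' @param n_branches sampled branches (whorls) per target tree.
#' @return An object of class `stand_config`.
#' @export
stand_config <- function(n_plots = 18,
                         plot_area_ha = 0.06,
                         targets_per_plot = 3,
                         trees_per_plot = NULL,
                         density_ha = 480,
                         competition_radius = 8,
                         years = 1999:2022,
                         felling_year = 2023,
                         climate_params = list(
                           cmd_mam_mm = c(mean = 60, sd = 20, ar1 = 0.2),
                           eref_mam_mm = c(mean = 250, sd = 30, ar1 = 0.2)
                         ),
                         status_mix = c(dominant = 1/3, intermediate = 1/3,
                                        suppressed = 1/3),
                         dbh_range = c(4.3, 46.33),
                         n_branches = 14) {
  if (n_plots < 1) stop("n_plots must be positive", call. = FALSE)
  if (plot_area_ha <= 0) stop("plot_area_ha must be > 0", call. = FALSE)
  if (competition_radius <= 0) stop("competition_radius must be > 0", call. = FALSE)
  if (targets_per_plot < 1) stop("targets_per_plot must be positive", call. = FALSE)
  if (!all(diff(years) == 1L)) stop("years must be contiguous", call. = FALSE)
  if (felling_year <= max(years)) stop("felling_year must follow the window", call. = FALSE)
  if (abs(sum(status_mix) - 1) > 1e-8) stop("status_mix must sum to 1", call. = FALSE)
  for (v in names(climate_params)) {
    p <- climate_params[[v]]
    if (abs(p[["ar1"]]) >= 1) {
      stop("climate AR(1) coefficient must satisfy |ar1| < 1 for ", v,
           call. = FALSE)
    }
  }
  side <- sqrt(plot_area_ha * 1e4)
  if (is.null(trees_per_plot)) {
    ext_area <- (side + 2 * competition_radius)^2 / 1e4
    trees_per_plot <- max(targets_per_plot, round(density_ha * ext_area))
  }
  if (trees_per_plot < targets_per_plot) {
    stop("trees_per_plot must be >= targets_per_plot", call. = FALSE)
  }
  structure(
    list(n_plots = n_plots, plot_area_ha = plot_area_ha, side_m = side,
         targets_per_plot = targets_per_plot, trees_per_plot = trees_per_plot,
         density_ha = density_ha, competition_radius = competition_radius,
         years = years, felling_year = felling_year,
         climate_params = climate_params, status_mix = status_mix,
         dbh_range = dbh_range, n_branches = n_branches),
    class = "stand_config"
  )
}

#' Simulate a stand layout
#'
#' Places stems uniformly at random over each plot plus a buffer of one
#' competition radius, draws felling-year DBH from a scaled Beta distribution
#' over the configured range, derives felling height and tree age from DBH by
#' smooth allometries with noise, and selects the target trees (one per social
#' status by default) from stems inside the core plot.
#'
#' @param config a [stand_config()].
#' @param seed integer seed; the same `(config, seed)` pair reproduces the
#'   stand exactly.
#' @return A list of class `bg_stand` with data frames `plots` (plot_id,
#'   area_ha, radius_m, side_m) and `trees` (tree_id, plot_id, x_m, y_m,
#'   dbh_felling_cm, ht_felling_m, age_felling, is_target, status).
#' @export
simulate_stand <- function(config, seed = 1L) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(as.integer(seed))
  side <- config$side_m
  buf <- config$competition_radius
  lo <- -buf
  hi <- side + buf
  plots <- data.frame(plot_id = seq_len(config$n_plots),
                      area_ha = config$plot_area_ha,
                      radius_m = config$competition_radius,
                      side_m = side)
  tree_list <- vector("list", config$n_plots)
  statuses <- c("dominant", "intermediate", "suppressed")
  n_status <- .split_counts(config$targets_per_plot, config$status_mix)
  for (p in seq_len(config$n_plots)) {
    n <- config$trees_per_plot
    x <- stats::runif(n, lo, hi)
    y <- stats::runif(n, lo, hi)
    # Beta(3.5, 2.9) over the range reproduces the observed DBH mean/sd
    dbh <- config$dbh_range[1] +
      diff(config$dbh_range) * stats::rbeta(n, 3.5, 2.9)
    ht <- 1.3 + 25 * (1 - exp(-0.075 * dbh))^1.3 *
      exp(stats::rnorm(n, 0, 0.05))
    age <- pmin(70, pmax(16, round(dbh * 1.45 + stats::rnorm(n, 0, 4))))
    core <- which(x >= 0 & x <= side & y >= 0 & y <= side)
    if (length(core) < config$targets_per_plot) {
      stop("not enough stems inside the core plot; increase trees_per_plot",
           call. = FALSE)
    }
    # pick targets at status-typical DBH quantiles among core stems
    ord <- core[order(dbh[core], decreasing = TRUE)]
    qs <- rep(c(0.10, 0.50, 0.90), times = n_status)
    idx <- unique(pmin(length(ord), pmax(1L, round(qs * (length(ord) - 1)) + 1L)))
    while (length(idx) < config$targets_per_plot) {
      idx <- unique(c(idx, sample.int(length(ord), 1L)))
    }
    target_ids <- ord[idx[seq_len(config$targets_per_plot)]]
    status <- rep(NA_character_, n)
    status[target_ids] <- rep(statuses, times = n_status)[seq_along(target_ids)]
    tree_list[[p]] <- data.frame(
      tree_id = sprintf("P%02d_T%03d", p, seq_len(n)),
      plot_id = p, x_m = x, y_m = y,
      dbh_felling_cm = dbh, ht_felling_m = ht, age_felling = age,
      is_target = seq_len(n) %in% target_ids,
      status = status
    )
  }
  structure(list(plots = plots, trees = do.call(rbind, tree_list),
                 config = config, seed = as.integer(seed)),
            class = "bg_stand")
}

# split n into integer counts proportional to mix
.split_counts <- function(n, mix) {
  k <- floor(n * mix)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(n * mix - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Simulate plot-level climate series
#'
#' One stationary Gaussian AR(1) series per plot and climate variable around
#' the configured mean, truncated at zero (negative draws are set to 0).
#'
#' @param config a [stand_config()].
#' @param seed integer seed.
#' @param years calendar years to generate (default the config window; the
#'   pipeline extends it backwards so that branches formed before the window
#'   can be grown forward).
#' @return Data frame `plot_id, year, <variable...>` with one row per
#'   plot-year (schema `climate.csv`).
#' @export
simulate_climate <- function(config, seed = 1L, years = config$years) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(as.integer(seed) + 104729L)  # independent stream from the stand
  out <- expand.grid(year = years, plot_id = seq_len(config$n_plots))
  out <- out[, c("plot_id", "year")]
  for (v in names(config$climate_params)) {
    p <- config$climate_params[[v]]
    phi <- p[["ar1"]]; mu <- p[["mean"]]; sd <- p[["sd"]]
    vals <- numeric(0)
    for (pl in seq_len(config$n_plots)) {
      x <- numeric(length(years))
      x[1] <- stats::rnorm(1, 0, sd)  # stationary marginal sd
      innov_sd <- sd * sqrt(1 - phi^2)
      for (t in seq_along(years)[-1]) {
        x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
      }
      vals <- c(vals, pmax(0, mu + x))
    }
    out[[v]] <- vals
  }
  rownames(out) <- NULL
  out
}

#' Simulate annual tree chronologies and ring series
#'
#' Grows every stem of a simulated stand along monotone Richards-type
#' height-age and diameter-age curves anchored at the felling-year values, and
#' derives the corresponding under-bark diameter and annual ring widths with
#' the stem bark coefficient, so that ring-based reconstruction can recover the
#' chronology exactly in the noise-free limit.
#'
#' @param stand a `bg_stand` from [simulate_stand()].
#' @param params a [growth_params()] (bark parameters are used).
#' @param seed integer seed (plot-level curve-shape noise).
#' @return List with `chronology` (tree_id, year, age, dbh1_cm, dbh0_cm, ht_m,
#'   dheight_m) covering every stem over the study window plus earlier years
#'   back to age 1, and `rings` (tree_id, year, orientation, width_mm).
#' @export
simulate_tree_growth <- function(stand, params, seed = 1L) {
  stopifnot(inherits(stand, "bg_stand"), inherits(params, "growth_params"))
  set.seed(as.integer(seed) + 15485863L)
  cfg <- stand$config
  ab <- params$bark_stem
  trees <- stand$trees
  k_plot <- stats::runif(cfg$n_plots, 0.035, 0.055)  # plot-level curve shape
  chron <- vector("list", nrow(trees))
  rings <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    ta <- tr$age_felling
    ages <- seq_len(ta)
    yrs <- cfg$felling_year - ta + ages
    k <- k_plot[tr$plot_id]
    hcurve <- (1 - exp(-k * ages))^1.4
    ht <- 1.3 + (tr$ht_felling_m - 1.3) * hcurve / hcurve[ta]
    dheight <- c(ht[1], diff(ht))
    # under-bark DBH at felling via the bark power law; the diameter curve
    # shares the height curve's shape so stand basal area co-moves with tree
    # height, as in the observed stands (tall insertion heights only occur
    # together with substantial basal area)
    dbh1_fell <- tr$dbh_felling_cm / (ab[["a"]] * ta^ab[["b"]])
    dbh1 <- dbh1_fell * hcurve / hcurve[ta]
    dbh0 <- ab[["a"]] * ages^ab[["b"]] * dbh1
    chron[[i]] <- data.frame(tree_id = tr$tree_id, year = yrs, age = ages,
                             dbh1_cm = dbh1, dbh0_cm = dbh0,
                             ht_m = ht, dheight_m = dheight)
    # ring widths (mm): radius increment; mean over orientations must cumulate
    w <- 10 * c(dbh1[1], diff(dbh1)) / 2
    rings[[i]] <- data.frame(tree_id = tr$tree_id, year = rep(yrs, 2),
                             orientation = rep(c("EW", "NS"), each = ta),
                             width_mm = rep(w, 2))
  }
  list(chronology = do.call(rbind, chron), rings = do.call(rbind, rings))
}

# AR(1) noise vector of length n, marginal sd `sd`
.ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1] + innov[t - 1]
  }
  e
}

#' Simulate annual branch increment series
#'
#' Runs the log-linear growth model forward as a generator. For each target
#' tree a random intercept `u ~ N(0, sigma_u2)` is drawn once per response;
#' each branch-year's log increment is the linear predictor (current branch
#' age, cumulative size, insertion height, tree height increment, stand basal
#' area, climate and the competition x climate interaction) plus an AR(1)
#' Gaussian error within the branch; increments are exponentiated, floored at
#' 0.01 natural units, and accumulated.
#'
#' Branch whorls are spread over the live crown; a whorl formed in year `t`
#' is inserted at the tree's height in year `t` (branches are not lifted), and
#' its depth into crown at felling is the subsequent height growth.
#'
#' @param stand a `bg_stand`.
#' @param climate climate table from [simulate_climate()].
#' @param competition per tree-year competition table from
#'   [competition_series()] (columns tree_id, year, bas).
#' @param chronology tree chronology table (from [simulate_tree_growth()]).
#' @param params_length,params_diameter [growth_params()] for the two
#'   responses.
#' @param seed integer seed.
#' @param dbl_max_cm,dbd_max_mm ceilings on a single year's increment,
#'   defaulting to the observed study maxima (66 cm, 13 mm). The log-linear
#'   recursion with a positive cumulative-size slope is unstable once an
#'   increment exceeds `-a1/a2`; the caps keep lucky high-intercept trees
#'   inside the observed range instead of letting them diverge. Capped rows
#'   are counted in the `n_capped` attribute.
#' @return Data frame in the `branches.csv` schema: branch_id, tree_id,
#'   whorl_age, bh_m, dinc_m, year, age, dbl_cm, dbd_mm, bl_cm, bd_mm.
#' @export
simulate_branch_growth <- function(stand, climate, competition, chronology,
                                   params_length, params_diameter,
                                   seed = 1L,
                                   dbl_max_cm = 66, dbd_max_mm = 13) {
  stopifnot(inherits(stand, "bg_stand"))
  set.seed(as.integer(seed) + 32452843L)
  cfg <- stand$config
  targets <- stand$trees[stand$trees$is_target, ]
  clim_var <- names(cfg$climate_params)
  n_capped <- 0L
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tr <- targets[i, ]
    ch <- chronology[chronology$tree_id == tr$tree_id, ]
    ch <- ch[order(ch$year), ]
    comp <- competition[competition$tree_id == tr$tree_id, ]
    cl <- climate[climate$plot_id == tr$plot_id, ]
    u_l <- stats::rnorm(1, 0, sqrt(params_length$sigma_u2))
    u_d <- stats::rnorm(1, 0, sqrt(params_diameter$sigma_u2))
    # whorl ages spread over the crown (oldest whorls near the crown base)
    max_age <- min(tr$age_felling - 2L, 34L)
    wa <- unique(round(seq(1, max_age, length.out = cfg$n_branches)))
    rows <- vector("list", length(wa))
    for (b in seq_along(wa)) {
      k <- wa[b]
      form_year <- cfg$felling_year - k
      bh <- ch$ht_m[match(form_year, ch$year)]
      if (is.na(bh)) bh <- min(ch$ht_m)
      dinc <- tr$ht_felling_m - bh
      yrs <- seq.int(form_year, cfg$felling_year - 1L)
      keep <- yrs %in% cfg$years
      if (!any(keep)) next
      n_y <- length(yrs)
      e_l <- .ar1_noise(n_y, sqrt(params_length$sigma2), params_length$rho)
      e_d <- .ar1_noise(n_y, sqrt(params_diameter$sigma2), params_diameter$rho)
      bl <- 0; bd <- 0
      rec <- matrix(NA_real_, n_y, 6)  # age, dbl, dbd, bl, bd, year
      for (t in seq_len(n_y)) {
        yr <- yrs[t]
        age_t <- t
        dh <- ch$dheight_m[match(yr, ch$year)]
        bas <- comp$bas[match(yr, comp$year)]
        cv_l <- cl[[clim_var[1]]][match(yr, cl$year)]
        cv_d <- cl[[clim_var[length(clim_var)]]][match(yr, cl$year)]
        if (is.na(dh) || is.na(bas) || is.na(cv_l) || is.na(cv_d)) {
          stop("missing covariate for tree ", tr$tree_id, " in year ", yr,
               call. = FALSE)
        }
        lp_l <- .linpred(params_length$fixed, age_t, bl / 100, bh, dh, bas, cv_l)
        lp_d <- .linpred(params_diameter$fixed, age_t, bd, bh, dh, bas, cv_d)
        dbl <- max(0.01, exp(lp_l + u_l + e_l[t]))
        dbd <- max(0.01, exp(lp_d + u_d + e_d[t]))
        if (dbl > dbl_max_cm || dbd > dbd_max_mm) n_capped <- n_capped + 1L
        dbl <- min(dbl, dbl_max_cm)
        dbd <- min(dbd, dbd_max_mm)
        bl <- bl + dbl
        bd <- bd + dbd
        rec[t, ] <- c(age_t, dbl, dbd, bl, bd, yr)
      }
      rec <- rec[keep, , drop = FALSE]
      rows[[b]] <- data.frame(
        branch_id = sprintf("%s_B%02d", tr$tree_id, b),
        tree_id = tr$tree_id, whorl_age = k, bh_m = bh, dinc_m = dinc,
        year = as.integer(rec[, 6]), age = as.integer(rec[, 1]),
        dbl_cm = rec[, 2], dbd_mm = rec[, 3],
        bl_cm = rec[, 4], bd_mm = rec[, 5]
      )
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_capped") <- n_capped
  res
}

# linear predictor of the shared model form; size already on model scale
.linpred <- function(a, age, size, bh, dheight, bas, clim) {
  a[["a0"]] + a[["a1"]] * age + a[["a2"]] * size + a[["a3"]] * bh +
    a[["a4"]] * dheight + a[["a5"]] * bas + a[["a6"]] * clim +
    a[["a7"]] * bas * clim
}

#' Simulate a replicate model frame with exogenous covariates
#'
#' The parameter-recovery protocol: covariates are drawn uniformly within the
#' observed study ranges (branch size on the model scale: metres for length,
#' millimetres for diameter; climate over a declared plausible range), grouped
#' into trees and branches, and the log response is the linear predictor plus
#' a tree intercept `N(0, sigma_u2)` plus (optionally AR(1)) residual noise.
#'
#' Covariates respect the hierarchy: insertion height is fixed per branch,
#' tree height increment, basal area and climate vary per tree-year, branch
#' age advances by one year along each series.
#'
#' @param params a [growth_params()].
#' @param n_trees,branches_per_tree layout (54 trees x 14 branches by default,
#'   about 745 series as in the motivating study).
#' @param series_years range of series lengths; each branch's length is drawn
#'   uniformly from it (default 4:10, about 5200 branch-years).
#' @param seed integer seed.
#' @return A model frame (see [build_design()]) with columns tree_id,
#'   branch_id, plot_id, year, age, size, bh, dheight, bas, climate, log_inc,
#'   inc_natural, plus attribute `response`.
#' @export
simulate_replicate_frame <- function(params,
                                     n_trees = 54,
                                     branches_per_tree = 14,
                                     series_years = 4:10,
                                     seed = 1L) {
  stopifnot(inherits(params, "growth_params"))
  set.seed(as.integer(seed))
  rng <- covariate_ranges()
  rg <- function(v) unlist(.range_of(v)[, c("min", "max")])
  size_rg <- if (params$response == "length") rg("bl") / 100 else rg("bd")
  clim_rg <- if (params$response == "length") c(10, 110) else c(160, 340)
  bh_rg <- rg("bh"); dh_rg <- rg("dheight"); bas_rg <- rg("bas")
  age_max <- rg("age")[["max"]]
  n_br <- n_trees * branches_per_tree
  tree_of_branch <- rep(seq_len(n_trees), each = branches_per_tree)
  len <- if (length(series_years) == 1L) rep(series_years, n_br) else
    sample(series_years, n_br, replace = TRUE)
  age0 <- vapply(pmax(1L, age_max - len), sample.int, integer(1), size = 1L)
  idx <- rep(seq_len(n_br), len)          # branch index per row
  pos <- sequence(len)                    # position within each series
  n <- length(idx)
  age <- age0[idx] + pos - 1L
  year <- 2022L - len[idx] + pos
  bh_br <- stats::runif(n_br, bh_rg[1], bh_rg[2])
  size <- stats::ave(stats::runif(n, size_rg[1], size_rg[2]), idx,
                     FUN = sort)          # cumulative size grows in time
  dheight <- stats::runif(n, dh_rg[1], dh_rg[2])
  bas <- stats::runif(n, bas_rg[1], bas_rg[2])
  clim <- stats::runif(n, clim_rg[1], clim_rg[2])
  u_tree <- stats::rnorm(n_trees, 0, sqrt(params$sigma_u2))
  if (params$rho == 0) {
    e <- stats::rnorm(n, 0, sqrt(params$sigma2))
  } else {
    e <- unlist(lapply(len, .ar1_noise, sd = sqrt(params$sigma2),
                       rho = params$rho), use.names = FALSE)
  }
  lp <- .linpred_vec(params$fixed, age, size, bh_br[idx], dheight, bas, clim)
  out <- data.frame(
    tree_id = sprintf("T%03d", tree_of_branch[idx]),
    branch_id = sprintf("T%03d_B%02d", tree_of_branch[idx],
                        (idx - 1L) %% branches_per_tree + 1L),
    plot_id = (tree_of_branch[idx] - 1L) %/% 3L + 1L,
    year = year, age = age, size = size, bh = bh_br[idx],
    dheight = dheight, bas = bas, climate = clim,
    log_inc = lp + u_tree[tree_of_branch[idx]] + e
  )
  out$inc_natural <- exp(out$log_inc)
  attr(out, "response") <- params$response
  attr(out, "climate_var") <-
    if (params$response == "length") "cmd_mam_mm" else "eref_mam_mm"
  class(out) <- c("growth_frame", class(out))
  out
}

.linpred_vec <- function(a, age, size, bh, dheight, bas, clim) {
  a[["a0"]] + a[["a1"]] * age + a[["a2"]] * size + a[["a3"]] * bh +
    a[["a4"]] * dheight + a[["a5"]] * bas + a[["a6"]] * clim +
    a[["a7"]] * bas * clim
}
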