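#' Fit the bark coefficient power law
#'
#' The bark coefficient `KB` — the ratio of over-bark to under-bark diameter —
#' declines smoothly with organ age and is modelled as `KB = a * age^b`. The
#' fit is least squares on the log-log scale:
#' `log(over/under) = log(a) + b * log(age)`.
#'
#' @param age organ ages (years, > 0).
#' @param over,under over-bark and under-bark diameters (same units, > 0).
#' @return List with `a`, `b`, `r2` (R-squared of the log-linear fit) and `n`.
#' @export
#' @examples
#' age <- rep(1:20, 3)
#' under <- runif(60, 5, 40)
#' over <- 1.34 * age^-0.06 * under
#' fit_bark_coefficient(age, over, under)
fit_bark_coefficient <- function(age, over, under) {
  if (length(age) != length(over) || length(over) != length(under)) {
    stop("age, over and under must have equal length", call. = FALSE)
  }
  if (length(age) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(age <= 0) || any(over <= 0) || any(under <= 0)) {
    stop("ages and diameters must be positive", call. = FALSE)
  }
  kb <- log(over / under)
  la <- log(age)
  fit <- stats::lm.fit(cbind(1, la), kb)
  res <- fit$residuals
  tss <- sum((kb - mean(kb))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  list(a = unname(exp(fit$coefficients[1])), b = unname(fit$coefficients[2]),
       r2 = r2, n = length(age))
}

#' Back-calculate annual stem diameters from ring widths
#'
#' Under-bark DBH at age `t` is twice the cumulative mean ring width through
#' `t` (orientations averaged per year, mm converted to cm); the over-bark
#' series applies the bark power law `DBH0 = a * age^b * DBH1`.
#'
#' @param rings data frame `tree_id, year, orientation, width_mm` (one or more
#'   orientations per year); a single tree or several.
#' @param bark list or vector with elements `a` and `b`.
#' @return Data frame `tree_id, year, age, dbh1_cm, dbh0_cm`, one row per
#'   tree-year from pith to the last measured ring.
#' @export
backcast_dbh <- function(rings, bark) {
  a <- bark[["a"]]; b <- bark[["b"]]
  if (nrow(rings) == 0) {
    return(data.frame(tree_id = character(), year = integer(),
                      age = integer(), dbh1_cm = numeric(),
                      dbh0_cm = numeric()))
  }
  if (any(rings$width_mm < 0)) stop("negative ring width", call. = FALSE)
  out <- lapply(split(rings, rings$tree_id), function(r) {
    w <- tapply(r$width_mm, r$year, mean)          # average orientations
    yrs <- as.integer(names(w))
    o <- order(yrs)
    yrs <- yrs[o]; w <- as.numeric(w[o])
    if (any(diff(yrs) != 1L)) {
      stop("ring years not contiguous for tree ", r$tree_id[1], call. = FALSE)
    }
    age <- seq_along(yrs)
    dbh1 <- 2 * cumsum(w) / 10                      # mm radius -> cm diameter
    data.frame(tree_id = r$tree_id[1], year = yrs, age = age,
               dbh1_cm = dbh1, dbh0_cm = a * age^b * dbh1)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reconstruct a tree's annual height series from whorl geometry
#'
#' In monopodial conifers the whorl of age `k` marks the tree apex `k` years
#' before felling, so the tree height `k` years before felling equals the
#' felling height minus the mean depth-into-crown (DINC) of the age-`k` whorl.
#' Years without a whorl are linearly interpolated and flagged; DINC
#' measurement noise can make the raw series non-monotone, in which case an
#' isotonic (pool-adjacent-violators) adjustment is applied with a warning.
#'
#' @param whorls data frame `whorl_age, dinc_m`, possibly several branches per
#'   whorl age; whorl age 0 (the leader) is optional.
#' @param felling_height tree height at felling (m).
#' @param felling_year calendar year of felling.
#' @param max_age oldest whorl age to reconstruct (default: max observed).
#' @return Data frame `year, ht_m, dheight_m, interpolated, adjusted`,
#'   ascending in year and ending at the felling year.
#' @export
reconstruct_height_series <- function(whorls, felling_height, felling_year,
                                      max_age = NULL) {
  stopifnot(felling_height > 0)
  dinc_by_age <- tapply(whorls$dinc_m, whorls$whorl_age, mean)
  ages <- as.integer(names(dinc_by_age))
  if (is.null(max_age)) max_age <- max(ages)
  full_ages <- 0:max_age
  dinc <- rep(NA_real_, length(full_ages))
  dinc[match(ages, full_ages)] <- as.numeric(dinc_by_age)
  if (is.na(dinc[1])) dinc[1] <- 0   # the apex itself: zero depth at felling
  interpolated <- is.na(dinc)
  if (any(interpolated)) {
    dinc <- stats::approx(full_ages[!is.na(dinc)], dinc[!is.na(dinc)],
                          xout = full_ages, rule = 2)$y
  }
  ht <- felling_height - dinc        # height (k years before felling)
  year <- felling_year - full_ages
  o <- order(year)
  year <- year[o]; ht <- ht[o]; interpolated <- interpolated[o]
  adjusted <- FALSE
  if (any(diff(ht) < 0)) {
    warning("non-monotone reconstructed heights; isotonic adjustment applied")
    ht <- stats::isoreg(seq_along(ht), ht)$yf
    adjusted <- TRUE
  }
  data.frame(year = year, ht_m = ht,
             dheight_m = c(NA_real_, diff(ht)),
             interpolated = interpolated, adjusted = adjusted)
}

#' Drop branch-year records from the post-thinning stabilization window
#'
#' Stands thinned during the study window are unreliable for retrospective
#' competition until the canopy recloses; records earlier than five growing
#' seasons after the thinning year are removed.
#'
#' @param dataset data frame with a `year` column (e.g. the branches table).
#' @param thinning_year thinning calendar year, or `NULL` for no filtering.
#' @param recovery_years seasons to discard after thinning (default 5).
#' @return The filtered data frame; attributes `n_before`/`n_after` record the
#'   row counts.
#' @export
apply_study_filters <- function(dataset, thinning_year = NULL,
                                recovery_years = 5) {
  n0 <- nrow(dataset)
  if (!is.null(thinning_year)) {
    dataset <- dataset[dataset$year >= thinning_year + recovery_years, ,
                       drop = FALSE]
    if (nrow(dataset) == 0) {
      warning("all records fall before the post-thinning window")
    }
  }
  message(sprintf("study filters: %d of %d records retained", nrow(dataset), n0))
  attr(dataset, "n_before") <- n0
  attr(dataset, "n_after") <- nrow(dataset)
  dataset
}
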