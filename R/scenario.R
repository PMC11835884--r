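#' Gradient curves of predicted branch growth over age
#'
#' For each requested variable, builds low/mid/high levels from equal-width
#' thirds of its observed range in `frame` (level = interval midpoint), holds
#' every other covariate at its frame mean, and predicts the back-transformed
#' increment across branch ages.
#'
#' @param model a `growth_model`.
#' @param frame the `growth_frame` that supplies ranges and means.
#' @param vars variables to sweep (must be design terms).
#' @param age_range ages at which to evaluate (default 1:30).
#' @param back_transform predictions on the natural scale (default TRUE).
#' @return Data frame `variable, level, value, age, pred`.
#' @export
scenario_curves <- function(model, frame, vars = c("dheight", "bh", "bas",
                                                   "climate"),
                            age_range = 1:30, back_transform = TRUE) {
  terms <- model$design$terms
  missing_v <- setdiff(vars, terms)
  if (length(missing_v)) {
    stop("gradient variables absent from the design: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  base <- c(age = mean(frame$age), size = mean(frame$size),
            bh = mean(frame$bh), dheight = mean(frame$dheight),
            bas = mean(frame$bas), climate = mean(frame$climate))
  out <- list()
  for (v in vars) {
    rg <- range(frame[[v]])
    cuts <- seq(rg[1], rg[2], length.out = 4)
    mids <- (cuts[-4] + cuts[-1]) / 2
    for (l in seq_along(mids)) {
      nd <- as.data.frame(as.list(base))[rep(1, length(age_range)), ]
      nd$age <- age_range
      nd[[v]] <- mids[l]
      pred <- predict(model, nd, back_transform = back_transform)
      out[[length(out) + 1]] <- data.frame(
        variable = v, level = c("low", "mid", "high")[l], value = mids[l],
        age = age_range, pred = pred)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Competition x climate scenario grid
#'
#' Crosses low/mid/high levels of stand basal area and the climate variable
#' (equal-width thirds of their observed ranges, midpoints) with all other
#' covariates at their frame means, and predicts increments across ages.
#'
#' @inheritParams scenario_curves
#' @return Data frame `bas_level, climate_level, bas, climate, age, pred`.
#' @export
scenario_grid <- function(model, frame, age_range = 1:30,
                          back_transform = TRUE) {
  if (!all(c("bas", "climate") %in% model$design$terms)) {
    stop("the design lacks bas and/or climate", call. = FALSE)
  }
  lev <- function(x) {
    cuts <- seq(min(x), max(x), length.out = 4)
    (cuts[-4] + cuts[-1]) / 2
  }
  bas_l <- lev(frame$bas); clim_l <- lev(frame$climate)
  base <- c(age = mean(frame$age), size = mean(frame$size),
            bh = mean(frame$bh), dheight = mean(frame$dheight))
  lab <- c("low", "mid", "high")
  out <- list()
  for (i in 1:3) for (j in 1:3) {
    nd <- as.data.frame(as.list(base))[rep(1, length(age_range)), ]
    nd$age <- age_range
    nd$bas <- bas_l[i]
    nd$climate <- clim_l[j]
    pred <- predict(model, nd, back_transform = back_transform)
    out[[length(out) + 1]] <- data.frame(
      bas_level = lab[i], climate_level = lab[j],
      bas = bas_l[i], climate = clim_l[j], age = age_range, pred = pred)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
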