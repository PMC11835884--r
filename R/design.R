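#' Specify a branch-growth model design
#'
#' @param response `"length"` (log annual length increment, cm) or
#'   `"diameter"` (log annual over-bark diameter increment, mm).
#' @param terms ordered covariate names among `age`, `size`, `bh`, `dheight`,
#'   `bas`, `climate`, `bas:climate`. The interaction requires both main
#'   effects.
#' @param climate_lag years the climate series is shifted back (0, 1 or 2):
#'   lag 1 pairs an increment with the previous year's climate.
#' @return An object of class `growth_design`.
#' @export
growth_design <- function(response = c("length", "diameter"),
                          terms = c("age", "size", "bh", "dheight", "bas",
                                    "climate", "bas:climate"),
                          climate_lag = 0L) {
  response <- match.arg(response)
  allowed <- c("age", "size", "bh", "dheight", "bas", "climate", "bas:climate")
  if (!all(terms %in% allowed)) {
    stop("unknown terms: ", paste(setdiff(terms, allowed), collapse = ", "),
         call. = FALSE)
  }
  if ("bas:climate" %in% terms && !all(c("bas", "climate") %in% terms)) {
    stop("the interaction requires both main effects", call. = FALSE)
  }
  if (!climate_lag %in% 0:2) stop("climate_lag must be 0, 1 or 2", call. = FALSE)
  structure(
    list(response = response, terms = terms, climate_lag = as.integer(climate_lag),
         climate_var = if (response == "length") "cmd_mam_mm" else "eref_mam_mm"),
    class = "growth_design"
  )
}

#' Assemble the branch-year model frame
#'
#' Joins the branch increment table with tree chronologies (height increment),
#' competition series (BAS) and plot climate into one row per branch-year.
#' The response is the natural log of the increment; the cumulative-size
#' covariate is the branch's size *entering* the year (cumulative minus the
#' year's increment), expressed in metres for the length model and millimetres
#' for the diameter model. Climate is shifted by the design's lag. Rows with a
#' non-positive increment are excluded with a warning; rows with any
#' unresolvable covariate are dropped and counted.
#'
#' @param branches branches table (`branches.csv` schema).
#' @param chronology tree chronology `tree_id, year, dheight_m` (+ more).
#' @param competition competition table `tree_id, year, bas`.
#' @param climate climate table `plot_id, year, <climate_var>`.
#' @param design a [growth_design()].
#' @param tree_plot optional map `tree_id, plot_id`; defaults to a `plot_id`
#'   column on `branches` or a prefix of `tree_id`.
#' @return A `growth_frame` data frame (one row per branch-year) with columns
#'   `tree_id, branch_id, plot_id, year, age, size, bh, dheight, bas, climate,
#'   log_inc, inc_natural` and attributes `response`, `climate_var`,
#'   `climate_lag`, `n_dropped`.
#' @export
build_design <- function(branches, chronology, competition, climate, design,
                         tree_plot = NULL) {
  stopifnot(inherits(design, "growth_design"))
  inc <- if (design$response == "length") branches$dbl_cm else branches$dbd_mm
  cum <- if (design$response == "length") branches$bl_cm else branches$bd_mm
  size_prev <- cum - inc
  if (design$response == "length") size_prev <- size_prev / 100  # cm -> m
  if (is.null(tree_plot)) {
    if (!is.null(branches$plot_id)) {
      plot_of <- branches$plot_id
    } else {
      plot_of <- as.integer(sub("^P(\\d+)_.*$", "\\1", branches$tree_id))
    }
  } else {
    plot_of <- tree_plot$plot_id[match(branches$tree_id, tree_plot$tree_id)]
  }
  dheight <- chronology$dheight_m[
    match(paste(branches$tree_id, branches$year),
          paste(chronology$tree_id, chronology$year))]
  bas <- competition$bas[
    match(paste(branches$tree_id, branches$year),
          paste(competition$tree_id, competition$year))]
  clim <- climate[[design$climate_var]][
    match(paste(plot_of, branches$year - design$climate_lag),
          paste(climate$plot_id, climate$year))]
  bad_inc <- !is.na(inc) & inc <= 0
  if (any(bad_inc)) {
    warning(sum(bad_inc), " rows with non-positive increment excluded")
  }
  keep <- !bad_inc & !is.na(inc) & !is.na(dheight) & !is.na(bas) & !is.na(clim)
  n_dropped <- sum(!keep) - sum(bad_inc)
  out <- data.frame(
    tree_id = branches$tree_id, branch_id = branches$branch_id,
    plot_id = plot_of, year = branches$year,
    age = branches$age, size = size_prev, bh = branches$bh_m,
    dheight = dheight, bas = bas, climate = clim,
    log_inc = log(pmax(inc, .Machine$double.xmin)),
    inc_natural = inc
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "response") <- design$response
  attr(out, "climate_var") <- design$climate_var
  attr(out, "climate_lag") <- design$climate_lag
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("growth_frame", class(out))
  out
}

# model matrix for a design on a frame; stable column order/names
.design_matrix <- function(frame, terms) {
  cols <- list(`(Intercept)` = rep(1, nrow(frame)))
  for (tm in terms) {
    cols[[tm]] <- if (tm == "bas:climate") frame$bas * frame$climate
    else frame[[tm]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}
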