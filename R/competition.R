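#' Hegyi distance-dependent competition index
#'
#' `CI_i = sum_j (d_j / d_i) / L_ij` over the competitors `j` within the
#' competition radius of subject `i`: larger and closer neighbours press
#' harder.
#'
#' @param subject_dbh subject diameter (cm, > 0).
#' @param comp_dbh competitor diameters (cm).
#' @param comp_dist competitor distances to the subject (m, > 0).
#' @return The index (0 for no competitors).
#' @export
#' @examples
#' hegyi_ci(25, c(30, 20), c(5, 4))  # 0.24 + 0.20
hegyi_ci <- function(subject_dbh, comp_dbh, comp_dist) {
  if (subject_dbh <= 0) stop("subject dbh must be > 0", call. = FALSE)
  if (length(comp_dbh) != length(comp_dist)) {
    stop("competitor dbh and distance vectors differ in length", call. = FALSE)
  }
  if (length(comp_dbh) == 0) return(0)
  if (any(comp_dist <= 0)) {
    stop("competitor distances must be > 0 (co-located trees unsupported)",
         call. = FALSE)
  }
  sum((comp_dbh / subject_dbh) / comp_dist)
}

#' Basal-area competition indices within the competition circle
#'
#' `BAS` is the competitors' basal area per hectare referenced to the
#' competition circle `S_compete`; `BAL` restricts the sum to competitors
#' larger than the subject. The conventional printed form of the reference
#' area is `S_compete = (pi/4) R^2` — the area of a circle whose *diameter*
#' is the competition radius; `s_convention = "radius"` selects the geometric
#' circle `pi R^2` instead.
#'
#' @param subject_dbh subject diameter (cm).
#' @param comp_dbh competitor diameters (cm, >= 0); the subject is excluded
#'   unless `include_subject = TRUE`.
#' @param radius competition radius R (m).
#' @param s_convention `"diameter"` (default, `S = (pi/4) R^2`) or `"radius"`
#'   (`S = pi R^2`).
#' @param include_subject add the subject's own basal area into BAS.
#' @return Named vector `c(bas =, bal =)` in m2/ha.
#' @export
#' @examples
#' basal_area_indices(25, c(30, 20), radius = 8)
basal_area_indices <- function(subject_dbh, comp_dbh, radius,
                               s_convention = c("diameter", "radius"),
                               include_subject = FALSE) {
  s_convention <- match.arg(s_convention)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (any(comp_dbh < 0) || subject_dbh < 0) {
    stop("diameters must be >= 0", call. = FALSE)
  }
  s_m2 <- if (s_convention == "diameter") pi / 4 * radius^2 else pi * radius^2
  d_m <- comp_dbh / 100
  if (include_subject) d_m <- c(d_m, subject_dbh / 100)
  bas <- pi / 4 * sum(d_m^2) * 1e4 / s_m2
  larger <- comp_dbh[comp_dbh > subject_dbh] / 100
  bal <- pi / 4 * sum(larger^2) * 1e4 / s_m2
  c(bas = bas, bal = bal)
}

#' Annual competition series for the target trees of a stand
#'
#' For every target tree and year, computes the Hegyi index, BAS and BAL from
#' the back-cast diameters of the neighbours within the competition radius,
#' plus the relative diameter `RD = DBH0 / Dg` against the plot's quadratic
#' mean diameter that year.
#'
#' @param stand a `bg_stand` (or list with `trees` incl. positions) from
#'   [simulate_stand()].
#' @param chronology data frame `tree_id, year, dbh0_cm` covering every stem
#'   for the requested years (gaps raise an error naming the tree-year).
#' @param years calendar years to evaluate.
#' @param radius competition radius (m); default from the stand config.
#' @param s_convention passed to [basal_area_indices()].
#' @param targets_only restrict to target trees (default) or all stems.
#' @param missing `"error"` (default): a neighbour chronology gap raises an
#'   error naming the tree-year; `"zero"`: a stem absent from the chronology
#'   that year had not yet established and contributes nothing (it is also
#'   excluded from the quadratic mean diameter).
#' @return Data frame `tree_id, year, ci, bas, bal, rd, n_competitors`
#'   (schema `competition.csv`).
#' @export
competition_series <- function(stand, chronology, years,
                               radius = NULL,
                               s_convention = c("diameter", "radius"),
                               targets_only = TRUE,
                               missing = c("error", "zero")) {
  s_convention <- match.arg(s_convention)
  missing <- match.arg(missing)
  trees <- stand$trees
  if (is.null(radius)) radius <- stand$config$competition_radius
  subjects <- if (targets_only) trees[trees$is_target, ] else trees
  # wide lookup: dbh0 by tree x year
  keys <- paste(chronology$tree_id, chronology$year)
  dbh_at <- function(id, yr, required = missing == "error") {
    v <- chronology$dbh0_cm[match(paste(id, yr), keys)]
    if (anyNA(v) && required) {
      bad <- paste(id[is.na(v)][1], yr)
      stop("chronology gap for tree-year ", bad, call. = FALSE)
    }
    v
  }
  out <- vector("list", nrow(subjects) * length(years))
  r <- 0L
  for (i in seq_len(nrow(subjects))) {
    su <- subjects[i, ]
    plot_trees <- trees[trees$plot_id == su$plot_id, ]
    dx <- plot_trees$x_m - su$x_m
    dy <- plot_trees$y_m - su$y_m
    dist <- sqrt(dx^2 + dy^2)
    neigh <- plot_trees$tree_id != su$tree_id & dist <= radius
    comp_ids <- plot_trees$tree_id[neigh]
    comp_dist <- dist[neigh]
    for (yr in years) {
      d_i <- dbh_at(su$tree_id, yr)      # subject gap: error or skip the year
      if (is.na(d_i)) next
      d_j <- if (length(comp_ids)) dbh_at(comp_ids, yr) else numeric(0)
      present <- !is.na(d_j)
      ci <- hegyi_ci(d_i, d_j[present], comp_dist[present])
      ba <- basal_area_indices(d_i, d_j[present], radius, s_convention)
      d_plot <- dbh_at(plot_trees$tree_id, yr, required = FALSE)
      dg <- sqrt(mean(d_plot^2, na.rm = TRUE))
      r <- r + 1L
      out[[r]] <- data.frame(tree_id = su$tree_id, year = yr, ci = ci,
                             bas = ba[["bas"]], bal = ba[["bal"]],
                             rd = d_i / dg, n_competitors = sum(present))
    }
  }
  res <- do.call(rbind, out[seq_len(r)])
  rownames(res) <- NULL
  res
}
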