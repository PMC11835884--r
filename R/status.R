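#' Classify tree social status from cumulative basal area
#'
#' Trees in a plot are ranked in descending DBH and the running sum of basal
#' area (`pi/4 DBH^2`) is cut into five intervals of equal cumulative basal
#' area. Trees in the first, third and fifth interval are labelled dominant,
#' intermediate and suppressed; the second and fourth intervals stay
#' unassigned. A tree whose basal-area span straddles a boundary goes to the
#' interval containing the midpoint of its span.
#'
#' @param dbh diameters at breast height (cm) of the trees in one plot.
#' @param ids optional tree identifiers (defaults to indices).
#' @return Character vector of labels (`dominant`, `intermediate`,
#'   `suppressed`, `unassigned`) in the input order. Fewer than five trees
#'   yields all-`unassigned` with a warning.
#' @export
#' @examples
#' classify_social_status(c(40, 35, 30, 25, 20, 10))
classify_social_status <- function(dbh, ids = seq_along(dbh)) {
  n <- length(dbh)
  if (n < 5) {
    warning("fewer than 5 trees: all unassigned")
    return(stats::setNames(rep("unassigned", n), ids))
  }
  o <- order(dbh, decreasing = TRUE)
  ba <- pi / 4 * dbh[o]^2
  cum <- cumsum(ba)
  total <- cum[n]
  mid <- cum - ba / 2
  interval <- pmin(5L, findInterval(mid, seq(0, total, length.out = 6),
                                    rightmost.closed = TRUE))
  lab <- rep("unassigned", n)
  lab[interval == 1L] <- "dominant"
  lab[interval == 3L] <- "intermediate"
  lab[interval == 5L] <- "suppressed"
  out <- character(n)
  out[o] <- lab
  stats::setNames(out, ids)
}
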