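#' Hierarchical partitioning of predictor-group importance
#'
#' Decomposes the full OLS model's R-squared into per-group independent
#' contributions by averaging, over all orders in which groups can enter the
#' model, the R-squared increase from adding each group (the
#' Chevan-Sutherland goodness-of-fit averaging, computed over the subset
#' lattice with Shapley weights). Independent contributions sum exactly to the
#' full-model R-squared; the joint contribution is the group's sole marginal
#' R-squared minus its independent contribution.
#'
#' @param frame a `growth_frame`.
#' @param groups named list mapping group labels to design-term vectors, e.g.
#'   `list("branch age" = "age", competition = "bas",
#'   interaction = "bas:climate")`.
#' @param stratum optional label recorded in the result (e.g. a social
#'   status).
#' @return An object of class `hp_result`: data frame `group, independent,
#'   independent_pct, marginal, joint` plus attributes `full_r2` and
#'   `stratum`.
#' @export
hierarchical_partition <- function(frame, groups, stratum = "all") {
  g <- length(groups)
  if (g > 12) stop("more than 12 groups: 2^g subset fits refused", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  y <- frame$log_inc
  n <- length(y)
  # R2 of every subset of groups, indexed by bitmask
  r2 <- numeric(2^g)
  for (mask in seq_len(2^g - 1)) {
    terms <- unlist(groups[which(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)],
                    use.names = FALSE)
    X <- .design_matrix(frame, terms)
    fit <- stats::lm.fit(X, y)
    r2[mask + 1] <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  full_r2 <- r2[2^g]
  indep <- numeric(g)
  fact <- factorial(0:g)
  for (k in seq_len(g)) {
    bit <- 2^(k - 1)
    acc <- 0
    for (mask in 0:(2^g - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      sz <- sum(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
      w <- fact[sz + 1] * fact[g - sz] / fact[g + 1]   # |S|! (g-|S|-1)! / g!
      acc <- acc + w * (r2[mask + bit + 1] - r2[mask + 1])
    }
    indep[k] <- acc
  }
  marginal <- r2[2^(seq_len(g) - 1) + 1]
  out <- data.frame(group = names(groups),
                    independent = indep,
                    independent_pct = 100 * indep / full_r2,
                    marginal = marginal,
                    joint = marginal - indep)
  attr(out, "full_r2") <- full_r2
  attr(out, "stratum") <- stratum
  class(out) <- c("hp_result", class(out))
  out
}

#' Default predictor grouping for the branch growth model
#'
#' The conventional grouping: branch age, branch size, branch height, tree
#' height growth, competition, climate, and the competition x climate
#' interaction.
#'
#' @return Named list usable as the `groups` argument of
#'   [hierarchical_partition()].
#' @export
default_hp_groups <- function() {
  list("branch age" = "age",
       "branch size" = "size",
       "branch height" = "bh",
       "tree height growth" = "dheight",
       "competition" = "bas",
       "climate" = "climate",
       "interaction" = "bas:climate")
}

#' Hierarchical partitioning stratified by tree social status
#'
#' Refits the partition within each social-status stratum of the frame.
#'
#' @param frame a `growth_frame`.
#' @param status named character vector or data frame (`tree_id`, `status`)
#'   mapping trees to `dominant` / `intermediate` / `suppressed`.
#' @param groups as in [hierarchical_partition()].
#' @return List of `hp_result`, one per stratum (plus `"all"`).
#' @export
hp_by_status <- function(frame, status, groups = default_hp_groups()) {
  if (is.data.frame(status)) {
    status <- stats::setNames(as.character(status$status), status$tree_id)
  }
  st <- status[frame$tree_id]
  out <- list(all = hierarchical_partition(frame, groups, stratum = "all"))
  for (s in c("dominant", "intermediate", "suppressed")) {
    sub <- frame[!is.na(st) & st == s, , drop = FALSE]
    if (nrow(sub) > 20) {
      out[[s]] <- hierarchical_partition(sub, groups, stratum = s)
    }
  }
  out
}
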