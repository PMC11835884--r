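#' Leave-one-tree-out cross-validation
#'
#' One fold per tree: the model is refitted on the remaining trees and the
#' held-out tree's branch-years are predicted with fixed effects only (no
#' calibration data exist for an unseen tree by construction). Pooled
#' predictions are scored on both the log and the natural scale.
#'
#' @param frame a `growth_frame`.
#' @param design a [growth_design()].
#' @param engine `"ols"` or `"mixed"`.
#' @param ar1,estimation passed to [fit_mixed()] when `engine = "mixed"`.
#' @param back_transform_smearing apply the lognormal correction when
#'   back-transforming (default FALSE: plain `exp`).
#' @return List with `metrics_natural`, `metrics_log` ([compute_metrics()]
#'   reports over the pooled holdout predictions), `n_folds`, `skipped`
#'   (folds with singular designs), and `predictions` (frame keys + `pred_log`,
#'   `pred_natural`).
#' @export
loocv <- function(frame, design, engine = c("ols", "mixed"), ar1 = FALSE,
                  estimation = "REML", back_transform_smearing = FALSE) {
  engine <- match.arg(engine)
  trees <- unique(frame$tree_id)
  if (length(trees) < 3) stop("need >= 3 trees", call. = FALSE)
  preds <- rep(NA_real_, nrow(frame))
  skipped <- character(0)
  p <- length(design$terms) + 1L
  for (id in trees) {
    hold <- frame$tree_id == id
    train <- frame[!hold, , drop = FALSE]
    fit <- tryCatch(
      if (engine == "ols") fit_ols(train, design)
      else fit_mixed(train, design, ar1 = ar1, estimation = estimation),
      error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, id)
      next
    }
    preds[hold] <- predict(fit, frame[hold, , drop = FALSE])
  }
  if (length(skipped)) {
    warning("folds skipped (singular or failed fits): ",
            paste(skipped, collapse = ", "))
  }
  ok <- !is.na(preds)
  pred_nat <- exp(preds[ok])
  if (back_transform_smearing) {
    full <- if (engine == "ols") fit_ols(frame, design)
            else fit_mixed(frame, design, ar1 = ar1, estimation = estimation)
    pred_nat <- pred_nat * exp(full$sigma2 / 2)
  }
  list(
    metrics_log = compute_metrics(frame$log_inc[ok], preds[ok], p = p,
                                  scale = "log"),
    metrics_natural = compute_metrics(frame$inc_natural[ok], pred_nat, p = p,
                                      scale = "natural"),
    n_folds = length(trees), skipped = skipped,
    predictions = data.frame(tree_id = frame$tree_id[ok],
                             branch_id = frame$branch_id[ok],
                             year = frame$year[ok],
                             observed = frame$inc_natural[ok],
                             pred_log = preds[ok], pred_natural = pred_nat)
  )
}

#' Calibration-size experiment for BLUP localization
#'
#' How many branches must be measured on a new tree before mixed-model
#' predictions stabilize? Per replicate and tree, `k` branches are sampled
#' without replacement; the tree's random intercept is predicted by BLUP from
#' the sampled branches' records and the remaining branch-years are predicted
#' and scored by MAE on the natural scale. `k = 0` is the uncalibrated
#' fixed-effects prediction of the same target rows.
#'
#' @param frame a `growth_frame`.
#' @param design a [growth_design()].
#' @param k_values numbers of calibration branches (default 0:8).
#' @param replicates Monte Carlo replicates of the branch subsampling.
#' @param seed integer seed.
#' @param model optional prefitted `growth_model` (mixed); fitted from `frame`
#'   when `NULL`.
#' @param ar1,estimation passed to [fit_mixed()].
#' @return Data frame of class `calibration_curve`: `k, mae_mean, mae_sd,
#'   replicates, seed`. Trees with fewer than `k + 1` branches use all but one
#'   branch and are flagged via the `capped` attribute.
#' @export
calibration_experiment <- function(frame, design, k_values = 0:8,
                                   replicates = 30, seed = 1L,
                                   model = NULL, ar1 = FALSE,
                                   estimation = "REML") {
  if (is.null(model)) {
    model <- fit_mixed(frame, design, ar1 = ar1, estimation = estimation)
  }
  set.seed(as.integer(seed))
  trees <- unique(frame$tree_id)
  branch_of <- split(frame$branch_id, frame$tree_id)
  capped <- FALSE
  mae <- matrix(NA_real_, length(k_values), replicates,
                dimnames = list(k_values, NULL))
  for (r in seq_len(replicates)) {
    # one branch permutation per tree per replicate, shared across k
    perms <- lapply(trees, function(id) sample(unique(branch_of[[id]])))
    names(perms) <- trees
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      abs_err <- numeric(0)
      for (id in trees) {
        br <- perms[[id]]
        k_use <- min(k, length(br) - 1L)
        if (k_use < k) capped <- TRUE
        cal_br <- if (k_use > 0) br[seq_len(k_use)] else character(0)
        rows <- frame$tree_id == id
        tgt <- rows & !(frame$branch_id %in% cal_br)
        if (!any(tgt)) next
        cal <- if (k_use > 0) frame[rows & frame$branch_id %in% cal_br, ,
                                    drop = FALSE] else NULL
        pr <- predict(model, frame[tgt, , drop = FALSE], calibration = cal,
                      back_transform = TRUE)
        abs_err <- c(abs_err, abs(frame$inc_natural[tgt] - pr))
      }
      mae[ki, r] <- mean(abs_err)
    }
  }
  out <- data.frame(k = k_values,
                    mae_mean = rowMeans(mae),
                    mae_sd = apply(mae, 1, stats::sd),
                    replicates = replicates, seed = as.integer(seed))
  attr(out, "capped") <- capped
  class(out) <- c("calibration_curve", class(out))
  out
}
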