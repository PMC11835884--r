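#' Greedy forward selection of growth-model terms
#'
#' Starting from the intercept, repeatedly adds the candidate whose marginal
#' t-test is significant at `alpha` and whose addition minimizes AIC; stops
#' when no candidate qualifies. The interaction `bas:climate` is only eligible
#' once both main effects are in the model. After every addition, variance
#' inflation factors are computed and any term with VIF above `vif_limit` is
#' dropped again (unless it is a main effect of a retained interaction) and
#' barred.
#'
#' @param frame a `growth_frame`.
#' @param candidates candidate term names in block order (default the full
#'   model pool).
#' @param alpha significance level for entry (0.05).
#' @param vif_limit VIF threshold for scrutiny (5).
#' @return List with `terms` (selected, in entry order), `design` (a
#'   [growth_design()] when the selection is non-empty, else intercept-only
#'   terms `character(0)`), and `trace` (a data frame logging every step).
#' @export
forward_select <- function(frame,
                           candidates = c("age", "size", "bh", "dheight",
                                          "bas", "climate", "bas:climate"),
                           alpha = 0.05, vif_limit = 5) {
  if (length(candidates) < 1) stop("need >= 1 candidate", call. = FALSE)
  selected <- character(0)
  barred <- character(0)
  trace <- list()
  y <- frame$log_inc
  n <- length(y)
  repeat {
    pool <- setdiff(candidates, c(selected, barred))
    if ("bas:climate" %in% pool &&
        !all(c("bas", "climate") %in% selected)) {
      pool <- setdiff(pool, "bas:climate")
    }
    if (!length(pool)) break
    best <- NULL
    for (cand in pool) {
      X <- .design_matrix(frame, c(selected, cand))
      p <- ncol(X)
      qr_x <- qr(X)
      if (qr_x$rank < p) {
        # candidate collinear with current model: treat as infinite VIF
        trace[[length(trace) + 1]] <- data.frame(
          step = length(selected) + 1L, term = cand, aic = NA_real_,
          p_value = NA_real_, action = "barred (singular)")
        barred <- c(barred, cand)
        next
      }
      beta <- qr.coef(qr_x, y)
      res <- y - X %*% beta
      sse <- sum(res^2)
      s2 <- sse / (n - p)
      se <- sqrt(diag(chol2inv(qr.R(qr_x))) * s2)
      tval <- beta[p] / se[p]
      pval <- 2 * stats::pt(-abs(tval), df = n - p)
      ll <- -0.5 * n * (log(2 * pi * sse / n) + 1)
      aic <- -2 * ll + 2 * (p + 1)
      trace[[length(trace) + 1]] <- data.frame(
        step = length(selected) + 1L, term = cand, aic = aic,
        p_value = pval, action = "evaluated")
      if (is.finite(pval) && pval < alpha &&
          (is.null(best) || aic < best$aic)) {
        best <- list(term = cand, aic = aic, p = pval)
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best$term)
    trace[[length(trace) + 1]] <- data.frame(
      step = length(selected), term = best$term, aic = best$aic,
      p_value = best$p, action = "added")
    # VIF scrutiny
    if (length(selected) >= 2) {
      vifs <- .vif(frame, selected)
      flagged <- names(vifs)[vifs > vif_limit]
      protected <- if ("bas:climate" %in% selected)
        c("bas", "climate", "bas:climate") else character(0)
      drop <- setdiff(flagged, protected)
      for (d in drop) {
        selected <- setdiff(selected, d)
        barred <- c(barred, d)
        trace[[length(trace) + 1]] <- data.frame(
          step = length(selected) + 1L, term = d, aic = NA_real_,
          p_value = NA_real_,
          action = sprintf("dropped (VIF %.1f > %.1f)", vifs[[d]], vif_limit))
      }
    }
  }
  design <- if (length(selected)) {
    resp <- attr(frame, "response")
    ds <- growth_design(if (is.null(resp)) "length" else resp,
                        terms = intersect(
                          c("age", "size", "bh", "dheight", "bas", "climate",
                            "bas:climate"), selected))
    ds$terms <- selected
    ds
  } else NULL
  list(terms = selected, design = design,
       trace = do.call(rbind, trace))
}

# variance inflation factors of the current terms (intercept excluded)
.vif <- function(frame, terms) {
  X <- .design_matrix(frame, terms)[, -1, drop = FALSE]
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  if (ncol(X) < 2) return(out + 1)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    out[j] <- if (r2 >= 1) Inf else 1 / (1 - r2)
  }
  out
}

#' Select the climate lag by AIC
#'
#' Builds the model frame at each candidate lag, fits, and returns the lag
#' minimizing AIC; ties (within `tol`) break toward the smaller lag. Lags the
#' climate series cannot support are skipped with a warning.
#'
#' @param builder function `function(lag)` returning a `growth_frame` (or
#'   `NULL`/error when the lag is unsupported).
#' @param design a [growth_design()] (its `climate_lag` is ignored).
#' @param lags candidate lags (default 0:2).
#' @param engine `"ols"` (default) or `"mixed"`.
#' @param tol AIC tie tolerance (1e-6).
#' @return List with `lag` (chosen) and `table` (lag, n, aic).
#' @export
lag_select <- function(builder, design, lags = 0:2, engine = c("ols", "mixed"),
                       tol = 1e-6) {
  engine <- match.arg(engine)
  rows <- list()
  for (l in lags) {
    fr <- tryCatch(builder(l), error = function(e) NULL)
    if (is.null(fr) || nrow(fr) == 0) {
      warning("lag ", l, " skipped: frame could not be built")
      next
    }
    fit <- if (engine == "ols") fit_ols(fr, design)
           else fit_mixed(fr, design, estimation = "ML")
    rows[[length(rows) + 1]] <- data.frame(lag = l, n = nrow(fr),
                                           aic = fit$aic)
  }
  if (!length(rows)) stop("no lag could be evaluated", call. = FALSE)
  tab <- do.call(rbind, rows)
  best_aic <- min(tab$aic)
  chosen <- min(tab$lag[tab$aic <= best_aic + tol])
  list(lag = chosen, table = tab)
}
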