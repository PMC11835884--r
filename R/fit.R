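#' Ordinary least squares branch-growth model
#'
#' Fits the log-scale growth model by OLS. The reported residual variance is
#' `SSE/(n - p)`; the log-likelihood is the Gaussian ML value and
#' `AIC = -2 logLik + 2 k` with `k` = coefficients + 1 variance.
#'
#' @param frame a `growth_frame` from [build_design()] or
#'   [simulate_replicate_frame()].
#' @param design a [growth_design()] (its `terms` pick the columns).
#' @return An object of class `growth_model`.
#' @export
fit_ols <- function(frame, design) {
  stopifnot(inherits(design, "growth_design"))
  X <- .design_matrix(frame, design$terms)
  y <- frame$log_inc
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("too few rows for the design", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  sigma2 <- sse / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(X)
  s2_ml <- sse / n
  loglik <- -0.5 * n * (log(2 * pi * s2_ml) + 1)
  k <- p + 1
  structure(
    list(design = design, estimation = "OLS",
         coefficients = beta, se = se, vcov = xtx_inv * sigma2,
         sigma2 = sigma2, sigma_u2 = 0, rho = 0, ar1 = FALSE,
         loglik = loglik, aic = -2 * loglik + 2 * k,
         n_obs = n, n_groups = length(unique(frame$tree_id)),
         p = p, k = k, converged = TRUE, boundary = FALSE,
         ranef = NULL, grouping = "tree_id",
         frame_means = colMeans(X)[-1],
         fitted = as.numeric(X %*% beta)),
    class = "growth_model"
  )
}

# --- mixed model internals ---------------------------------------------------

# per-group precomputation; T = [X y], kept with branch/year labels
.mixed_prepare <- function(frame, X, y, grouping) {
  g <- factor(frame[[grouping]])
  idx <- split(seq_along(y), g)
  lapply(idx, function(ii) {
    Ti <- cbind(X[ii, , drop = FALSE], y[ii])
    list(T = Ti, TtT = crossprod(Ti), Tt1 = colSums(Ti),
         n = length(ii),
         branch = frame$branch_id[ii], year = frame$year[ii])
  })
}

# accumulate C = sum_i T' V^-1 T and logdet over groups for (lambda, rho);
# AR(1) Cholesky factors are cached per unique year-spacing pattern
.mixed_parts <- function(prep, lambda, rho) {
  pp1 <- ncol(prep[[1]]$T)
  C <- matrix(0, pp1, pp1)
  logdet <- 0
  chol_cache <- new.env(parent = emptyenv())
  for (gr in prep) {
    if (rho == 0) {
      s <- gr$n
      Tw <- gr$Tt1
      TtWT <- gr$TtT
      ldR <- 0
    } else {
      TtWT <- matrix(0, pp1, pp1)
      Tw <- numeric(pp1)
      s <- 0; ldR <- 0
      for (bb in split(seq_len(gr$n), gr$branch)) {
        yb <- gr$year[bb]
        Tb <- gr$T[bb, , drop = FALSE]
        if (length(bb) == 1L) {
          TtWT <- TtWT + tcrossprod(Tb[1, ])
          Tw <- Tw + Tb[1, ]
          s <- s + 1
        } else {
          key <- paste(diff(yb), collapse = ",")
          ch <- chol_cache[[key]]
          if (is.null(ch)) {
            ch <- chol(rho^abs(outer(yb, yb, "-")))
            chol_cache[[key]] <- ch
          }
          ldR <- ldR + 2 * sum(log(diag(ch)))
          Wt <- backsolve(ch, forwardsolve(t(ch), cbind(Tb, 1)))
          TtWT <- TtWT + crossprod(Tb, Wt[, seq_len(pp1), drop = FALSE])
          w1 <- Wt[, pp1 + 1]
          Tw <- Tw + crossprod(Tb, w1)[, 1]
          s <- s + sum(w1)
        }
      }
    }
    C <- C + TtWT - (lambda / (1 + lambda * s)) * tcrossprod(Tw)
    logdet <- logdet + ldR + log(1 + lambda * s)
  }
  list(C = C, logdet = logdet)
}

# negative profiled (RE)ML log-likelihood at par = (log lambda[, atanh rho])
.mixed_nll <- function(par, prep, n, p, reml, ar1) {
  lambda <- exp(par[1])
  rho <- if (ar1) tanh(par[2]) else 0
  parts <- .mixed_parts(prep, lambda, rho)
  C <- parts$C
  A <- C[seq_len(p), seq_len(p), drop = FALSE]
  b <- C[seq_len(p), p + 1]
  q <- C[p + 1, p + 1]
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(1e10)
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  rss <- max(q - sum(b * beta), 1e-12)
  if (reml) {
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(2 * pi * s2) + parts$logdet +
             2 * sum(log(diag(chA))) + (n - p))
  } else {
    s2 <- rss / n
    0.5 * (n * log(2 * pi * s2) + parts$logdet + n)
  }
}

#' Linear mixed-effects branch-growth model
#'
#' Random intercept per tree with optional AR(1) within-branch errors
#' (correlation `rho^|delta year|` between records of the same branch;
#' branches of one tree are conditionally independent given the tree
#' intercept). The Gaussian likelihood is profiled over the fixed effects and
#' the residual variance and maximized by multi-start quasi-Newton over
#' `(log lambda, atanh rho)` with `lambda = sigma_u2 / sigma2`.
#'
#' @param frame a `growth_frame`.
#' @param design a [growth_design()].
#' @param grouping column defining the random-intercept groups
#'   (default `"tree_id"`; `"plot_id"` gives plot-level intercepts).
#' @param ar1 model within-branch AR(1) correlation?
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param control list: `n_starts`, `maxit`, `reltol`.
#' @return A `growth_model` with variance components, BLUPs of the group
#'   intercepts, and convergence/boundary flags.
#' @export
fit_mixed <- function(frame, design, grouping = "tree_id", ar1 = FALSE,
                      estimation = c("REML", "ML"),
                      control = list()) {
  stopifnot(inherits(design, "growth_design"))
  estimation <- match.arg(estimation)
  ctl <- utils::modifyList(list(n_starts = 3L, maxit = 500L, reltol = 1e-10),
                           control)
  X <- .design_matrix(frame, design$terms)
  y <- frame$log_inc
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design", call. = FALSE)
  groups <- unique(frame[[grouping]])
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  prep <- .mixed_prepare(frame, X, y, grouping)
  reml <- estimation == "REML"
  lam_starts <- c(0.5, 0.05, 2)[seq_len(max(1, ctl$n_starts))]
  obj <- function(par) .mixed_nll(par, prep, n, p, reml, ar1)
  best <- NULL
  trace <- list()
  for (l0 in lam_starts) {
    par0 <- if (ar1) c(log(l0), atanh(0.3)) else log(l0)
    opt <- tryCatch(
      stats::optim(par0, obj, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
      error = function(e) NULL)
    if (is.null(opt)) {  # gradient-free fallback
      opt <- stats::optim(par0, obj,
                          method = if (ar1) "Nelder-Mead" else "Brent",
                          lower = if (ar1) -Inf else -20,
                          upper = if (ar1) Inf else 10,
                          control = list(maxit = ctl$maxit))
    }
    trace[[length(trace) + 1]] <- c(start = l0, value = opt$value,
                                    conv = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("mixed-model optimization failed to converge; trace: ",
         paste(vapply(trace, function(t) sprintf("%.4g", t[["value"]]),
                      ""), collapse = ", "), call. = FALSE)
  }
  lambda <- exp(best$par[1])
  rho <- if (ar1) tanh(best$par[2]) else 0
  parts <- .mixed_parts(prep, lambda, rho)
  C <- parts$C
  A <- C[seq_len(p), seq_len(p), drop = FALSE]
  b <- C[seq_len(p), p + 1]
  q <- C[p + 1, p + 1]
  chA <- chol(A)
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  names(beta) <- colnames(X)
  rss <- max(q - sum(b * beta), 1e-12)
  sigma2 <- if (reml) rss / (n - p) else rss / n
  sigma_u2 <- lambda * sigma2
  A_inv <- chol2inv(chA)
  se <- sqrt(diag(A_inv) * sigma2)
  names(se) <- colnames(X)
  loglik <- -best$value
  boundary <- lambda < 1e-6
  k <- p + 2 + as.integer(ar1)   # beta, sigma2, sigma_u2 [, rho]
  # BLUPs from the full data
  ranef <- vapply(prep, function(gr) {
    r <- gr$T[, p + 1] - gr$T[, seq_len(p), drop = FALSE] %*% beta
    ws <- .group_w(gr, rho)
    lambda * sum(ws$w * r) / (1 + lambda * ws$s)
  }, numeric(1))
  structure(
    list(design = design, estimation = estimation,
         coefficients = beta, se = se, vcov = A_inv * sigma2,
         sigma2 = sigma2, sigma_u2 = sigma_u2, rho = rho, ar1 = ar1,
         loglik = loglik, aic = -2 * loglik + 2 * k,
         n_obs = n, n_groups = length(groups),
         p = p, k = k,
         converged = best$convergence == 0, boundary = boundary,
         opt_trace = trace,
         ranef = ranef, grouping = grouping,
         frame_means = colMeans(X)[-1],
         fitted = as.numeric(X %*% beta)),
    class = "growth_model"
  )
}

# w = R^-1 1 and s = 1' R^-1 1 for one prepared group
.group_w <- function(gr, rho) {
  if (rho == 0) return(list(w = rep(1, gr$n), s = gr$n))
  w <- numeric(gr$n); s <- 0
  for (bb in split(seq_len(gr$n), gr$branch)) {
    if (length(bb) == 1L) {
      w[bb] <- 1; s <- s + 1
    } else {
      R <- rho^abs(outer(gr$year[bb], gr$year[bb], "-"))
      wb <- solve(R, rep(1, length(bb)))
      w[bb] <- wb; s <- s + sum(wb)
    }
  }
  list(w = w, s = s)
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("Branch growth model (%s, %s response)\n",
              x$estimation, x$design$response))
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se)
  print(signif(tab, 4))
  cat(sprintf("sigma2 = %.4f  sigma_u2 = %.4f  rho = %.3f\n",
              x$sigma2, x$sigma_u2, x$rho))
  cat(sprintf("logLik = %.3f  AIC = %.3f  n = %d  groups = %d\n",
              x$loglik, x$aic, x$n_obs, x$n_groups))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (x$boundary) cat("note: sigma_u2 at the zero boundary\n")
  invisible(x)
}

#' @export
coef.growth_model <- function(object, ...) object$coefficients

#' @export
logLik.growth_model <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' Predict branch increments, optionally with BLUP calibration
#'
#' Without calibration data the prediction is the population mean `X beta`.
#' With calibration pairs, each tree's random intercept is predicted from its
#' supplied residuals by the best linear unbiased predictor — for `m`
#' independent residuals with mean `rbar`,
#' `u_hat = m sigma_u2 / (m sigma_u2 + sigma2) * rbar`, generalized through
#' the AR(1) covariance when the model has one — and added to the linear
#' predictor for that tree's rows.
#'
#' @param object a `growth_model`.
#' @param newdata a `growth_frame` (or data frame with the design columns).
#' @param calibration optional data frame of observed rows (same columns as a
#'   frame, including `log_inc`) used to localize the random effects; its
#'   trees must appear in `newdata`.
#' @param back_transform return increments on the natural scale (`exp`)?
#' @param smearing apply the lognormal correction `exp(sigma2/2)` on
#'   back-transformation.
#' @param ... unused.
#' @return Numeric vector of predictions, one per `newdata` row.
#' @export
predict.growth_model <- function(object, newdata, calibration = NULL,
                                 back_transform = FALSE, smearing = FALSE,
                                 ...) {
  X <- .design_matrix(newdata, object$design$terms)
  lp <- as.numeric(X %*% object$coefficients)
  if (!is.null(calibration) && nrow(calibration) > 0 &&
      object$sigma_u2 > 0) {
    unknown <- setdiff(unique(calibration$tree_id), unique(newdata$tree_id))
    if (length(unknown)) {
      stop("calibration references trees absent from newdata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lambda <- object$sigma_u2 / object$sigma2
    Xc <- .design_matrix(calibration, object$design$terms)
    r_all <- calibration$log_inc - as.numeric(Xc %*% object$coefficients)
    for (id in unique(calibration$tree_id)) {
      ii <- which(calibration$tree_id == id)
      gr <- list(n = length(ii), branch = calibration$branch_id[ii],
                 year = calibration$year[ii])
      ws <- .group_w(gr, if (object$ar1) object$rho else 0)
      u_hat <- lambda * sum(ws$w * r_all[ii]) / (1 + lambda * ws$s)
      lp[newdata$tree_id == id] <- lp[newdata$tree_id == id] + u_hat
    }
  }
  if (back_transform) {
    out <- exp(lp)
    if (smearing) out <- out * exp(object$sigma2 / 2)
    out
  } else {
    lp
  }
}

#' Serialize a fitted model to JSON
#'
#' @param model a `growth_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @param seed optional seed to record in the metadata.
#' @return The JSON string, invisibly when written to a file.
#' @export
model_to_json <- function(model, path = NULL, seed = NULL) {
  obj <- list(
    design = list(response = model$design$response,
                  terms = model$design$terms,
                  climate_lag = model$design$climate_lag),
    estimation = model$estimation,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    sigma2 = model$sigma2, sigma_u2 = model$sigma_u2, rho = model$rho,
    loglik = model$loglik, aic = model$aic,
    n_obs = model$n_obs, n_groups = model$n_groups,
    converged = model$converged, boundary = model$boundary,
    package_version = as.character(utils::packageVersion("branchgrowth")),
    seed = seed
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else {
    js
  }
}
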