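#' Goodness-of-fit and prediction-error metrics
#'
#' The standard evaluation suite for growth models: R-squared against the mean
#' baseline, RMSE with denominator `n - p - 1`, mean error, mean absolute
#' error, mean percentage error (`mean(y - yhat) / ybar`, in percent), mean
#' absolute percentage error (`mean(|y - yhat| / y)`, in percent; zero
#' observations are excluded per row with a warning), the fit index FI
#' (algebraically identical to R-squared; both are reported), and AIC when a
#' log-likelihood is supplied.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param p number of model parameters (for the RMSE denominator and AIC).
#' @param loglik optional log-likelihood for AIC (`-2 LL + 2p`).
#' @param scale label recorded in the report: `"natural"` or `"log"`.
#' @return An object of class `metrics_report` (a list).
#' @export
#' @examples
#' compute_metrics(c(10, 20, 30), c(12, 18, 33), p = 0)
compute_metrics <- function(observed, predicted, p = 0, loglik = NULL,
                            scale = c("natural", "log")) {
  scale <- match.arg(scale)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in length", call. = FALSE)
  }
  n <- length(observed)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  err <- observed - predicted
  sse <- sum(err^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse == 0)
  zero <- observed == 0
  if (any(zero)) {
    warning(sum(zero), " zero observations excluded from MAPE")
  }
  structure(
    list(r2 = r2,
         rmse = sqrt(sse / (n - p - 1)),
         aic = if (!is.null(loglik)) -2 * loglik + 2 * p else NA_real_,
         me = mean(err),
         mae = mean(abs(err)),
         mpe_percent = 100 * mean(err) / mean(observed),
         mape_percent = 100 * mean(abs(err[!zero]) / observed[!zero]),
         fi = if (sst > 0) 1 - sse / sst else as.numeric(sse == 0),
         n = n, p = p, scale = scale),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s scale, n = %d, p = %d)\n", x$scale, x$n, x$p))
  cat(sprintf("  R2 = %.4f  RMSE = %.4f  ME = %.4f  MAE = %.4f\n",
              x$r2, x$rmse, x$me, x$mae))
  cat(sprintf("  MPE%% = %.4f  MAPE%% = %.4f  FI = %.4f  AIC = %.3f\n",
              x$mpe_percent, x$mape_percent, x$fi, x$aic))
  invisible(x)
}
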