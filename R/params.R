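#' Reference coefficient sets for Korean pine branch-growth models
#'
#' Published coefficient estimates for the annual branch length and diameter
#' growth models of plantation-grown Korean pine in Northeast China. Both
#' responses share the same linear predictor on the log scale:
#'
#' \deqn{\log(\Delta) = a_0 + a_1 AGE + a_2 SIZE + a_3 BH + a_4 Dheight +
#'   a_5 BAS + a_6 CLIM + a_7 BAS \cdot CLIM}
#'
#' where `SIZE` is the branch's cumulative length (m) or over-bark basal
#' diameter (mm), `BH` the insertion height (m), `Dheight` the annual tree
#' height increment (m), `BAS` the stand basal area within the competition
#' circle (m2/ha) and `CLIM` the spring climatic moisture deficit (length
#' model, mm) or spring reference evapotranspiration (diameter model, mm).
#'
#' The `"mixed"` sets add a tree-level random-intercept variance `sigma_u2`
#' and residual variance `sigma2` on the log scale.
#'
#' @param response `"length"` (increment in cm) or `"diameter"` (increment in
#'   mm).
#' @param model `"basic"` (single-level OLS) or `"mixed"` (tree-level random
#'   intercept).
#' @return A [growth_params] object.
#' @export
#' @examples
#' reference_params("length", "mixed")
reference_params <- function(response = c("length", "diameter"),
                             model = c("basic", "mixed")) {
  response <- match.arg(response)
  model <- match.arg(model)
  fe <- switch(
    paste(response, model),
    "length basic" = c(a0 = 2.894, a1 = -1.111e-1, a2 = 4.118e-1,
                       a3 = 2.128e-2, a4 = 7.316e-1, a5 = -9.738e-3,
                       a6 = -2.369e-3, a7 = 5.033e-5),
    "length mixed" = c(a0 = 1.992, a1 = -7.064e-2, a2 = 4.667e-1,
                       a3 = 1.707e-1, a4 = 8.047e-1, a5 = -6.997e-2,
                       a6 = -1.985e-4, a7 = 5.077e-5),
    "diameter basic" = c(a0 = 1.117, a1 = -1.321e-1, a2 = 4.023e-2,
                         a3 = 1.911e-2, a4 = 3.889e-1, a5 = -1.355e-2,
                         a6 = -2.043e-3, a7 = 4.806e-5),
    "diameter mixed" = c(a0 = 9.657e-1, a1 = -1.098e-1, a2 = 3.701e-2,
                         a3 = 6.355e-2, a4 = 3.002e-1, a5 = -3.743e-2,
                         a6 = -1.871e-3, a7 = 5.849e-5)
  )
  if (model == "mixed") {
    vc <- switch(response,
                 length = c(sigma2 = 0.2018, sigma_u2 = 0.4013),
                 diameter = c(sigma2 = 0.1673, sigma_u2 = 0.0476))
  } else {
    # Single-level fits report no between-tree variance; the residual level is
    # taken from the corresponding mixed fit so the generator has a noise scale.
    vc <- switch(response,
                 length = c(sigma2 = 0.2018, sigma_u2 = 0),
                 diameter = c(sigma2 = 0.1673, sigma_u2 = 0))
  }
  growth_params(response = response, fixed = fe,
                sigma2 = vc[["sigma2"]], sigma_u2 = vc[["sigma_u2"]],
                rho = 0)
}

#' Generative parameters for the branch-growth simulator
#'
#' Bundles the fixed-effect vector, variance components, AR(1) coefficient and
#' bark power-law parameters that drive [simulate_branch_growth()] and
#' [simulate_replicate_frame()].
#'
#' @param response `"length"` or `"diameter"`.
#' @param fixed named numeric vector `a0..a7` (see [reference_params()]).
#' @param sigma2 residual variance on the log scale (> 0 required only when
#'   noise is generated; 0 gives the noise-free limit).
#' @param sigma_u2 tree-level random-intercept variance (>= 0).
#' @param rho AR(1) coefficient of within-branch log-scale errors, |rho| < 1.
#' @param bark_branch,bark_stem `(a, b)` of the bark coefficient power law
#'   `KB = a * age^b` for branches and stems.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(response = c("length", "diameter"),
                          fixed,
                          sigma2 = 0,
                          sigma_u2 = 0,
                          rho = 0,
                          bark_branch = c(a = 1.34, b = -0.06),
                          bark_stem = c(a = 1.11, b = -0.01)) {
  response <- match.arg(response)
  fixed <- unlist(fixed)
  if (length(fixed) != 8L) {
    stop("`fixed` must hold the eight coefficients a0..a7", call. = FALSE)
  }
  names(fixed) <- paste0("a", 0:7)
  if (!is.numeric(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.numeric(sigma_u2) || sigma_u2 < 0) stop("sigma_u2 must be >= 0", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  structure(
    list(response = response, fixed = fixed, sigma2 = sigma2,
         sigma_u2 = sigma_u2, rho = rho,
         bark_branch = c(a = unname(bark_branch[1]), b = unname(bark_branch[2])),
         bark_stem = c(a = unname(bark_stem[1]), b = unname(bark_stem[2]))),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Branch growth generative parameters (", x$response, " model)\n", sep = "")
  cat("  fixed effects:\n")
  print(signif(x$fixed, 4))
  cat(sprintf("  sigma2 = %.4g  sigma_u2 = %.4g  rho = %.3g\n",
              x$sigma2, x$sigma_u2, x$rho))
  invisible(x)
}

#' Observed covariate ranges of the motivating branch study
#'
#' Minimum/maximum (and mean, sd) of the branch-, tree- and stand-level
#' variables in the 54-tree Korean pine felled-tree dataset that motivates the
#' package. Used as sampling ranges by the synthetic-data generators.
#'
#' Units: `age` years; `bh`, `dinc`, `ht`, `dheight` m; `bl`, `dbl`, `dbh0`,
#' `dg` cm; `bd`, `dbd` mm; `bas`, `bal` m2/ha; `ci`, `rd` unitless.
#'
#' @return A data frame with columns `variable`, `mean`, `max`, `min`, `sd`.
#' @export
covariate_ranges <- function() {
  data.frame(
    variable = c("age", "bh", "dinc", "bl", "bd", "dbl", "dbd",
                 "ht", "dheight", "dbh0", "ddbh0", "ta",
                 "dg", "n_ha", "ci", "rd", "bas", "bal"),
    mean = c(8.61, 14.53, 2.80, 196.39, 23.57, 20.83, 2.52,
             17.33, 0.30, 27.43, 0.51, 47.98,
             27.13, 1666.15, 2.03, 1.01, 27.50, 14.88),
    max = c(34, 24.66, 11.79, 667, 72.85, 66, 12.94,
            24.92, 0.87, 46.33, 2.51, 70,
            36.65, 3531.25, 14.16, 1.59, 48.74, 44.45),
    min = c(1, 2.27, 0.01, 2, 0.99, 2, 0.01,
            3.61, 0.04, 4.30, 0.01, 16,
            9.33, 795.77, 0.15, 0.42, 3.67, 0),
    sd = c(5.77, 4.54, 2.05, 133.71, 14.52, 9.74, 1.32,
           4.14, 0.14, 7.73, 0.30, 12.75,
           6.04, 871.74, 1.77, 0.20, 8.86, 10.90)
  )
}

# internal: look up one range row
.range_of <- function(var) {
  r <- covariate_ranges()
  r[r$variable == var, , drop = FALSE]
}
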