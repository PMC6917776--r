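# Four-parameter-logistic dose-response fitting and mechanism-of-action
# classification from IC50 shifts.
#
# Model: y = bottom + (top - bottom) / (1 + (x / ic50)^hill)
# With hill > 0 this is a descending inhibition curve (y -> top as x -> 0).
# For a substrate-competitive inhibitor IC50([S]) = Ki (1 + [S]/Km), so the
# intercept of IC50 against [S] is Ki; for an uncompetitive (co-substrate-
# dependent) inhibitor IC50([C]) = K (1 + Km/[C]), which falls as [C] rises.

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt least squares of
#' `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)`. IC50 is fitted on the
#' log scale internally. Standard errors come from the Jacobian
#' (delta method for IC50). Non-convergence is flagged, never thrown.
#'
#' @param concentrations molar inhibitor concentrations (> 0).
#' @param responses activity (counts or percent of the no-inhibitor control).
#' @param fix_hill optional fixed Hill slope (e.g. 1 for low-n series).
#' @return list of class `fourpl_fit`: `bottom`, `top`, `ic50`, `hill`,
#'   `se` (named vector), `converged`, `fitted`, `data`.
#' @examples
#' x <- 10^seq(-9, -5, length.out = 8)
#' y <- 100 / (1 + (x / 8e-8))
#' fit_4pl(x, y)$ic50
#' @export
fit_4pl <- function(concentrations, responses, fix_hill = NULL) {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(x) != length(y)) stop("concentration/response length mismatch")
  if (any(!is.finite(x)) || any(x <= 0)) stop("concentrations must be positive and finite")
  if (any(!is.finite(y))) stop("responses must be finite")
  if (length(unique(x)) < 4L) stop("need >= 4 distinct concentrations")
  bad <- list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
              hill = NA_real_, se = c(bottom = NA, top = NA, ic50 = NA, hill = NA),
              converged = FALSE, fitted = rep(NA_real_, length(y)),
              data = data.frame(concentration = x, response = y))
  class(bad) <- "fourpl_fit"
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) return(bad)  # flat: degenerate
  # starting values: responses assumed descending with concentration
  top0 <- max(y); bot0 <- min(y)
  mid <- (top0 + bot0) / 2
  l50 <- log(x[which.min(abs(y - mid))])
  df <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (is.null(fix_hill)) {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (log(x) - l50))),
        data = df,
        start = list(bottom = bot0, top = top0, l50 = l50, hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(fix_hill * (log(x) - l50))),
        data = df,
        start = list(bottom = bot0, top = top0, l50 = l50),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se_of <- function(nm) if (!is.null(sm) && nm %in% rownames(sm)) sm[nm, 2L] else NA_real_
  ic50 <- exp(cf[["l50"]])
  hill <- if (is.null(fix_hill)) cf[["hill"]] else fix_hill
  res <- list(
    bottom = cf[["bottom"]], top = cf[["top"]], ic50 = unname(ic50),
    hill = unname(hill),
    se = c(bottom = se_of("bottom"), top = se_of("top"),
           ic50 = unname(ic50) * se_of("l50"),   # delta method on log scale
           hill = if (is.null(fix_hill)) se_of("hill") else 0),
    converged = TRUE,
    fitted = stats::fitted(fit),
    data = df
  )
  if (res$top <= res$bottom) { # inverted curve: report but flag
    res$converged <- FALSE
  }
  class(res) <- "fourpl_fit"
  res
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<4PL fit> IC50 = %.3g M, hill = %.2f, range [%.3g, %.3g]%s\n",
              x$ic50, x$hill, x$bottom, x$top,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Predicted IC50 for a substrate-competitive inhibitor
#'
#' `IC50 = ki * (1 + s_conc / km_s)`: rises with substrate concentration;
#' the zero-substrate intercept is Ki.
#'
#' @param ki inhibition constant (molar).
#' @param s_conc substrate concentration (molar).
#' @param km_s substrate Michaelis constant (molar).
#' @return IC50 in molar.
#' @export
predict_ic50_competitive <- function(ki, s_conc, km_s) {
  if (any(c(ki, s_conc, km_s) <= 0)) stop("all arguments must be positive")
  ki * (1 + s_conc / km_s)
}

#' Predicted IC50 for an uncompetitive (co-substrate-dependent) inhibitor
#'
#' `IC50 = k * (1 + km_s / s_conc)`: falls as the co-substrate concentration
#' rises.
#'
#' @param k limiting inhibition constant (molar).
#' @param s_conc co-substrate concentration (molar).
#' @param km_s co-substrate Michaelis constant (molar).
#' @return IC50 in molar.
#' @export
predict_ic50_uncompetitive <- function(k, s_conc, km_s) {
  if (any(c(k, s_conc, km_s) <= 0)) stop("all arguments must be positive")
  k * (1 + km_s / s_conc)
}

#' Classify mechanism of action from an IC50-versus-concentration series
#'
#' Linear regression of IC50 on the varied concentration. When per-point
#' standard errors are supplied they are treated as known: the fit is
#' weighted least squares with weights `1/SE^2`, the parameter covariance is
#' `(X'WX)^-1` (not rescaled by the residual variance), and the slope is
#' tested with a z-statistic -- the standard propagation when each point is
#' itself a fitted parameter with its own uncertainty. Without SEs an
#' ordinary unweighted fit with t-tests is used. A slope significantly
#' greater than zero (two-sided at `alpha`) calls a competitive pattern;
#' significantly below zero, uncompetitive; otherwise independent. For a
#' competitive call on the substrate axis the Y-intercept is reported as Ki
#' with its standard error.
#'
#' @param concentrations varied substrate/co-substrate concentrations (molar).
#' @param ic50 fitted IC50 values (molar).
#' @param se optional IC50 standard errors (used as weights `1/se^2`).
#' @param varied_axis `"substrate"` or `"cofactor"` (annotation only).
#' @param alpha significance level for the slope test (default 0.05).
#' @param weighted set `FALSE` for an unweighted fit.
#' @return list of class `moa_call`: `pattern`, `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `p_value`, `ki`, `ki_se` (NA unless
#'   competitive on the substrate axis).
#' @export
classify_moa <- function(concentrations, ic50, se = NULL,
                         varied_axis = c("substrate", "cofactor"),
                         alpha = 0.05, weighted = TRUE) {
  varied_axis <- match.arg(varied_axis)
  x <- as.numeric(concentrations); y <- as.numeric(ic50)
  if (length(x) < 3L) stop("need >= 3 points in the IC50 series")
  if (stats::sd(x) == 0) stop("varied concentrations have zero variance")
  if (weighted && !is.null(se)) {
    if (any(se <= 0)) stop("standard errors must be positive")
    # known-variance WLS: covariance (X'WX)^-1, z-based inference
    X <- cbind(1, x)
    W <- 1 / se^2
    XtWX <- crossprod(X * W, X)
    beta <- solve(XtWX, crossprod(X * W, y))
    covb <- solve(XtWX)
    est <- as.vector(beta)
    ses <- sqrt(diag(covb))
    z <- est[2L] / ses[2L]
    sm <- rbind("(Intercept)" = c(est[1L], ses[1L]),
                "x" = c(est[2L], ses[2L]))
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    fit <- stats::lm(y ~ x)
    smf <- summary(fit)$coefficients
    sm <- smf[, 1:2, drop = FALSE]
    p <- smf["x", 4L]
  }
  slope <- sm["x", 1L]; slope_se <- sm["x", 2L]
  pattern <- if (p < alpha && slope > 0) "competitive"
  else if (p < alpha && slope < 0) "uncompetitive"
  else "independent"
  ki <- ki_se <- NA_real_
  if (pattern == "competitive" && varied_axis == "substrate") {
    ki <- sm["(Intercept)", 1L]; ki_se <- sm["(Intercept)", 2L]
    if (ki <= 0) warning("competitive pattern but non-positive intercept; Ki not reported")
  }
  structure(list(
    pattern = pattern, varied_axis = varied_axis,
    slope = slope, slope_se = slope_se,
    intercept = sm["(Intercept)", 1L], intercept_se = sm["(Intercept)", 2L],
    p_value = p, ki = if (!is.na(ki) && ki > 0) ki else NA_real_,
    ki_se = if (!is.na(ki) && ki > 0) ki_se else NA_real_,
    alpha = alpha, weighted = weighted
  ), class = "moa_call")
}

#' @export
print.moa_call <- function(x, ...) {
  cat(sprintf("<MOA> %s (%s axis), slope %.3g (p = %.3g)",
              x$pattern, x$varied_axis, x$slope, x$p_value))
  if (!is.na(x$ki)) cat(sprintf(", Ki = %.3g M +/- %.2g", x$ki, x$ki_se))
  cat("\n")
  invisible(x)
}
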