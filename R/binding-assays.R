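# Thermal-shift (DSF / NALTSA) and SPR 1:1 Langmuir binding analysis.

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Model: `F(T) = F_pre + (F_post - F_pre) / (1 + exp((Tm - T)/a))`.
#' Tm is the midpoint of the transition (half-maximal signal change); `a`
#' (degrees C) sets the transition width. The fit is flagged when it does not
#' converge, when the fitted transition is inverted (`a < 0`, signal falling
#' with temperature where a melt should rise), or when Tm falls outside the
#' scanned temperature range.
#'
#' @param temperatures degrees C, ascending.
#' @param signal fluorescence/luminescence, arbitrary units.
#' @return list of class `boltzmann_fit`: `tm`, `slope`, `f_pre`, `f_post`,
#'   `se` (named), `converged`, `flags`, `fitted`.
#' @examples
#' tt <- seq(40, 65, by = 0.5)
#' ff <- 10 + 90 / (1 + exp((52 - tt) / 1.2))
#' fit_boltzmann(tt, ff)$tm
#' @export
fit_boltzmann <- function(temperatures, signal) {
  tt <- as.numeric(temperatures); ff <- as.numeric(signal)
  if (length(tt) < 8L) stop("need >= 8 points across the transition")
  if (is.unsorted(tt, strictly = FALSE)) stop("temperatures must be ascending")
  bad <- list(tm = NA_real_, slope = NA_real_, f_pre = NA_real_,
              f_post = NA_real_,
              se = c(tm = NA, slope = NA, f_pre = NA, f_post = NA),
              converged = FALSE, flags = "non_convergence",
              fitted = rep(NA_real_, length(ff)))
  class(bad) <- "boltzmann_fit"
  if (stats::sd(ff) < 1e-12 * max(abs(ff), 1)) {
    bad$flags <- "flat_signal"
    return(bad)
  }
  mid <- (max(ff) + min(ff)) / 2
  tm0 <- tt[which.min(abs(ff - mid))]
  df <- data.frame(tt = tt, ff = ff)
  fit <- tryCatch(
    minpack.lm::nlsLM(ff ~ f_pre + (f_post - f_pre) / (1 + exp((tm - tt) / a)),
                      data = df,
                      start = list(f_pre = min(ff), f_post = max(ff),
                                   tm = tm0, a = diff(range(tt)) / 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se_of <- function(nm) if (!is.null(sm)) sm[nm, 2L] else NA_real_
  flags <- character(0)
  # high-T limit is f_post when a > 0, f_pre when a < 0; a melt must rise
  rising <- (cf[["a"]] > 0) == (cf[["f_post"]] > cf[["f_pre"]])
  if (!rising) flags <- c(flags, "negative_slope_transition")
  if (cf[["tm"]] < min(tt) || cf[["tm"]] > max(tt)) flags <- c(flags, "tm_outside_scan")
  res <- list(
    tm = unname(cf[["tm"]]), slope = unname(cf[["a"]]),
    f_pre = unname(cf[["f_pre"]]), f_post = unname(cf[["f_post"]]),
    se = c(tm = se_of("tm"), slope = se_of("a"),
           f_pre = se_of("f_pre"), f_post = se_of("f_post")),
    converged = length(flags) == 0L,
    flags = if (length(flags)) flags else "ok",
    fitted = stats::fitted(fit)
  )
  class(res) <- "boltzmann_fit"
  res
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<Boltzmann fit> Tm = %.2f C (slope %.2f C) [%s]\n",
              x$tm, x$slope, paste(x$flags, collapse = ",")))
  invisible(x)
}

#' Thermal-shift binding call from apo and ligand-bound melt curves
#'
#' `delta_tm = tm_ligand - tm_apo`. Binding is called significant when
#' `delta_tm` exceeds `threshold` (default 2 degrees C). The comparison mode is
#' `">"` (strict; the DSF convention "greater than 2 C") or `">="` (used for
#' cell-based NALTSA data where a shift of exactly 2 C is reported as
#' engagement).
#'
#' @param apo,holo fitted `boltzmann_fit` objects, or melt-curve data.frames
#'   with columns `temperature` and `signal`.
#' @param threshold degrees C.
#' @param mode `">"` or `">="`.
#' @return list of class `thermal_shift_result`: `tm_apo`, `tm_ligand`,
#'   `delta_tm`, `significant_binding`, SEs.
#' @export
thermal_shift <- function(apo, holo, threshold = 2, mode = c(">", ">=")) {
  mode <- match.arg(mode)
  as_fit <- function(m) {
    if (inherits(m, "boltzmann_fit")) return(m)
    fit_boltzmann(m$temperature, m$signal)
  }
  fa <- as_fit(apo); fh <- as_fit(holo)
  if (!fa$converged || !fh$converged) {
    stop("melt-curve fit did not converge (flags: apo=",
         paste(fa$flags, collapse = ","), "; holo=",
         paste(fh$flags, collapse = ","), ")")
  }
  dtm <- fh$tm - fa$tm
  sig <- if (mode == ">") dtm > threshold else dtm >= threshold
  structure(list(
    tm_apo = fa$tm, tm_apo_se = unname(fa$se["tm"]),
    tm_ligand = fh$tm, tm_ligand_se = unname(fh$se["tm"]),
    delta_tm = dtm, threshold = threshold, mode = mode,
    significant_binding = sig
  ), class = "thermal_shift_result")
}

#' @export
print.thermal_shift_result <- function(x, ...) {
  cat(sprintf("<thermal shift> Tm %.1f -> %.1f C, dTm = %+.2f C: %s\n",
              x$tm_apo, x$tm_ligand, x$delta_tm,
              if (x$significant_binding) "binding" else "no significant binding"))
  invisible(x)
}

# closed-form 1:1 Langmuir trace: association then exponential dissociation
# (fully vectorized over rows so it can serve as a global-fit model)
.langmuir_trace <- function(time, conc, kon, koff, rmax, t_on_end) {
  kobs <- kon * conc + koff
  req <- rmax * kon * conc / kobs
  r_end <- req * (1 - exp(-kobs * t_on_end))
  dis <- time > t_on_end
  r <- req * (1 - exp(-kobs * pmax(time, 0)))
  r[dis] <- (r_end * exp(-koff * (time - t_on_end)))[dis]
  r
}

#' Global kinetic fit of SPR traces to the 1:1 Langmuir model
#'
#' Association phase: `dR/dt = kon C (Rmax - R) - koff R`, giving
#' `R(t) = Req (1 - exp(-(kon C + koff) t))` with
#' `Req = Rmax kon C / (kon C + koff)`. Dissociation phase:
#' `R(t) = R(t_off) exp(-koff (t - t_off))`. All traces share `kon`, `koff`
#' and `Rmax`; rates are fitted on the log scale.
#'
#' @param traces data.frame with columns `time` (s), `response` (RU),
#'   `concentration` (molar), or a list of such per-concentration data.frames.
#' @param t_on_end association end time (s); association is assumed to start
#'   at t = 0.
#' @return list of class `spr_kinetic_fit`: `kon` (1/M/s), `koff` (1/s),
#'   `rmax` (RU), `kd` (= koff/kon, molar), `se` (named), `converged`.
#' @export
fit_spr_kinetic <- function(traces, t_on_end = 60) {
  if (is.data.frame(traces)) df <- traces
  else df <- do.call(rbind, traces)
  need <- c("time", "response", "concentration")
  if (!all(need %in% names(df))) stop("traces need columns: ", paste(need, collapse = ", "))
  concs <- sort(unique(df$concentration[df$concentration > 0]))
  if (length(concs) < 3L) stop("need >= 3 nonzero analyte concentrations")
  # initialization by the classical two-stage route: each association segment
  # is fitted to R = Req (1 - exp(-kobs t)); the regression kobs ~ C then
  # gives kon (slope) and koff (intercept), cross-checked against the
  # log-linear decay of the highest-concentration dissociation segment
  per_trace <- lapply(concs, function(cc) {
    ass <- df[df$concentration == cc & df$time <= t_on_end, ]
    if (nrow(ass) < 4L) return(NULL)
    k0 <- 2 / max(ass$time)
    ft <- tryCatch(
      minpack.lm::nlsLM(response ~ req * (1 - exp(-kobs * time)), data = ass,
                        start = list(req = max(ass$response), kobs = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    c(conc = cc, kobs = stats::coef(ft)[["kobs"]], req = stats::coef(ft)[["req"]])
  })
  per_trace <- do.call(rbind, per_trace)
  top <- df[df$concentration == max(concs), ]
  dis <- top[top$time > t_on_end & top$response > 0, ]
  koff_dis <- if (nrow(dis) >= 3L) {
    k <- tryCatch(spr_dissociation_koff(dis$time, dis$response),
                  error = function(e) NA_real_)
    if (is.finite(k) && k > 0) k else NA_real_
  } else NA_real_
  kon0 <- 1e5; koff0 <- if (is.finite(koff_dis)) koff_dis else 0.05
  rmax0 <- max(df$response) * 1.2
  if (!is.null(per_trace) && nrow(per_trace) >= 2L) {
    cf <- unname(stats::coef(stats::lm(per_trace[, "kobs"] ~ per_trace[, "conc"])))
    if (is.finite(cf[2L]) && cf[2L] > 0) kon0 <- cf[2L]
    if (is.finite(cf[1L]) && cf[1L] > 0 && !is.finite(koff_dis)) koff0 <- cf[1L]
    req_top <- per_trace[which.max(per_trace[, "conc"]), "req"]
    kobs_top <- per_trace[which.max(per_trace[, "conc"]), "kobs"]
    r0 <- req_top * kobs_top / max(kobs_top - koff0, 0.1 * kobs_top)
    if (is.finite(r0) && r0 > 0) rmax0 <- r0
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ .langmuir_trace(time, concentration, exp(lkon), exp(lkoff),
                                 rmax, t_on_end),
      data = df,
      start = list(lkon = log(unname(kon0)), lkoff = log(unname(koff0)),
                   rmax = unname(rmax0)),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(kon = NA_real_, koff = NA_real_, rmax = NA_real_, kd = NA_real_,
                se = c(kon = NA, koff = NA, rmax = NA, kd = NA), converged = FALSE)
    class(out) <- "spr_kinetic_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se_of <- function(nm) if (!is.null(sm)) sm[nm, 2L] else NA_real_
  kon <- exp(cf[["lkon"]]); koff <- exp(cf[["lkoff"]])
  kd <- koff / kon
  se_kon <- kon * se_of("lkon"); se_koff <- koff * se_of("lkoff")
  out <- list(
    kon = kon, koff = koff, rmax = unname(cf[["rmax"]]), kd = kd,
    se = c(kon = se_kon, koff = se_koff, rmax = se_of("rmax"),
           kd = kd * sqrt((se_kon / kon)^2 + (se_koff / koff)^2)),
    converged = TRUE, t_on_end = t_on_end
  )
  class(out) <- "spr_kinetic_fit"
  out
}

#' @export
print.spr_kinetic_fit <- function(x, ...) {
  cat(sprintf("<SPR 1:1 fit> kon = %.3g /M/s, koff = %.3g /s, Kd = %.3g M, Rmax = %.1f RU\n",
              x$kon, x$koff, x$kd, x$rmax))
  invisible(x)
}

#' koff from a pure dissociation segment by log-linear regression
#'
#' @param time seconds (within the dissociation phase).
#' @param response RU, positive and decaying.
#' @return koff in 1/s.
#' @export
spr_dissociation_koff <- function(time, response) {
  keep <- response > 0
  if (sum(keep) < 3L) stop("need >= 3 positive responses in the dissociation segment")
  -unname(stats::coef(stats::lm(log(response[keep]) ~ time[keep]))[2L])
}

#' Steady-state affinity fit of SPR plateau responses
#'
#' Model: `Req = Rmax * C / (Kd + C)`.
#'
#' @param concentration molar analyte concentrations (>= 4 distinct).
#' @param req equilibrium responses (RU).
#' @return list of class `spr_steady_state_fit`: `kd`, `rmax`, `se`,
#'   `converged`, `ill_conditioned` (no curvature in the sampled range).
#' @export
fit_spr_steady_state <- function(concentration, req) {
  x <- as.numeric(concentration); y <- as.numeric(req)
  if (length(unique(x)) < 4L) stop("need >= 4 distinct concentrations")
  df <- data.frame(x = x, y = y)
  kd0 <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ rmax * x / (exp(lkd) + x), data = df,
                      start = list(rmax = max(y) * 1.5, lkd = log(kd0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(kd = NA_real_, rmax = NA_real_, se = c(kd = NA, rmax = NA),
                converged = FALSE, ill_conditioned = NA)
    class(out) <- "spr_steady_state_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  kd <- exp(cf[["lkd"]])
  ill <- kd < min(x) / 50 || kd > max(x) * 50
  if (ill) warning("no curvature in the sampled concentration range; Kd ill-conditioned")
  out <- list(
    kd = kd, rmax = unname(cf[["rmax"]]),
    se = c(kd = if (!is.null(sm)) kd * sm["lkd", 2L] else NA_real_,
           rmax = if (!is.null(sm)) sm["rmax", 2L] else NA_real_),
    converged = TRUE, ill_conditioned = ill
  )
  class(out) <- "spr_steady_state_fit"
  out
}
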