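#' Percent inhibition relative to an untreated control
#'
#' `100 * (1 - treated / untreated)`. Negative values indicate enhanced
#' migration relative to the control and are legitimate results.
#'
#' @param treated_count migrated cell count under treatment.
#' @param untreated_count migrated cell count of the untreated control
#'   (must be > 0).
#' @return Percent inhibition (vectorized).
#' @examples
#' percentInhibition(70, 100)   # 30
#' percentInhibition(105, 100)  # -5
#' @export
percentInhibition <- function(treated_count, untreated_count) {
  if (any(untreated_count <= 0))
    stop("untreated control count must be > 0")
  100 * (1 - treated_count / untreated_count)
}

#' Migration index relative to a reference-treated control
#'
#' Ratio of migrated counts, with the reference-treated (e.g. pepitem)
#' samples set to 1.0 so that designed analogs can be compared against the
#' reference compound.
#'
#' @param treated_count migrated cell count under the test compound.
#' @param reference_count migrated cell count under the reference compound
#'   (must be > 0).
#' @return `treated_count / reference_count` (vectorized).
#' @export
migrationIndex <- function(treated_count, reference_count) {
  if (any(reference_count <= 0))
    stop("reference control count must be > 0")
  treated_count / reference_count
}

.dr_model <- function(logc, log_ec50, bottom, top = 100) {
  bottom + (top - bottom) / (1 + 10^(logc - log_ec50))
}

#' Constrained three-parameter dose-response fit
#'
#' Least-squares fit of
#' \eqn{Y = bottom + (top - bottom)/(1 + 10^{\log_{10} c - \log_{10} EC_{50}})}
#' to responses expressed as % of the untreated control, with the top
#' constrained to 100 and the Hill slope fixed to 1, leaving
#' \eqn{EC_{50}} and the bottom plateau free. The fit is parameterized in
#' \eqn{\log_{10}} concentration and initialized from a deterministic
#' multi-start grid of 5 EC50 values across the observed concentration
#' range; the best-RSS start wins. Replicates are pooled unweighted.
#'
#' @param concentrations positive concentrations (any unit; at least 4
#'   distinct values).
#' @param responses responses, % of untreated control, same length.
#' @param top fixed upper plateau.
#' @param min_signal minimum inhibition depth (% below top) required to call
#'   a signal; flatter data return `converged = FALSE` with reason
#'   `"no inhibition signal"`.
#' @return A \linkS4class{DoseResponseFit}.
#' @examples
#' conc <- 10^seq(-1, 3, length.out = 8)
#' y <- 60 + (100 - 60) / (1 + 10^(log10(conc) - log10(10)))
#' ec50(fitEC50(conc, y))  # 10
#' @export
fitEC50 <- function(concentrations, responses, top = 100, min_signal = 5) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 4L)
    stop("need at least 4 distinct concentrations")
  logc <- log10(concentrations)
  fail <- function(reason) new("DoseResponseFit",
    ec50 = NA_real_, bottom = NA_real_, top = top, slope = 1,
    rss = NA_real_, converged = FALSE, reason = reason)
  # signal check: mean response at some concentration must dip below top
  mr <- tapply(responses, concentrations, mean)
  if ((top - min(mr)) < min_signal) return(fail("no inhibition signal"))

  starts <- seq(min(logc), max(logc), length.out = 5)
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ .dr_model(logc, log_ec50, bottom, top),
        start = list(log_ec50 = s0,
                     bottom = max(min(responses), 0)),
        lower = c(log_ec50 = min(logc) - 6, bottom = -100),
        upper = c(log_ec50 = max(logc) + 6, bottom = top),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, coef = stats::coef(fit))
  }
  if (is.null(best)) return(fail("optimization failed"))
  new("DoseResponseFit", ec50 = 10^best$coef[["log_ec50"]],
      bottom = best$coef[["bottom"]], top = top, slope = 1,
      rss = best$rss, converged = TRUE, reason = "")
}

#' One-phase exponential decay fit (serum stability)
#'
#' Fits \eqn{Y = (y_0 - plateau) e^{-kt} + plateau} to a remaining-peptide
#' time series normalized to 100% at t = 0, with the plateau bounded in
#' [0, 100], and reports the half-life \eqn{t_{1/2} = \ln 2 / k}. Series
#' without a decay signal return `converged = FALSE`; when additionally the
#' last point is still at or above `stable_threshold` the half-life is
#' censored as `"> max(times)"` (the standard notation for stable
#' peptides).
#'
#' @param times time points, hours, including t = 0.
#' @param remaining remaining peptide, % of t = 0.
#' @param min_signal minimum drop (%) below the starting level required to
#'   call decay.
#' @param stable_threshold last-point level (%) at or above which a
#'   non-converged series is labeled censored-stable.
#' @return A \linkS4class{DecayFit}.
#' @examples
#' t <- c(0, 2, 4, 8, 24)
#' y <- 100 * exp(-log(2) / 3.1 * t)
#' halfLife(fitDecay(t, y))  # 3.1
#' @export
fitDecay <- function(times, remaining, min_signal = 5,
                     stable_threshold = 80) {
  stopifnot(length(times) == length(remaining))
  if (length(times) < 3L) stop("need at least 3 time points")
  if (!any(times == 0)) stop("series must include t = 0 (normalized 100%)")
  tmax <- max(times)
  censor <- if (remaining[which.max(times)] >= stable_threshold)
    sprintf(">%g", tmax) else ""
  fail <- function(reason) new("DecayFit",
    k = NA_real_, y0 = NA_real_, plateau = NA_real_, halfLife = NA_real_,
    rss = NA_real_, converged = FALSE, reason = reason,
    censorLabel = censor)
  y0_start <- remaining[which.min(times)]
  if ((y0_start - min(remaining)) < min_signal)
    return(fail("no decay signal"))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      remaining ~ (y0 - plateau) * exp(-k * times) + plateau,
      start = list(k = log(2) / max(tmax / 4, .Machine$double.eps),
                   y0 = y0_start, plateau = max(min(remaining), 0)),
      lower = c(k = 1e-8, y0 = 0, plateau = 0),
      upper = c(k = Inf, y0 = 200, plateau = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimization failed"))
  cf <- stats::coef(fit)
  hl <- log(2) / cf[["k"]]
  if (!is.finite(hl) || hl > 100 * tmax)
    return(fail("decay too slow to resolve within the observed window"))
  new("DecayFit", k = cf[["k"]], y0 = cf[["y0"]],
      plateau = cf[["plateau"]], halfLife = hl,
      rss = sum(stats::residuals(fit)^2), converged = TRUE, reason = "",
      censorLabel = "")
}

#' Transendothelial electrical resistance
#'
#' `TEER [Ohm cm^2] = (resistance of the cell monolayer - resistance of the
#' empty control insert) * insert surface area`.
#'
#' @param resistance_monolayer measured resistance with cells, Ohm.
#' @param resistance_blank resistance of the empty control insert, Ohm.
#' @param area insert surface area, cm^2 (> 0).
#' @return TEER in Ohm cm^2. Negative values (blank above monolayer) are
#'   returned but flagged with a warning.
#' @examples
#' teer(200, 100, 0.33)  # 33
#' @export
teer <- function(resistance_monolayer, resistance_blank, area) {
  if (any(area <= 0)) stop("insert area must be > 0")
  out <- (resistance_monolayer - resistance_blank) * area
  if (any(out < 0))
    warning("negative TEER: blank resistance exceeds monolayer resistance")
  out
}

#' Apparent permeability coefficient
#'
#' `Papp (cm/s) = (C_abluminal * V_abluminal) / (area * C_luminal * t)`.
#' The abluminal volume must be given in cm^3 (mL) for a cm/s result; the
#' two concentrations must share units.
#'
#' @param c_abluminal tracer concentration in the receiver compartment.
#' @param v_abluminal receiver compartment volume, cm^3.
#' @param area insert surface area, cm^2 (> 0).
#' @param c_luminal initial tracer concentration in the donor compartment
#'   (> 0).
#' @param t incubation time, seconds (> 0).
#' @return Papp in cm/s.
#' @examples
#' papp(1, 0.6, 0.33, 100, 4 * 3600)  # ~1.26e-6
#' @export
papp <- function(c_abluminal, v_abluminal, area, c_luminal, t) {
  if (any(area <= 0) || any(c_luminal <= 0) || any(t <= 0) ||
      any(v_abluminal <= 0))
    stop("area, luminal concentration, volume and time must be > 0")
  (c_abluminal * v_abluminal) / (area * c_luminal * t)
}
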