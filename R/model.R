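#' Default plate-reader sampling grid
#'
#' Measurements every 10 minutes over a 16-hour run: 97 time points.
#'
#' @param t_end Horizon (h).
#' @param by Sampling interval (h).
#' @return Strictly increasing numeric vector of times (h).
#' @export
default_grid <- function(t_end = 16, by = 1 / 6) seq(0, t_end, by = by)

#' Ribosome availability
#'
#' Available ribosomes as a function of the ribosomal response coefficient
#' `A` and the baseline level `R_basal`:
#' \deqn{R = A(1 - R_b) + (1 - A) R_b + A R_b = A + R_b (1 - A)}
#' which interpolates from the baseline level at `A = 0` to full availability
#' at `A = 1`.
#'
#' @param A Response coefficient in `[0, 1]`; here coupled to growth as
#'   \eqn{A(t) = \mu(t) / \max_t \mu(t)}.
#' @param R_basal Baseline ribosome level in `[0, 1]`.
#' @return Availability in `[0, 1]`.
#' @export
ribosome_availability <- function(A, R_basal) {
  if (any(A < 0 | A > 1) || any(R_basal < 0 | R_basal > 1))
    stop("ribosome_availability() arguments must lie in [0, 1]")
  A * (1 - R_basal) + (1 - A) * R_basal + A * R_basal
}

#' Simulate the biosensor reporter model
#'
#' Integrates the three-state FdeR biosensor model over a sampling grid:
#' FdeR transcript (mRNA), FdeR protein, and the normalized reporter GFP/OD.
#' \deqn{d(mRNA)/dt = v_{max,PROM} K_{Pk} K_{mRNAp} - \mu\, mRNA -
#'       k_{deg} K_{mRNAdeg}\, mRNA}
#' \deqn{d(FdeR)/dt = k_{FdeR} R\, RBS\, \frac{mRNA}{mRNA + K_{NFdeR}} -
#'       k_{deg,FdeR} K_{lysis} FdeR - \mu\, FdeR}
#' \deqn{d(GFP/OD)/dt = v_{max,NAR} K_P R\, \frac{FdeR^2}{FdeR^2 + 0.5^2} -
#'       k_{deg,GFP} K_{lysis}\, GFP/OD - \mu\, GFP/OD}
#' The dilution rate \eqn{\mu(t)} comes analytically from the double-logistic
#' growth law, and the ribosomal response coefficient is
#' \eqn{A(t) = \mu(t)/\max \mu} (clipped to `[0, 1]`), so translation
#' capacity tracks growth. Induction is the saturating 400 uM naringenin
#' reference, folded into `vmax_NAR`.
#'
#' @param gp A [growth_params()] object.
#' @param kp A [kinetic_params()] object.
#' @param times Strictly increasing sampling grid (h).
#' @param init Named or positional numeric of initial `(mRNA, FDER,
#'   GFP/OD)`; defaults to all zero.
#' @param growth `"dynamic"` (default) for the full growth-coupled model, or
#'   `"frozen"` to hold the population constant (`mu = 0`, `A = 0`), which
#'   isolates the reaction kinetics.
#' @param ctx Optional context label used in error messages.
#' @param rtol,atol Integrator tolerances (adaptive stiff-capable `lsoda`).
#' @return A `biosensor_trajectory` data.frame with columns `time_h`, `od`,
#'   `mrna`, `fder`, `gfp_per_od`; all states non-negative.
#' @export
simulate_biosensor <- function(gp, kp, times = default_grid(),
                               init = c(mrna = 0, fder = 0, gfp_per_od = 0),
                               growth = c("dynamic", "frozen"), ctx = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  growth <- match.arg(growth)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  init <- as.numeric(init)
  if (length(init) != 3L || any(init < 0) || any(!is.finite(init)))
    stop("init must be three non-negative states")

  frozen <- growth == "frozen"
  mu_max <- if (frozen) 0 else mu_max_over(gp, t_end = max(times))

  parms <- c(gp$L1, gp$a1, gp$t1, gp$k1, gp$k2, mu_max,
             as.numeric(frozen),
             kp$vmax_PROM, kp$K_Pk, kp$K_mRNAp, kp$k_deg, kp$K_mRNAdeg,
             kp$K_P, kp$K_lysis, kp$RBS_strength, kp$k_FDER, kp$K_NFDER,
             kp$k_deg_FDER, kp$vmax_NAR, kp$k_deg_GFP, kp$R_basal,
             kp$hill_half, kp$hill_exp)

  out <- tryCatch(
    deSolve::lsoda(y = init, times = times, func = "biosensor_derivs",
                   parms = parms, dllname = "biosensordbtl",
                   initfunc = "biosensor_initmod",
                   rtol = rtol, atol = atol),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(out, "condition") || nrow(out) < length(times) ||
      any(!is.finite(out))) {
    lbl <- if (is.null(ctx)) "" else paste0(" for context ", context_id(ctx))
    stop("biosensor ODE integration failed", lbl, " (parameters: ",
         paste(sprintf("%s=%.3g", names(kp), unlist(kp)), collapse = ", "),
         ")")
  }

  traj <- data.frame(
    time_h = times,
    od = if (frozen) rep(double_logistic(0, gp), length(times))
         else double_logistic(times, gp),
    mrna = pmax(out[, 2], 0),
    fder = pmax(out[, 3], 0),
    gfp_per_od = pmax(out[, 4], 0)
  )
  class(traj) <- c("biosensor_trajectory", "data.frame")
  traj
}

#' Steady-state gain of a reporter trajectory
#'
#' The screening-oriented response summary: the maximum GFP/OD reached over
#' the assay horizon. The horizon maximum stands in for the steady state
#' (responses peak and may then decline through proteolysis and dilution, so
#' the final value can understate the usable signal).
#'
#' @param traj A `biosensor_trajectory` (or anything with a `gfp_per_od`
#'   column).
#' @return Gain in fluorescence/OD units.
#' @export
steady_state_gain <- function(traj) {
  if (is.null(traj$gfp_per_od) || length(traj$gfp_per_od) == 0)
    stop("empty trajectory")
  max(traj$gfp_per_od)
}

#' Gains relative to the best of a set
#'
#' @param gains Numeric vector of absolute gains.
#' @return Percent of the set maximum (the best design scores 100).
#' @export
relative_gain <- function(gains) 100 * gains / max(gains)

#' Half-time of a reporter response
#'
#' The dynamic-regulation-oriented summary: the first time at which GFP/OD
#' reaches 50% of its horizon maximum, linearly interpolated between samples
#' and converted to seconds. If the first sample already exceeds half-max,
#' the first grid time is returned.
#'
#' @param traj A `biosensor_trajectory`.
#' @return Half-time in seconds (divide by 1e3 for the s x 10^3 reporting
#'   convention).
#' @export
half_time <- function(traj) {
  y <- traj$gfp_per_od
  tt <- traj$time_h
  if (is.null(y) || length(y) == 0) stop("empty trajectory")
  ymax <- max(y)
  if (ymax <= 0) stop("no response: reporter signal is identically zero")
  half <- ymax / 2
  if (y[1] >= half) return(tt[1] * 3600)
  i <- which(y >= half)[1]
  # linear interpolation between the bracketing samples
  t_half <- tt[i - 1] + (half - y[i - 1]) * (tt[i] - tt[i - 1]) /
    (y[i] - y[i - 1])
  t_half * 3600
}
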