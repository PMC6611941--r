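#' Mean intracranial pressure over a readout window
#'
#' The scalar "ICP" of a run is the arithmetic time-average of `P_ic` over
#' the final `window` seconds of the trace, long enough to span whole
#' cardiac cycles and taken after the exponential transients (time
#' constants well under a second) have decayed.
#'
#' @param trace A `csf_trace`.
#' @param window Averaging window, s; must not exceed the trace duration.
#' @return Mean ICP in Pa.
#' @export
mean_icp <- function(trace, window = 10) {
  stopifnot(inherits(trace, "csf_trace"))
  t_end <- trace$t[nrow(trace)]
  if (!is.numeric(window) || window <= 0 || window > t_end) {
    stop("'window' must be positive and no longer than the trace",
         call. = FALSE)
  }
  sel <- trace$t >= t_end - window
  if (!any(sel)) stop("empty readout window", call. = FALSE)
  mean(trace$P_ic[sel])
}

#' Shunt efficiency
#'
#' The figure of merit of a shunt: how much of the pathological ICP
#' elevation the shunt removes, relative to the pre-shunt level,
#' `efficiency = (1 - (ICP_after - ICP_healthy) / ICP_before) * 100`.
#' A shunt restoring the healthy ICP exactly scores
#' `(1 - 0/ICP_before) * 100 = 100` percent.
#'
#' @param icp_after Mean ICP with the shunt fitted, Pa.
#' @param icp_healthy Mean ICP of the healthy (normal outflow) brain, Pa.
#' @param icp_before Mean ICP of the untreated pathology, Pa; must be
#'   positive.
#' @return Efficiency in percent.
#' @examples
#' shunt_efficiency(896.131, 709.13, 3648)  # ~95
#' @export
shunt_efficiency <- function(icp_after, icp_healthy, icp_before) {
  if (any(icp_before <= 0)) {
    stop("'icp_before' must be positive", call. = FALSE)
  }
  (1 - (icp_after - icp_healthy) / icp_before) * 100
}

#' Percent increase of ICP over the healthy baseline
#'
#' @param icp Mean ICP of the scenario, Pa.
#' @param icp_healthy Healthy-baseline mean ICP, Pa; must be positive.
#' @return Increase in percent.
#' @examples
#' percent_increase(3648, 709.13)  # ~414
#' @export
percent_increase <- function(icp, icp_healthy) {
  if (any(icp_healthy <= 0)) {
    stop("'icp_healthy' must be positive", call. = FALSE)
  }
  (icp / icp_healthy - 1) * 100
}

#' Compartment volume rates along a trace
#'
#' Recovers the four compartment volume rates from a trace: arterial
#' `dVa/dt = Cai d(P_a - P_ic)/dt`, venous `dVv/dt = Cvi d(P_v - P_ic)/dt`,
#' tissue `dVtiss/dt = -Ctiss dP_ic/dt`, and CSF
#' `dVcsf/dt = q_f - (q_o + q_sh)`. Under the closed-cranium constraint the
#' four rates sum to zero at every instant. Pressure derivatives are
#' central finite differences on the output grid (one-sided at the ends).
#'
#' @param trace A `csf_trace`.
#' @param params A `csf_params` object; defaults to the parameters the
#'   trace was simulated with.
#' @return A data frame with columns `t`, `dVa`, `dVv`, `dVtiss`, `dVcsf`.
#' @export
volume_rates <- function(trace, params = attr(trace, "params")) {
  stopifnot(inherits(trace, "csf_trace"), inherits(params, "csf_params"))
  ddt <- function(x) {
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) /
      (trace$t[3:n] - trace$t[1:(n - 2)])
    d[1] <- (x[2] - x[1]) / (trace$t[2] - trace$t[1])
    d[n] <- (x[n] - x[n - 1]) / (trace$t[n] - trace$t[n - 1])
    d
  }
  data.frame(
    t = trace$t,
    dVa = params$Cai * ddt(trace$P_a - trace$P_ic),
    dVv = params$Cvi * ddt(trace$P_v - trace$P_ic),
    dVtiss = -params$Ctiss * ddt(trace$P_ic),
    dVcsf = trace$q_f - (trace$q_o + trace$q_sh))
}

#' Poiseuille resistance of a catheter
#'
#' Hydraulic resistance of laminar flow through a tube,
#' `R = 8 mu l / (pi r^4)`, relating a shunt catheter's geometry and the
#' fluid viscosity to the resistance it presents: `dP = q R`. The fourth
#' power of the radius makes lumen narrowing (cellular ingrowth, material
#' deposition) the dominant failure mode — halving the radius multiplies
#' the resistance sixteen-fold.
#'
#' @param mu Dynamic viscosity, Pa s.
#' @param l Tube length, m.
#' @param r Inner radius, m.
#' @return Hydraulic resistance in Pa s / m^3.
#' @examples
#' poiseuille_resistance(1, pi / 8, 1)  # 1
#' @export
poiseuille_resistance <- function(mu, l, r) {
  if (any(mu <= 0) || any(l <= 0) || any(r <= 0)) {
    stop("'mu', 'l' and 'r' must all be positive", call. = FALSE)
  }
  8 * mu * l / (pi * r^4)
}

#' Shunt resistance achieving a target efficiency
#'
#' Design tool: finds the constant shunt resistance whose simulated
#' efficiency, for the pathology described by `params` (e.g. `Ro = 10` for
#' severe hydrocephalus) against a healthy baseline simulated with
#' `Ro = Ro_healthy`, equals `target_eff`. Efficiency is monotone
#' decreasing in the shunt resistance, so the root is unique. The search is
#' bracketed using the analytic DC solution and then refined on the full
#' pulsatile simulation to within 0.1 percentage points.
#'
#' @param target_eff Target efficiency, percent, in (0, 100].
#' @param params A `csf_params` object with the pathological `Ro`.
#' @param settings A `csf_settings` object used for every run.
#' @param Ro_healthy Outflow resistance of the healthy baseline, ohm.
#' @param window Readout window passed to [mean_icp()], s.
#' @return Shunt resistance in ohm.
#' @examples
#' \donttest{
#' resistance_for_efficiency(80, model_parameters(Ro = 10))  # ~3 ohm
#' }
#' @export
resistance_for_efficiency <- function(target_eff,
                                      params = model_parameters(Ro = 10),
                                      settings = simulation_settings(),
                                      Ro_healthy = 1,
                                      window = 10) {
  if (!is.numeric(target_eff) || length(target_eff) != 1L ||
      target_eff <= 0 || target_eff > 100) {
    stop("'target_eff' must be in (0, 100]", call. = FALSE)
  }
  healthy_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(Ro = Ro_healthy)))
  icp_healthy <- mean_icp(simulate_circuit(healthy_params,
                                           settings = settings), window)
  icp_before <- mean_icp(simulate_circuit(params, settings = settings),
                         window)
  eff_sim <- function(rsh) {
    icp_after <- mean_icp(
      simulate_circuit(params, shunt_constant(rsh), settings), window)
    shunt_efficiency(icp_after, icp_healthy, icp_before)
  }
  # analytic DC pre-bracket: efficiency from the linear steady state
  eff_dc <- function(rsh) {
    shunt_efficiency(dc_steady_state(params, rsh)[["P_ic"]],
                     dc_steady_state(healthy_params)[["P_ic"]],
                     dc_steady_state(params)[["P_ic"]])
  }
  root_dc <- tryCatch(
    stats::uniroot(function(r) eff_dc(r) - target_eff,
                   interval = c(1e-3, 1e3), tol = 1e-6)$root,
    error = function(e) NA_real_)
  if (is.na(root_dc)) {
    stop(sprintf("target efficiency %.2f%% is unattainable for this pathology",
                 target_eff), call. = FALSE)
  }
  lo <- root_dc / 2
  hi <- root_dc * 2
  f <- function(r) eff_sim(r) - target_eff
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    stop(sprintf("target efficiency %.2f%% is unattainable for this pathology",
                 target_eff), call. = FALSE)
  }
  root <- stats::uniroot(f, lower = lo, upper = hi,
                         f.lower = flo, f.upper = fhi,
                         tol = root_dc * 1e-4)$root
  achieved <- eff_sim(root)
  if (abs(achieved - target_eff) > 0.1) {
    stop(sprintf(
      "root refinement stopped %.3f pp away from the %.2f%% target",
      abs(achieved - target_eff), target_eff), call. = FALSE)
  }
  root
}
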