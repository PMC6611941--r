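#' Named simulation scenarios
#'
#' A scenario bundles the outflow-resistance pathology, the shunt branch
#' and the simulation settings for the standard experiments:
#'
#' * `normal` — healthy brain, `Ro = 1` ohm, no shunt.
#' * `moderate` — moderate hydrocephalus, `Ro = 5` ohm, no shunt.
#' * `severe` — severe hydrocephalus, `Ro = 10` ohm, no shunt.
#' * `shunt_fixed` — severe pathology treated with a constant-resistance
#'   shunt (default `Rshunt = 1.11111` ohm, the near-perfect shunt whose
#'   parallel combination with `Ro = 10` restores the healthy outflow
#'   resistance of 1 ohm).
#' * `shunt_blocked` — severe pathology with an occluded shunt,
#'   `Rshunt = 100` ohm.
#' * `shunt_timevarying` — severe pathology with the time-varying
#'   malfunction shunt, simulated for 15 s from the untreated severe
#'   steady state.
#'
#' @param id Scenario identifier, one of the names above.
#' @param Ro Optional outflow-resistance override, ohm.
#' @param rshunt Optional constant shunt resistance override, ohm (constant
#'   shunt scenarios only).
#' @param settings Optional `csf_settings` override.
#' @return An object of class `csf_scenario`.
#' @examples
#' scenario("severe")
#' scenario("shunt_fixed", rshunt = 2.5)
#' @export
scenario <- function(id = c("normal", "moderate", "severe", "shunt_fixed",
                            "shunt_blocked", "shunt_timevarying"),
                     Ro = NULL, rshunt = NULL, settings = NULL) {
  id <- match.arg(id)
  def <- switch(id,
    normal = list(Ro = 1, shunt = shunt_absent()),
    moderate = list(Ro = 5, shunt = shunt_absent()),
    severe = list(Ro = 10, shunt = shunt_absent()),
    shunt_fixed = list(Ro = 10, shunt = shunt_constant(1.11111)),
    shunt_blocked = list(Ro = 10, shunt = shunt_constant(100)),
    shunt_timevarying = list(Ro = 10, shunt = shunt_time_varying()))
  if (!is.null(Ro)) def$Ro <- Ro
  if (!is.null(rshunt)) {
    if (def$shunt$kind == "time_varying") {
      stop("'rshunt' does not apply to the time-varying shunt scenario",
           call. = FALSE)
    }
    def$shunt <- shunt_constant(rshunt)
  }
  if (is.null(settings)) {
    settings <- if (id == "shunt_timevarying") {
      simulation_settings(t_end = 15)
    } else {
      simulation_settings()
    }
  }
  structure(list(id = id, Ro = def$Ro, shunt = def$shunt,
                 settings = settings),
            class = "csf_scenario")
}

#' @export
print.csf_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': Ro = %g ohm, t_end = %g s\n",
              x$id, x$Ro, x$settings$t_end))
  print(x$shunt)
  invisible(x)
}

#' Run a scenario end to end
#'
#' Simulates the scenario and summarises it: mean ICP over the readout
#' window, percent increase relative to a fresh normal-scenario run under
#' identical settings, and (when a shunt is fitted) the shunt efficiency
#' computed against the healthy baseline and the same-pathology no-shunt
#' run. The time-varying scenario starts from the untreated severe DC
#' steady state, matching a patient whose ICP is elevated when the shunt
#' starts operating; all other scenarios start from the reference state.
#'
#' @param scn A `csf_scenario` (or an id string accepted by [scenario()]).
#' @param params A `csf_params` object; its `Ro` is overridden by the
#'   scenario's.
#' @param window Readout window for [mean_icp()], s.
#' @return A list of class `csf_run` with elements `result` (a
#'   `csf_result`) and `trace` (a `csf_trace`).
#' @examples
#' \donttest{
#' run_scenario("moderate")$result
#' }
#' @export
run_scenario <- function(scn = scenario("normal"),
                         params = model_parameters(),
                         window = 10) {
  if (is.character(scn)) scn <- scenario(scn)
  stopifnot(inherits(scn, "csf_scenario"), inherits(params, "csf_params"))
  p <- with_ro(params, scn$Ro)
  log_info("scenario '%s': Ro = %g ohm, shunt %s, t_end = %g s, window = %g s",
           scn$id, scn$Ro, scn$shunt$kind, scn$settings$t_end, window)

  init <- if (scn$id == "shunt_timevarying") dc_state(p, NA) else NULL
  trace <- simulate_circuit(p, scn$shunt, scn$settings, init = init)
  icp <- mean_icp(trace, window = min(window, scn$settings$t_end))

  p_norm <- with_ro(params, 1)
  icp_healthy <- if (scn$id == "normal" && identical(scn$Ro, 1)) {
    icp
  } else {
    mean_icp(simulate_circuit(p_norm, settings = norm_settings(scn$settings)),
             window)
  }
  pct <- percent_increase(icp, icp_healthy)

  eff <- NA_real_
  rsh <- NA_real_
  if (scn$shunt$kind != "absent") {
    icp_before <- mean_icp(
      simulate_circuit(p, settings = norm_settings(scn$settings)), window)
    eff <- shunt_efficiency(icp, icp_healthy, icp_before)
    rsh <- if (scn$shunt$kind == "constant") scn$shunt$Rshunt else NA_real_
  }
  solver <- attr(trace, "solver")
  if (!is.null(solver)) {
    log_info("solver: %d steps, %d rhs evaluations",
             solver[["steps"]], solver[["rhs_evals"]])
  }
  result <- structure(
    list(scenario_id = scn$id,
         mean_icp = icp,
         mean_icp_mmhg = pa_to_mmhg(icp, params),
         percent_increase = pct,
         efficiency = eff,
         rshunt = rsh,
         Ro = scn$Ro,
         params = p),
    class = "csf_result")
  structure(list(result = result, trace = trace), class = "csf_run")
}

with_ro <- function(params, Ro) {
  do.call(model_parameters,
          utils::modifyList(unclass(params), list(Ro = Ro)))
}

# identical solver controls, default 60 s horizon for baselines
norm_settings <- function(settings) {
  simulation_settings(t_end = max(settings$t_end, 60),
                      dt_out = settings$dt_out,
                      rel_tol = settings$rel_tol,
                      abs_tol = settings$abs_tol)
}

#' @export
print.csf_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (Ro = %g ohm)\n", x$scenario_id, x$Ro))
  cat(sprintf("  mean ICP: %.3f Pa (%.2f mmHg)\n",
              x$mean_icp, x$mean_icp_mmhg))
  cat(sprintf("  increase vs normal: %.1f%%\n", x$percent_increase))
  if (!is.na(x$efficiency)) {
    cat(sprintf("  shunt efficiency: %.1f%%", x$efficiency))
    if (!is.na(x$rshunt)) cat(sprintf(" (Rshunt = %g ohm)", x$rshunt))
    cat("\n")
  }
  invisible(x)
}

#' Sweep of constant-shunt resistances under severe pathology
#'
#' Simulates the severe pathology (`Ro = 10` ohm) for each shunt resistance
#' in `rshunt_grid` and tabulates mean ICP and shunt efficiency, with the
#' healthy and untreated baselines simulated once under the same settings.
#'
#' @param params A `csf_params` object.
#' @param rshunt_grid Shunt resistances to sweep, ohm.
#' @param Ro Pathological outflow resistance, ohm.
#' @param settings A `csf_settings` object.
#' @param window Readout window, s.
#' @return A data frame with columns `rshunt_ohm`, `icp_pa`, `icp_mmhg`,
#'   `efficiency_pct`.
#' @examples
#' \donttest{
#' run_table2_sweep()
#' }
#' @export
run_table2_sweep <- function(params = model_parameters(),
                             rshunt_grid = c(1.11111, 1.5, 2, 2.5, 3),
                             Ro = 10,
                             settings = simulation_settings(),
                             window = 10) {
  p <- with_ro(params, Ro)
  icp_healthy <- mean_icp(
    simulate_circuit(with_ro(params, 1), settings = settings), window)
  icp_before <- mean_icp(simulate_circuit(p, settings = settings), window)
  icp <- vapply(rshunt_grid, function(rsh) {
    mean_icp(simulate_circuit(p, shunt_constant(rsh), settings), window)
  }, numeric(1))
  data.frame(rshunt_ohm = rshunt_grid,
             icp_pa = icp,
             icp_mmhg = pa_to_mmhg(icp, params),
             efficiency_pct = shunt_efficiency(icp, icp_healthy, icp_before))
}

#' Time-varying (malfunctioning) shunt experiment
#'
#' Severe pathology (`Ro = 10` ohm) treated with the decaying oscillatory
#' shunt resistance `15 exp(-0.3 t)(1.2 + sin t)` ohm, started from the
#' untreated severe steady state and followed for 15 s: the resistance is
#' initially high (valve closed, ICP stays elevated), falls as the
#' envelope decays (valve opens, ICP drops toward normal), and eventually
#' becomes so low that the shunt over-drains.
#'
#' @param params A `csf_params` object.
#' @param settings A `csf_settings` object (default 15 s horizon).
#' @return A `csf_trace`.
#' @export
run_timevarying_shunt <- function(params = model_parameters(),
                                  settings = simulation_settings(t_end = 15)) {
  run_scenario(scenario("shunt_timevarying", settings = settings),
               params = params)$trace
}

#' Write a scenario summary as JSON
#'
#' @param result A `csf_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path) {
  stopifnot(inherits(result, "csf_result"))
  out <- list(scenario = result$scenario_id,
              ro_ohm = result$Ro,
              mean_icp_pa = result$mean_icp,
              mean_icp_mmhg = result$mean_icp_mmhg,
              percent_increase = result$percent_increase,
              efficiency = result$efficiency,
              rshunt = result$rshunt)
  out <- out[!vapply(out, function(x) is.numeric(x) && is.na(x), logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# INFO-level logging, enabled with options(csfshunt.verbose = TRUE)
log_info <- function(fmt, ...) {
  if (isTRUE(getOption("csfshunt.verbose", FALSE))) {
    message(sprintf(paste0("[csfshunt] ", fmt), ...))
  }
  invisible(NULL)
}
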