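#' Simulation settings
#'
#' Numerical controls for the transient simulation: total simulated time,
#' output grid spacing, and the relative/absolute tolerances handed to the
#' adaptive stiff-capable integrator (`deSolve::lsoda`). The ideal-valve
#' nonlinearity `max(dP, 0)/R` is continuous and piecewise linear, so no
#' event detection is needed.
#'
#' @param t_end Simulated duration, s.
#' @param dt_out Output grid spacing, s.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @param init_mode `"zeros"` starts the state at the reference pressure;
#'   `"dc"` starts at the DC steady state of the scenario being run.
#' @return An object of class `csf_settings`.
#' @export
simulation_settings <- function(t_end = 60, dt_out = 0.01,
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                init_mode = c("zeros", "dc")) {
  init_mode <- match.arg(init_mode)
  for (nm in c("t_end", "dt_out", "rel_tol", "abs_tol")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm),
           call. = FALSE)
    }
  }
  structure(list(t_end = t_end, dt_out = dt_out,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 init_mode = init_mode),
            class = "csf_settings")
}

#' Capillary node pressure
#'
#' The capillary node is the only node of the circuit without a compliance,
#' so its pressure is algebraic: the unique `P_c` balancing the currents
#' `(P_a - P_c)/R2 = (P_c - P_v)/R3 + f_df (P_c - P_ic)/Rf`, where the
#' formation-valve flag `f_df` is 1 when the choroid-plexus branch conducts
#' (`P_c > P_ic`) and 0 otherwise. The flag is resolved by a two-case fixed
#' point: if the conducting solution has `P_c >= P_ic` it is kept, otherwise
#' the branch is open and the non-conducting solution applies (the two cases
#' agree at the switching boundary, so the result is continuous).
#'
#' @param P_a,P_v,P_ic Arterial, venous and intracranial pressures, Pa
#'   (vectorised).
#' @param params A `csf_params` object.
#' @return Capillary pressure `P_c` in Pa.
#' @export
capillary_pressure <- function(P_a, P_v, P_ic, params = model_parameters()) {
  g2 <- 1 / params$R2
  g3 <- 1 / params$R3
  gf <- 1 / params$Rf
  pc_on <- (P_a * g2 + P_v * g3 + P_ic * gf) / (g2 + g3 + gf)
  pc_off <- (P_a * g2 + P_v * g3) / (g2 + g3)
  ifelse(pc_on >= P_ic, pc_on, pc_off)
}

# Branch flows through the ideal one-way valves at given node pressures.
# A valve conducts only for positive driving pressure; flow at dP = 0 is 0.
branch_flows <- function(t, P_c, P_ic, params, shunt) {
  q_f <- pmax(P_c - P_ic, 0) / params$Rf
  q_o <- pmax(P_ic - params$P_vs, 0) / params$Ro
  if (shunt$kind == "absent") {
    q_sh <- rep_len(0, length(P_ic))
  } else {
    rsh <- shunt_resistance_at(t, shunt)
    dp <- P_ic - params$P_vs
    if (shunt$has_valve) dp <- pmax(dp, 0)
    q_sh <- dp / rsh
  }
  list(q_f = q_f, q_o = q_o, q_sh = q_sh)
}

#' Time derivative of the circuit state
#'
#' The state holds the three independent compliance pressure differences:
#' `u_ai = P_a - P_ic` (arterial-intracranial), `u_vi = P_v - P_ic`
#' (venous-intracranial) and `u_ic = P_ic` (brain tissue, relative to
#' reference). Kirchhoff current balances at the arterial and venous nodes
#' give the first two derivatives; the third is the closed-cranium volume
#' conservation (the Monro-Kellie constraint: the compartment volume rates
#' sum to zero) rearranged for `dP_ic/dt`:
#'
#' \preformatted{
#' du_ai/dt = [ (P_src(t) - P_a)/R1 - (P_a - P_c)/R2 ] / Cai
#' du_vi/dt = [ (P_c - P_v)/R3 - P_v/R4 ] / Cvi
#' du_ic/dt = [ Cai du_ai/dt + Cvi du_vi/dt + q_f - q_o - q_sh ] / Ctiss
#' }
#'
#' with CSF formation `q_f = max(P_c - P_ic, 0)/Rf`, arachnoid absorption
#' `q_o = max(P_ic - P_vs, 0)/Ro` and shunt drainage
#' `q_sh = max(P_ic - P_vs, 0)/Rshunt(t)` (zero when no shunt is fitted).
#' Both drainage branches terminate at the sagittal-sinus reference
#' pressure `P_vs`.
#'
#' @param t Time, s.
#' @param state Numeric vector `c(u_ai, u_vi, u_ic)` in Pa.
#' @param params A `csf_params` object.
#' @param shunt A `csf_shunt` object.
#' @return A list in `deSolve` form: the derivative vector, then a named
#'   vector of auxiliary outputs (node pressures and branch flows).
#' @export
ode_rhs <- function(t, state, params = model_parameters(),
                    shunt = shunt_absent()) {
  u_ai <- state[[1L]]
  u_vi <- state[[2L]]
  P_ic <- state[[3L]]
  P_a <- u_ai + P_ic
  P_v <- u_vi + P_ic
  P_c <- capillary_pressure(P_a, P_v, P_ic, params)
  q <- branch_flows(t, P_c, P_ic, params, shunt)

  p_src <- arterial_source(t, params)
  cbf <- (p_src - P_a) / params$R1
  d_ai <- (cbf - (P_a - P_c) / params$R2) / params$Cai
  d_vi <- ((P_c - P_v) / params$R3 - P_v / params$R4) / params$Cvi
  d_ic <- (params$Cai * d_ai + params$Cvi * d_vi +
             q$q_f - q$q_o - q$q_sh) / params$Ctiss

  list(c(d_ai, d_vi, d_ic),
       c(P_src = p_src, P_a = P_a, P_c = P_c, P_v = P_v,
         q_f = q$q_f, q_o = q$q_o, q_sh = q$q_sh, cbf = cbf))
}

#' Analytic DC steady state of the circuit
#'
#' With the source held at its offset, the compliances fully charged (no
#' current) and every one-way valve assumed conducting, the circuit is
#' linear and the four node pressures satisfy the current balances
#'
#' \preformatted{
#' (src_offset - P_a)/R1 = (P_a - P_c)/R2
#' (P_a - P_c)/R2 = (P_c - P_v)/R3 + (P_c - P_ic)/Rf
#' (P_c - P_ic)/Rf = (P_ic - P_vs)/R_eff
#' (P_c - P_v)/R3 = P_v/R4
#' }
#'
#' where `R_eff` is the parallel combination of `Ro` and the shunt
#' resistance (or `Ro` alone with no shunt). The solution is the reference
#' point the transient simulation converges to when the pulsatile
#' amplitudes are zero, and serves as an independent oracle for it. The
#' conducting-valve assumption is checked on the solution; parameters for
#' which it fails are rejected rather than silently mis-solved.
#'
#' @param params A `csf_params` object.
#' @param shunt_resistance Constant shunt resistance in ohm, or `NA` for no
#'   shunt.
#' @return Named numeric vector with `P_a`, `P_c`, `P_v`, `P_ic` in Pa.
#' @examples
#' dc_steady_state(model_parameters())["P_ic"]            # healthy, ~706 Pa
#' dc_steady_state(model_parameters(Ro = 10))["P_ic"]     # severe, ~3645 Pa
#' @export
dc_steady_state <- function(params = model_parameters(),
                            shunt_resistance = NA) {
  r_eff <- if (is.na(shunt_resistance)) {
    params$Ro
  } else {
    if (shunt_resistance <= 0) {
      stop("'shunt_resistance' must be positive", call. = FALSE)
    }
    1 / (1 / params$Ro + 1 / shunt_resistance)
  }
  g1 <- 1 / params$R1; g2 <- 1 / params$R2; g3 <- 1 / params$R3
  g4 <- 1 / params$R4; gf <- 1 / params$Rf; ge <- 1 / r_eff
  # unknowns x = (P_a, P_c, P_v, P_ic)
  A <- rbind(
    c(-g1 - g2, g2,             0,        0),
    c(g2,       -g2 - g3 - gf,  g3,       gf),
    c(0,        gf,             0,        -gf - ge),
    c(0,        g3,             -g3 - g4, 0))
  b <- c(-params$src_offset * g1, 0, -params$P_vs * ge, 0)
  x <- drop(solve(A, b))
  names(x) <- c("P_a", "P_c", "P_v", "P_ic")
  if (x[["P_c"]] < x[["P_ic"]] || x[["P_ic"]] < params$P_vs) {
    stop("ideal-valve conducting assumption fails for these parameters; ",
         "no all-conducting DC operating point exists", call. = FALSE)
  }
  x
}

#' Simulate the CSF circuit
#'
#' Integrates the circuit state over `[0, t_end]` with the stiff-capable
#' adaptive integrator `deSolve::lsoda` and returns the pressure and flow
#' trace sampled on a uniform grid. The trace carries the arterial source
#' value, all four node pressures, the three valve-gated CSF flows
#' (formation, arachnoid absorption, shunt) and the cerebral blood flow
#' (the current through the source series resistance `R1`).
#'
#' @param params A `csf_params` object.
#' @param shunt A `csf_shunt` object.
#' @param settings A `csf_settings` object.
#' @param init Optional numeric initial state `c(u_ai, u_vi, u_ic)` in Pa;
#'   overrides `settings$init_mode`.
#' @return A data frame of class `csf_trace` with columns `t`, `P_a`,
#'   `P_c`, `P_v`, `P_ic`, `q_f`, `q_o`, `q_sh`, `cbf`, `P_src`. The
#'   parameters, shunt and settings used are attached as attributes.
#' @examples
#' tr <- simulate_circuit(model_parameters(),
#'                        settings = simulation_settings(t_end = 5))
#' tail(tr$P_ic, 1)
#' @export
simulate_circuit <- function(params = model_parameters(),
                             shunt = shunt_absent(),
                             settings = simulation_settings(),
                             init = NULL) {
  stopifnot(inherits(params, "csf_params"), inherits(shunt, "csf_shunt"),
            inherits(settings, "csf_settings"))
  if (is.null(init)) {
    init <- if (settings$init_mode == "dc") {
      rsh <- switch(shunt$kind,
                    absent = NA,
                    constant = shunt$Rshunt,
                    time_varying = shunt_resistance_at(0, shunt))
      dc_state(params, rsh)
    } else {
      c(0, 0, 0)
    }
  }
  stopifnot(is.numeric(init), length(init) == 3L)
  times <- seq(0, settings$t_end, by = settings$dt_out)
  sol <- deSolve::lsoda(
    y = c(u_ai = init[[1L]], u_vi = init[[2L]], u_ic = init[[3L]]),
    times = times,
    func = function(t, y, parms) ode_rhs(t, y, params, shunt),
    parms = NULL,
    rtol = settings$rel_tol, atol = settings$abs_tol)
  attr_diag <- diagnostics_text(sol)
  if (nrow(sol) < length(times)) {
    stop(sprintf("integration failed at t = %.4f s", sol[nrow(sol), 1L]),
         call. = FALSE)
  }
  out <- as.data.frame(sol)
  trace <- data.frame(t = out$time,
                      P_a = out$P_a, P_c = out$P_c, P_v = out$P_v,
                      P_ic = out$u_ic,
                      q_f = out$q_f, q_o = out$q_o, q_sh = out$q_sh,
                      cbf = out$cbf, P_src = out$P_src)
  structure(trace,
            class = c("csf_trace", "data.frame"),
            params = params, shunt = shunt, settings = settings,
            solver = attr_diag)
}

# state vector (u_ai, u_vi, u_ic) at the DC operating point
dc_state <- function(params, shunt_resistance = NA) {
  p <- dc_steady_state(params, shunt_resistance)
  c(p[["P_a"]] - p[["P_ic"]], p[["P_v"]] - p[["P_ic"]], p[["P_ic"]])
}

diagnostics_text <- function(sol) {
  istate <- attr(sol, "istate")
  if (is.null(istate)) return(NULL)
  c(steps = istate[3L], rhs_evals = istate[4L])
}

#' @export
print.csf_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("CSF circuit trace: %d samples over %.3g s\n", n, x$t[n]))
  cat(sprintf("  final P_ic = %.4g Pa (%.3g mmHg)\n", x$P_ic[n],
              pa_to_mmhg(x$P_ic[n], attr(x, "params"))))
  invisible(x)
}

#' Write a trace to CSV
#'
#' @param trace A `csf_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "csf_trace"))
  cols <- c("t", "P_a", "P_c", "P_v", "P_ic", "q_f", "q_o", "q_sh", "cbf",
            "P_src")
  utils::write.csv(as.data.frame(trace)[, cols], path, row.names = FALSE)
  invisible(path)
}
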