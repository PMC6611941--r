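# Shared simulation runs, computed once per test session. Every entry is a
# deterministic function of the default parameters, so caching cannot leak
# state between tests.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

# pulsatile 60 s trace for a given outflow resistance / constant shunt
sim_trace <- function(Ro, rshunt = NA) {
  key <- sprintf("trace_Ro%g_Rsh%g", Ro, rshunt)
  cached(key, {
    shunt <- if (is.na(rshunt)) shunt_absent() else shunt_constant(rshunt)
    simulate_circuit(model_parameters(Ro = Ro), shunt)
  })
}

sim_icp <- function(Ro, rshunt = NA, window = 10) {
  mean_icp(sim_trace(Ro, rshunt), window = window)
}

timevarying_trace <- function() {
  cached("trace_tv", run_timevarying_shunt())
}

# independent DC oracle: brute-force linear solve of the four Kirchhoff
# current balances, written without reference to the package internals
oracle_dc_icp <- function(Ro, rshunt = NA, p = model_parameters()) {
  reff <- if (is.na(rshunt)) Ro else Ro * rshunt / (Ro + rshunt)
  A <- matrix(0, 4, 4)
  b <- numeric(4)
  # x = (P_a, P_c, P_v, P_ic)
  A[1, ] <- c(1 / p$R1 + 1 / p$R2, -1 / p$R2, 0, 0)
  b[1] <- p$src_offset / p$R1
  A[2, ] <- c(-1 / p$R2, 1 / p$R2 + 1 / p$R3 + 1 / p$Rf, -1 / p$R3,
              -1 / p$Rf)
  A[3, ] <- c(0, -1 / p$Rf, 0, 1 / p$Rf + 1 / reff)
  b[3] <- p$P_vs / reff
  A[4, ] <- c(0, -1 / p$R3, 1 / p$R3 + 1 / p$R4, 0)
  x <- solve(A, b)
  c(P_a = x[1], P_c = x[2], P_v = x[3], P_ic = x[4])
}

# fabricate a minimal constant trace for pure-arithmetic metric tests
constant_trace <- function(value, t_end = 5, dt = 0.1) {
  t <- seq(0, t_end, by = dt)
  structure(data.frame(t = t, P_a = value, P_c = value, P_v = value,
                       P_ic = value, q_f = 0, q_o = 0, q_sh = 0,
                       cbf = 0, P_src = value),
            class = c("csf_trace", "data.frame"),
            params = model_parameters())
}
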