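test_that("capillary pressure solves the node balance by hand cases", {
  # no formation flow and equal endpoints: node floats at the endpoints
  p_eq <- model_parameters()
  expect_equal(capillary_pressure(100, 100, 1e6, p_eq), 100)
  # symmetric three-resistor case: (3 - Pc) = (Pc - 0) + (Pc - 0) => Pc = 1
  p_sym <- model_parameters(R2 = 2, R3 = 2, Rf = 2)
  expect_equal(capillary_pressure(3, 0, 0, p_sym), 1)
  # normal DC operating point: P_c is six times P_ic
  dc <- dc_steady_state(model_parameters())
  pc <- capillary_pressure(dc[["P_a"]], dc[["P_v"]], dc[["P_ic"]],
                           model_parameters())
  expect_equal(pc, dc[["P_c"]], tolerance = 1e-12)
  expect_equal(pc / dc[["P_ic"]], 6, tolerance = 1e-2)
})

test_that("capillary pressure is continuous across the valve switch", {
  p <- model_parameters()
  # scan P_ic through the switching point and look for a jump
  pic <- seq(3000, 6000, by = 1)
  pc <- capillary_pressure(8000, 2000, pic, p)
  expect_lt(max(abs(diff(pc))), 1.5)  # slope-bounded, no discontinuity
})

test_that("the unforced network at reference pressure is an equilibrium", {
  p0 <- model_parameters(src_amp1 = 0, src_amp2 = 0, src_offset = 0)
  d <- ode_rhs(0, c(0, 0, 0), p0, shunt_absent())
  expect_identical(d[[1]], c(0, 0, 0))
})

test_that("the DC steady state is a fixed point of the dynamics", {
  for (ro in c(1, 5, 10)) {
    p <- model_parameters(Ro = ro, src_amp1 = 0, src_amp2 = 0)
    dc <- dc_steady_state(p)
    state <- c(dc[["P_a"]] - dc[["P_ic"]], dc[["P_v"]] - dc[["P_ic"]],
               dc[["P_ic"]])
    d <- ode_rhs(0.25, state, p, shunt_absent())[[1]]
    expect_lt(max(abs(d)), 1e-8)
  }
})

test_that("drainage valves block backflow when ICP is below sinus pressure", {
  p <- model_parameters()
  # intracranial pressure below the drainage reference
  d <- ode_rhs(0, c(500, 200, -50), p, shunt_constant(1.25))
  aux <- d[[2]]
  expect_identical(aux[["q_o"]], 0)
  expect_identical(aux[["q_sh"]], 0)
})

test_that("DC solve matches an independent nodal oracle across scenarios", {
  cases <- list(c(1, NA), c(5, NA), c(10, NA), c(10, 1.11111),
                c(10, 1.25), c(10, 3), c(10, 100), c(2.5, 4))
  for (cs in cases) {
    got <- dc_steady_state(model_parameters(Ro = cs[1]), cs[2])
    want <- oracle_dc_icp(cs[1], cs[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("DC ICP lands within 0.5% of the reported steady pressures", {
  expect_equal(dc_steady_state(model_parameters())[["P_ic"]],
               709.13, tolerance = 5e-3)
  expect_equal(dc_steady_state(model_parameters(Ro = 5))[["P_ic"]],
               2496, tolerance = 5e-3)
  expect_equal(dc_steady_state(model_parameters(Ro = 10))[["P_ic"]],
               3648, tolerance = 5e-3)
  expect_equal(dc_steady_state(model_parameters(Ro = 10), 1.25)[["P_ic"]],
               778.892, tolerance = 5e-3)
})

test_that("DC solution is linear in the source with all valves conducting", {
  p1 <- model_parameters()
  p2 <- model_parameters(src_offset = 32000)
  expect_equal(dc_steady_state(p2), 2 * dc_steady_state(p1),
               tolerance = 1e-12)
})

test_that("transient simulation converges to the DC oracle without pulsation", {
  for (ro in c(1, 10)) {
    p <- model_parameters(Ro = ro, src_amp1 = 0, src_amp2 = 0)
    tr <- simulate_circuit(p, settings = simulation_settings(t_end = 40))
    dc <- dc_steady_state(p)[["P_ic"]]
    icp30 <- tr$P_ic[which.min(abs(tr$t - 30))]
    expect_equal(icp30, dc, tolerance = 1e-3)
    expect_equal(tr$P_ic[nrow(tr)], dc, tolerance = 1e-4)
  }
})

test_that("volume conservation holds along the trace", {
  p <- model_parameters(Ro = 10)
  tr <- sim_trace(10, 1.25)
  # residual of the closed-cranium balance, re-evaluated from the states
  res <- vapply(seq(1, nrow(tr), by = 37), function(i) {
    st <- c(tr$P_a[i] - tr$P_ic[i], tr$P_v[i] - tr$P_ic[i], tr$P_ic[i])
    d <- ode_rhs(tr$t[i], st, p, shunt_constant(1.25))
    du <- d[[1]]
    q <- d[[2]]
    p$Cai * du[1] + p$Cvi * du[2] + q[["q_f"]] - q[["q_o"]] -
      q[["q_sh"]] - p$Ctiss * du[3]
  }, numeric(1))
  peak_flow <- max(tr$q_f, tr$q_o, tr$q_sh, abs(tr$cbf))
  expect_lt(max(abs(res)), 1e-6 * peak_flow)
})

test_that("all valve-gated flows stay non-negative everywhere", {
  traces <- list(sim_trace(1), sim_trace(10), sim_trace(10, 1.11111),
                 timevarying_trace())
  for (tr in traces) {
    expect_gte(min(tr$q_f), 0)
    expect_gte(min(tr$q_o), 0)
    expect_gte(min(tr$q_sh), 0)
    expect_true(all(diff(tr$t) > 0))
  }
})

test_that("mean ICP is strictly monotone in outflow and shunt resistance", {
  icp_ro <- vapply(c(1, 5, 10), sim_icp, numeric(1))
  expect_true(all(diff(icp_ro) > 0))
  icp_rsh <- vapply(c(1.11111, 1.5, 2, 2.5, 3, 100),
                    function(r) sim_icp(10, r), numeric(1))
  expect_true(all(diff(icp_rsh) > 0))
})

test_that("a near-perfect shunt restores the healthy operating point", {
  # Ro = 10 in parallel with 1.11111 is the healthy outflow resistance
  expect_equal(sim_icp(10, 1.11111), sim_icp(1), tolerance = 1e-5)
})

test_that("DC solve refuses parameters that violate valve conduction", {
  # drainage reference far above any achievable ICP: valves cannot conduct
  p <- model_parameters(P_vs = 1e6)
  expect_error(dc_steady_state(p), "conducting")
})

test_that("traces round-trip through CSV with the documented columns", {
  tr <- simulate_circuit(model_parameters(),
                         settings = simulation_settings(t_end = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back)[1:9],
                   c("t", "P_a", "P_c", "P_v", "P_ic", "q_f", "q_o",
                     "q_sh", "cbf"))
  expect_equal(back$P_ic, tr$P_ic, tolerance = 1e-12)
})
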