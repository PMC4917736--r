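test_that("T-gate steady states: midpoints, saturation, monotonicity, window", {
  for (vx in c(-7, -2, 0)) {
    expect_equal(t_gate_steady(-(vx + 57), vx)$s_inf, 0.5)
    expect_equal(t_gate_steady(-(vx + 81), vx)$u_inf, 0.5)
  }
  g <- t_gate_steady(100, -7)
  expect_gt(g$s_inf, 0.999)
  expect_lt(g$u_inf, 0.01)
  vm <- seq(-120, 60, by = 0.5)
  gs <- t_gate_steady(vm, -7)
  expect_true(all(diff(gs$s_inf) > 0))
  expect_true(all(diff(gs$u_inf) < 0))
  # window conductance s_inf^2 * u_inf has an interior maximum
  w <- gs$s_inf^2 * gs$u_inf
  i <- which.max(w)
  expect_gt(i, 1)
  expect_lt(i, length(vm))
  expect_gt(w[i], w[1])
  expect_gt(w[i], w[length(vm)])
})

test_that("T-gate time constants: scaling, frozen value, branch behavior", {
  # temperature prefactor: printed 1/3.7, consistent with Q10 = 3 over 24->36 C
  expect_equal(T_TAU_SCALE, 1 / 3.7)
  expect_equal(T_TAU_SCALE, 1 / 3^1.2, tolerance = 0.011)
  # tau_s at vm + vx = -132: the first inner exponential is e^0 = 1
  tt <- t_gate_tau(-132, 0)
  expect_equal(tt$tau_s, (0.612 + 1 / (1 + exp((-132 + 16.8) / 18.2))) / 3.7,
               tolerance = 1e-12)
  expect_equal(tt$tau_s, 0.4352, tolerance = 1e-4)
  # both tau_u branch expressions at the -80 mV boundary are close (the
  # printed formulas carry a ~20% seam, inherited from their source)
  b_lo <- exp((-80 + 467) / 66.6) / 3.7
  b_hi <- (exp(-(-80 + 22) / 10.5) + 28) / 3.7
  expect_lt(abs(b_lo - b_hi) / b_hi, 0.25)
  expect_equal(t_gate_tau(-80 - 1e-9, 0)$tau_u, b_lo, tolerance = 1e-6)
  expect_equal(t_gate_tau(-80, 0)$tau_u, b_hi, tolerance = 1e-12)
  # strictly positive everywhere
  taus <- t_gate_tau(seq(-150, 60, by = 1), -7)
  expect_true(all(taus$tau_s > 0))
  expect_true(all(taus$tau_u > 0))
  # near rest the LTS recovery times match the mechanism's time scales:
  # fast S-gate (~2-3 ms), slow U-gate (~15-20 ms)
  near <- t_gate_tau(-54, -7)
  expect_lt(near$tau_s, 4)
  expect_gt(near$tau_u, 10)
})

test_that("T-type current density follows g * s^2 * u * (V - V_Ca)", {
  expect_equal(t_current(-54, 1, 0, 0.4, 120), 0)    # closed inactivation gate
  expect_equal(t_current(120, 0.5, 0.5, 0.4, 120), 0)  # reversal potential
  expect_equal(t_current(-54, 1, 1, 0.4, 120), -69.6)
  expect_error(t_current(-54, 1.5, 1, 0.4, 120))
})

test_that("reticular Ts and I_h kinetics are well-behaved", {
  v <- seq(-120, 40, by = 1)
  ts <- ts_gate(v)
  expect_true(all(diff(ts$s_inf) > 0))
  expect_true(all(diff(ts$u_inf) < 0))
  expect_true(all(ts$tau_s > 0) && all(ts$tau_u > 0))
  expect_equal(ts_gate(-52)$s_inf, 0.5)
  expect_equal(ts_gate(-80)$u_inf, 0.5)
  ih <- ih_rates(v)
  expect_true(all(diff(ih$h_inf) < 0))      # hyperpolarization-activated
  expect_true(all(ih$tau_h >= 20))
  eq <- ih_equilibrium(-63, 5e-5)
  expect_true(eq$o >= 0 && eq$o_l >= 0 && eq$p1 >= 0)
  expect_lte(eq$o + eq$o_l, 1)
  # more calcium -> more bound factor and more locked-open channels
  eq_hi <- ih_equilibrium(-63, 1e-3)
  expect_gt(eq_hi$p1, eq$p1)
  expect_gt(eq_hi$o_l, eq$o_l)
})

test_that("Na/K rate functions are finite at their removable singularities", {
  vt <- -56.2
  for (v in c(vt + 13, vt + 15, vt + 40, -71.9, 0)) {
    r <- na_k_rates(v, vt)
    expect_true(all(vapply(r, is.finite, logical(1))))
    expect_true(all(unlist(r) >= 0))
  }
  # limit value at the m-gate singularity: 0.32 * y with y = 4
  expect_equal(na_k_rates(vt + 13, vt)$a_m, 0.32 * 4, tolerance = 1e-5)
})

test_that("gate_step matches the closed-form relaxation and clips", {
  # constant Vm: n small steps equal the analytic exponential solution
  x0 <- 0.9; x_inf <- 0.2; tau <- 3.7
  x <- x0
  for (i in 1:200) x <- gate_step(x, x_inf, tau, 0.05)
  expect_equal(x, x_inf + (x0 - x_inf) * exp(-10 / tau), tolerance = 1e-10)
  expect_equal(gate_step(0.4, 0.4, 5, 1), 0.4)          # fixed point
  expect_equal(gate_step(0.4, 0.8, 5, 1e-9), 0.4, tolerance = 1e-8)
  expect_equal(gate_step(0.5, 1.4, 1, 100), 1)          # clipped to [0,1]
})

test_that("calcium pool: fixed point, influx sign, closed-form match", {
  pool <- list(ca_i = 5e-5, d_nm = 100, tau_ca = 5, ca_rest = 5e-5, ca_out = 2)
  expect_equal(calcium_pool_step(pool, 0, 1)$ca_i, 5e-5)  # equilibrium
  expect_gt(calcium_pool_step(pool, -1, 0.1)$ca_i, 5e-5)  # inward current raises Ca
  expect_equal(calcium_pool_step(pool, 1, 0.1)$ca_i,      # outward: decay only
               calcium_pool_step(pool, 0, 0.1)$ca_i)
  # step-current response: n small steps vs the scalar linear-ODE closed form
  it <- -0.5
  p <- pool
  for (i in 1:100) p <- calcium_pool_step(p, it, 0.02)
  influx <- ca_influx_rate(it, 100)
  target <- 5e-5 + 5 * influx
  expect_equal(p$ca_i, target + (5e-5 - target) * exp(-2 / 5), tolerance = 1e-10)
  # influx rate: inward 1 uA/cm^2 through a 100 nm shell
  expect_equal(ca_influx_rate(-1, 100), 1e-3 / (2 * 96485.33212 * 1e-5),
               tolerance = 1e-12)
})

test_that("nernst_ca recovers the fixed 120 mV LTS reversal at ~240 nM", {
  # RT/2F * ln(Cao/Cai) evaluated independently
  rt2f <- 1e3 * 8.31446261815324 * 309.15 / (2 * 96485.33212)
  expect_equal(nernst_ca(2.4e-4, 2, 309.15), rt2f * log(2 / 2.4e-4))
  expect_equal(nernst_ca(2.4e-4, 2, 309.15), 120, tolerance = 0.005)
  expect_error(nernst_ca(0))
})

test_that("channel sets carry the printed conductances and compositions", {
  rs <- build_channel_set("RS")
  expect_equal(rs$channels$Na$g, 56)
  expect_equal(rs$channels$Kd$g, 6)
  expect_equal(rs$channels$M$g, 0.075)
  expect_equal(rs$channels$Leak$g, 0.0205)
  expect_equal(rs$v_t, -56.2)
  expect_null(rs$channels[["T"]])
  lts <- build_channel_set("LTS")
  expect_equal(lts$channels[["T"]]$g, 0.4)
  expect_equal(lts$channels[["T"]]$v_rev, 120)
  expect_equal(lts$v_x, -7)
  re <- build_channel_set("RE")
  expect_equal(re$channels$Na$g, 200)
  expect_equal(re$channels$Kd$g, 20)
  expect_equal(re$channels$Ts$g, 3)
  expect_null(re$channels[["M"]])
  tc <- build_channel_set("TC")
  expect_equal(tc$channels$h$g, 0.0175)
  expect_equal(tc$channels$KL$g, 0.0138)
  expect_equal(tc$v_x, 0)
  expect_error(build_channel_set("XX"))
  expect_error(build_channel_set("TC", "fig7"), "preset")
  # fig7 species preset swaps the cortical parameters
  expect_equal(build_channel_set("LTS", "fig7")$v_x, -2)
  expect_equal(build_channel_set("RS", "fig7")$channels$Leak$g, 0.1)
})

test_that("the parameter registry is complete and carries units", {
  reg <- param_registry()
  expect_true(all(c("parameter", "cell_type", "preset", "value", "unit")
                  %in% names(reg)))
  expect_gte(nrow(reg), 100)
  expect_equal(reg$value[reg$parameter == "g_na" & reg$cell_type == "RE"], 200)
  expect_equal(reg$value[reg$parameter == "k1" & reg$cell_type == "all"], 2.5e7)
})
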