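test_that("resting states are roots of the steady current and dynamically stable", {
  for (ct in c("RS", "FS", "LTS", "TC", "RE")) {
    n <- nice_neuron(ct)
    r <- resting_state(n)
    expect_lt(abs(steady_current(n, r$v_m0)), 1e-8)
    # rest is a fixed point of the full dynamics: 1 s drift < 0.5 mV,
    # including under a zero-amplitude drive
    sim <- simulate_neuron(n, pulse_train(0.69e6, duty = 1, duration = 1),
                           sinusoidal_drive(0), duration = 1)
    expect_lt(max(abs(sim$trace$vm_mV - r$v_m0)), 0.5)
    expect_length(sim$spikes, 0)
  }
})

test_that("alternative-species presets reproduce their resting potentials", {
  for (ct in c("RS", "FS", "LTS")) {
    n <- nice_neuron(ct, "fig7")
    expect_lt(abs(resting_state(n)$v_m0 - n$v_m0_ref), 1)
  }
})

test_that("chimeric channel addition: null channel is inert, duplicates rejected", {
  rs <- nice_neuron("RS")
  rs0 <- add_channel(rs, g = 0)
  tr <- pulsed_train(duration = 0.05, carrier = 0.2e6)
  a <- simulate_neuron(rs, tr, cal_drive(0.5), duration = 0.06)
  b <- simulate_neuron(rs0, tr, cal_drive(0.5), duration = 0.06)
  expect_equal(b$trace$vm_mV, a$trace$vm_mV, tolerance = 1e-10)
  expect_error(add_channel(nice_neuron("LTS")), "already has")
  expect_error(add_channel(rs, type = "KCa"), "T-type")
  # the original neuron is untouched
  expect_equal(rs$t_kind, "none")
})

test_that("spike detection: crossings, refractory floor, empty traces", {
  t <- seq(0, 0.5, by = 1e-4)
  flat <- data.frame(time_s = t, vm_mV = rep(-70, length(t)))
  expect_length(detect_spikes(flat), 0)
  # 50 upward crossings in 0.5 s (100 Hz sine around -10 with amplitude 40)
  wav <- data.frame(time_s = t, vm_mV = -10 + 40 * sin(2 * pi * 100 * t))
  expect_length(detect_spikes(wav), 50)
  # double peak within 1 ms counts once
  t2 <- seq(0, 0.004, by = 1e-5)
  v2 <- rep(-70, length(t2))
  v2[t2 > 0.001 & t2 < 0.0012] <- 20
  v2[t2 > 0.0015 & t2 < 0.0017] <- 20
  expect_length(detect_spikes(data.frame(time_s = t2, vm_mV = v2)), 1)
})

test_that("firing_rate counts spikes over the window", {
  expect_equal(firing_rate(seq(0, 0.49, by = 0.01), c(0, 0.5)), 100)
  expect_equal(firing_rate(numeric(0), c(0, 0.5)), 0)
  expect_equal(firing_rate(seq(0.005, 2, by = 0.01), c(1, 1.5)), 100)
  expect_error(firing_rate(1, c(0.5, 0.5)))
})

test_that("charge formulation matches an independent voltage-state integrator", {
  skip_if_not_installed("deSolve")
  n <- nice_neuron("RS")
  iext <- 0.05e-3 / (n$area_um2 * 1e-8)  # 0.05 nA as density, subthreshold
  rhs <- function(t, y, p) {
    r <- na_k_rates(y[1], n$v_t)
    mg <- m_gate(y[1], n$tau_max)
    i <- n$g_na * y[2]^3 * y[3] * (y[1] - n$v_na) +
      n$g_kd * y[4]^4 * (y[1] - n$v_k) +
      n$g_m * y[5] * (y[1] - n$v_k) +
      n$g_leak * (y[1] - n$v_leak)
    list(c((-i + iext) / n$cm0,
           r$a_m * (1 - y[2]) - r$b_m * y[2],
           r$a_h * (1 - y[3]) - r$b_h * y[3],
           r$a_n * (1 - y[4]) - r$b_n * y[4],
           (mg$p_inf - y[5]) / mg$tau_p))
  }
  rest <- resting_state(n)
  y0 <- c(rest$v_m0, rest$gates$m, rest$gates$h, rest$gates$n, rest$gates$p)
  times <- seq(0, 1, by = 5e-4)  # seconds... deSolve runs in ms below
  ref <- deSolve::lsoda(y0, times * 1e3, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  sim <- simulate_neuron(n, duration = 1, i_ext_nA = 0.05, dt_report = 5e-4)
  expect_equal(sim$trace$time_s, times, tolerance = 1e-9)
  expect_lt(max(abs(sim$trace$vm_mV - ref[, 2])), 0.1)
})

test_that("stored samples satisfy charge balance away from spikes", {
  n <- nice_neuron("RS")
  sim <- simulate_neuron(n, duration = 0.15, i_ext_nA = 0.05,
                         dt_report = 5e-5)
  tr <- sim$trace
  iext <- 0.05e-3 / (n$area_um2 * 1e-8)
  rhs <- -(tr$i_na + tr$i_kd + tr$i_m + tr$i_t + tr$i_h + tr$i_kl +
             tr$i_leak) + iext
  dt_ms <- diff(tr$time_s)[1] * 1e3
  fd <- (tr$q_nC_cm2[-(1:2)] - tr$q_nC_cm2[1:(nrow(tr) - 2)]) / (2 * dt_ms)
  mid <- rhs[2:(nrow(tr) - 1)]
  expect_lt(max(abs(fd - mid)), 0.02 * max(abs(mid)))
})

test_that("halving the integration steps leaves subthreshold traces unchanged", {
  n <- nice_neuron("RS")
  a <- simulate_neuron(n, duration = 0.1, i_ext_nA = 0.05, dt_report = 1e-4)
  b <- simulate_neuron(n, duration = 0.1, i_ext_nA = 0.05, dt_report = 1e-4,
                       dt_scale = 0.5)
  expect_lt(max(abs(a$trace$vm_mV - b$trace$vm_mV)), 0.1)
})

test_that("cycle-averaged displacement drive accumulates depolarizing charge through leak", {
  # leak-only membrane (all voltage-gated conductances removed): over whole
  # carrier cycles the asymmetric hyperpolarization rectifies the leak
  # current into net inward charge
  n <- nice_neuron("RS")
  n$g_na <- 0; n$g_kd <- 0; n$g_m <- 0
  # carrier 0.2 MHz, reporting every carrier period (5 us): every stored
  # sample sits at a whole-cycle boundary where Cm = Cm0
  tr <- cw_train(duration = 0.002, carrier = 0.2e6)
  sim <- simulate_neuron(n, tr, cal_drive(0.8), duration = 0.002,
                         dt_report = 5e-6)
  expect_true(all(abs(sim$trace$cm_uF_cm2 - 1) < 1e-6))
  q <- sim$trace$q_nC_cm2
  expect_gt(q[length(q)], q[1])
  expect_true(all(diff(q) > 0))
})

test_that("gate variables stay in [0,1] and calcium positive throughout drive", {
  for (ct in c("LTS", "TC")) {
    sim <- simulate_neuron(nice_neuron(ct),
                           pulsed_train(duration = 0.1, carrier = 0.2e6),
                           cal_drive(0.8), duration = 0.12)
    g <- sim$trace[, c("m", "h", "n", "p", "s", "u")]
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(sim$trace$ca_mM > 0))
  }
})

test_that("simulations are bit-for-bit deterministic", {
  tr <- pulsed_train(duration = 0.08, carrier = 0.2e6)
  a <- simulate_neuron(nice_neuron("LTS"), tr, cal_drive(0.8), duration = 0.1)
  b <- simulate_neuron(nice_neuron("LTS"), tr, cal_drive(0.8), duration = 0.1)
  expect_identical(a$trace, b$trace)
  expect_identical(a$spikes, b$spikes)
  expect_gt(length(a$spikes), 0)
})
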