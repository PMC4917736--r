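test_that("bi-exponential kernel: zero at onset, unit peak at closed-form time", {
  sp <- synapse_spec("RS", "LTS", 0.09, 0, t1 = 0.1, t2 = 3)
  expect_equal(syn_open_prob(0, sp), 0)
  tpk <- syn_peak_time(sp)
  expect_equal(tpk, 0.1 * 3 / (3 - 0.1) * log(3 / 0.1))
  expect_equal(syn_open_prob(tpk, sp), 1)
  expect_lt(syn_open_prob(tpk + 1e-4, sp), 1)   # true maximum
  expect_lt(syn_open_prob(tpk - 1e-4, sp), 1)
  expect_lt(syn_open_prob(200, sp), 1e-10)
  # linear superposition over spikes
  expect_equal(syn_open_prob(5, sp, spike_times = c(0, 5 - tpk)),
               syn_open_prob(5, sp) + 1)
})

test_that("short-term plasticity follows the printed factors", {
  # RS->LTS: facilitating, f = 0.2, tau_f = 200 ms
  lts <- synapse_spec("RS", "LTS", 0.09, 0, t1 = 0.1, t2 = 3,
                      f = 0.2, tau_f = 200)
  st <- plasticity_on_spike(plasticity_init(), lts)
  expect_equal(st$F, 1.2)
  expect_equal(st$D1, 1)
  st <- plasticity_decay(st, lts, 200)
  expect_equal(st$F, 1 + 0.2 * exp(-1))
  # RS->FS: facilitating + two depressions
  fs <- synapse_spec("RS", "FS", 0.04, 0, t1 = 0.1, t2 = 3,
                     f = 0.5, tau_f = 94,
                     d1 = 0.46, tau_d1 = 380, d2 = 0.975, tau_d2 = 9200)
  st <- plasticity_on_spike(plasticity_init(), fs)
  expect_equal(st$F, 1.5)
  expect_equal(st$D1, 0.46)
  expect_equal(st$D2, 0.975)
  # long silence relaxes the composite scale back to 1
  st <- plasticity_decay(st, fs, 1e6)
  expect_equal(st$F * st$D1 * st$D2, 1, tolerance = 1e-9)
  # static synapse: P identically 1
  stat <- synapse_spec("FS", "RS", 0.015, -85, t1 = 0.5, t2 = 8)
  s0 <- plasticity_decay(plasticity_on_spike(plasticity_init(), stat), stat, 50)
  expect_equal(s0$F * s0$D1 * s0$D2, 1)
})

test_that("synaptic current follows g_bar * P * s * (V - V_rev)", {
  sp <- synapse_spec("RS", "LTS", 0.09, 0, t1 = 0.1, t2 = 3)
  expect_equal(syn_current(sp, s = 1, v_post = 0), 0)     # at reversal
  expect_equal(syn_current(sp, s = 0, v_post = -54), 0)   # closed
  expect_equal(syn_current(sp, s = 1, v_post = -54), -4.86)
  # density conversion by the LTS area
  expect_equal(syn_current(sp, 1, -54) * 1e-3 / (25e3 * 1e-8), -19.44,
               tolerance = 1e-6)
  gaba <- synapse_spec("FS", "LTS", 0.86, -85, t1 = 0.5, t2 = 8)
  expect_equal(syn_current(gaba, 1, -85), 0)
})

test_that("the microcircuit wiring matches the three-population diagram", {
  net <- cortical_network()
  expect_length(net$synapses, 8)
  conns <- vapply(net$synapses, function(s) paste(s$pre, s$post), character(1))
  expect_setequal(conns, c("RS RS", "RS FS", "RS LTS", "FS RS", "FS FS",
                           "FS LTS", "LTS RS", "LTS FS"))
  expect_false("LTS LTS" %in% conns)
  # AMPA from RS, GABA-A from the interneurons
  for (s in net$synapses) {
    expect_equal(s$v_rev, if (s$pre == "RS") 0 else -85)
    expect_equal(s$t2, if (s$pre == "RS") 3 else if (s$pre == "FS") 8 else 50)
  }
  # plasticity only on the excitatory connections to the interneurons
  dyn <- vapply(net$synapses, function(s) s$has_f || s$has_d, logical(1))
  expect_setequal(conns[dyn], c("RS FS", "RS LTS"))
  # thalamic input to RS and FS only, ratio 1.4
  expect_equal(net$i_th_rs, 0.17)
  expect_equal(net$r_th, 1.4)
})

test_that("a silent network produces no synaptic current", {
  net <- cortical_network(i_th_rs = 0)
  sim <- simulate_network(net, duration = 0.3)
  expect_true(all(vapply(sim$spikes, length, integer(1)) == 0))
  expect_true(all(abs(sim$trace[, grep("^isyn_", names(sim$trace))]) == 0))
})

test_that("network simulations are bit-for-bit deterministic", {
  net <- cortical_network()
  tr <- pulsed_train(duration = 0.1, carrier = 0.2e6, onset = 0.1)
  a <- simulate_network(net, tr, cal_drive(0.8), duration = 0.25)
  b <- simulate_network(net, tr, cal_drive(0.8), duration = 0.25)
  expect_identical(a$trace, b$trace)
  expect_identical(a$spikes, b$spikes)
  expect_gt(sum(vapply(a$spikes, length, integer(1))), 0)
})

test_that("baseline thalamic drive produces sustained asynchronous activity", {
  sim <- simulate_network(cortical_network(), duration = 1)
  rs <- firing_rate(sim$spikes$RS, c(0.25, 1))
  fs <- firing_rate(sim$spikes$FS, c(0.25, 1))
  expect_gt(rs, 3)
  expect_lt(rs, 15)
  expect_gt(fs, rs)   # FS receives 1.4x the thalamic input
  expect_lt(firing_rate(sim$spikes$LTS, c(0.25, 1)), 5)
})
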