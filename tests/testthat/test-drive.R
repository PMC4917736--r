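test_that("pulse envelope implements the duty-cycle timing", {
  tr <- pulsed_train(duration = 0.3)  # 5% duty, PRF 100 Hz
  # 5% of a 10 ms period is 0.5 ms: on at 0.2 ms into a period, off at 5 ms
  expect_true(envelope(0.0002, tr))
  expect_false(envelope(0.005, tr))
  expect_true(envelope(0.0102, tr))      # second period, early phase
  expect_false(envelope(0.31, tr))       # past stimulus end
  # CW: on for the whole window
  cw <- cw_train(duration = 0.05)
  expect_true(all(envelope(seq(0, 0.049, by = 1e-3), cw)))
  expect_false(envelope(0.05, cw))
  # on-time per period is duty/prf
  t <- seq(0, 0.01 - 1e-7, by = 1e-7)
  expect_equal(mean(envelope(t, tr)), 0.05, tolerance = 1e-3)
})

test_that("pulse train validation enforces its invariants", {
  expect_error(pulse_train(0.69e6, duty = 0, duration = 1), "duty")
  expect_error(pulse_train(0.69e6, duty = 1.2, duration = 1), "duty")
  expect_error(pulse_train(1e3, prf = 1e4, duty = 0.5, duration = 1), "prf")
  expect_error(pulse_train(0.69e6, prf = 1e5, duty = 0.005, duration = 1),
               "carrier period")
  expect_error(sinusoidal_drive(1.0), "positive")
  expect_error(sinusoidal_drive(-0.1), "positive")
})

test_that("capacitance waveform: off periods, coverage weighting, quarter-period", {
  tr <- pulsed_train(duration = 0.3)
  drv <- cal_drive(0.8)
  # off period: resting capacitance, zero derivative
  off <- drive_capacitance(0.005, drv, tr)
  expect_equal(off$cm, 1)
  expect_equal(off$dcm_dt, 0)
  # zero coverage: resting capacitance always
  none <- drive_capacitance(c(1e-7, 0.0002, 0.005), cal_drive(0.8, coverage = 0), tr)
  expect_equal(none$cm, rep(1, 3))
  expect_equal(none$dcm_dt, rep(0, 3))
  # quarter carrier period into a pulse: Cm = Cm0 + C_Amp = 1.8
  tq <- 0.25 / tr$carrier_f
  expect_equal(drive_capacitance(tq, drv, tr)$cm, 1.8, tolerance = 1e-9)
  # phase restarts at each pulse onset: sin = 0 at pulse start
  expect_equal(drive_capacitance(0.01, drv, tr)$cm, 1, tolerance = 1e-6)
})

test_that("capacitance stays positive and dips to the stated minimum", {
  tr <- pulsed_train(duration = 0.05)
  drv <- cal_drive(0.8)
  t <- seq(0, 0.0005, length.out = 4001)  # one full pulse
  cm <- drive_capacitance(t, drv, tr)$cm
  expect_true(all(cm > 0))
  expect_equal(min(cm), 0.2, tolerance = 1e-4)  # the 80% decline
  expect_equal(max(cm), 1.8, tolerance = 1e-4)
})

test_that("dCm/dt is the exact derivative and has no net drift over whole cycles", {
  tr <- pulsed_train(duration = 0.05)
  drv <- cal_drive(0.8)
  per <- 1 / tr$carrier_f
  h <- per / 1e4
  t <- per * c(0.1, 0.33, 0.618, 0.9) + 2e-3 * 0  # inside the first pulse
  got <- drive_capacitance(t, drv, tr)$dcm_dt
  fd <- (drive_capacitance(t + h, drv, tr)$cm -
           drive_capacitance(t - h, drv, tr)$cm) / (2 * h)
  expect_equal(got, fd, tolerance = 1e-6)
  # integral of dCm/dt over whole cycles within a pulse is zero
  n <- 20000
  tt <- seq(0, 100 * per, length.out = n + 1)
  d <- drive_capacitance(tt, drv, tr)$dcm_dt
  integral <- sum((d[-1] + d[-(n + 1)]) / 2) * (tt[2] - tt[1])
  expect_lt(abs(integral), 1e-6 * drv$c_amp)
})

test_that("intensity-to-amplitude mapping is anchored and clips", {
  expect_equal(amplitude_from_intensity(3.3), 0.8)
  # quarter intensity = half pressure amplitude under the sqrt mapping
  expect_equal(amplitude_from_intensity(0.825), 0.4)
  expect_equal(amplitude_from_intensity(1e-9), 0.8 * sqrt(1e-9 / 3.3))
  expect_warning(a <- amplitude_from_intensity(10), "clipped")
  expect_lt(a, 1)
  expect_error(amplitude_from_intensity(0), "positive")
  # monotone below the clip
  ii <- c(0.1, 0.5, 1, 2, 3.3)
  expect_true(all(diff(amplitude_from_intensity(ii)) > 0))
})
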