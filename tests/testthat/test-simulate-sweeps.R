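test_that("subthreshold sweeps obey Ohm's law at steady state", {
  p <- noise_free_params()
  proto <- quick_protocol()
  ss <- simulate_neuron_sweeps(p, proto)
  s <- sweep_at(ss, -50)
  v <- ss$voltage[, s]
  t_ms <- satmg:::protocol_times_ms(proto)
  # steady state: last sample inside the step, 250 ms >> tau = 20 ms
  i_end <- max(which(t_ms < proto$pre_ms + proto$step_ms))
  expected <- p$rest_mV + p$Rin_MOhm * (-50) / 1000  # MOhm * pA -> mV
  expect_equal(v[i_end], expected, tolerance = 1e-3)
  # baseline sits at rest before the step
  expect_equal(v[1], p$rest_mV)
})

test_that("membrane charging follows the RC exponential", {
  p <- noise_free_params()
  proto <- quick_protocol()
  ss <- simulate_neuron_sweeps(p, proto)
  v <- ss$voltage[, sweep_at(ss, -50)]
  t_ms <- satmg:::protocol_times_ms(proto)
  during <- t_ms >= proto$pre_ms & t_ms < proto$pre_ms + proto$step_ms
  dV <- p$Rin_MOhm * (-50) / 1000
  model <- p$rest_mV + dV * (1 - exp(-(t_ms[during] - proto$pre_ms) / p$tau_m_ms))
  expect_equal(v[during], model, tolerance = 1e-12)
})

test_that("planted spike count and first-ISI frequency follow f1 = gain * (I - rheobase)", {
  p <- noise_free_params()
  proto <- quick_protocol()
  ss <- simulate_neuron_sweeps(p, proto)
  s <- sweep_at(ss, 300)  # 100 pA above rheobase -> f1 = 0.4 * 100 = 40 Hz
  st <- detect_spikes(ss$voltage[, s], proto$sample_rate_hz)
  truth <- ss$truth$spikes[ss$truth$spikes$amplitude_pA == 300, ]
  expect_equal(nrow(st), nrow(truth))
  expect_equal(ss$truth$f1_hz[s], 40)
  # detected 0 mV cross times match the planted ones
  expect_equal(st$time_ms, truth$cross_ms, tolerance = 1e-9)
  # first ISI of onsets corresponds to 40 Hz up to grid snapping
  expect_equal(truth$onset_ms[2] - truth$onset_ms[1], 25, tolerance = proto$dt_ms)
})

test_that("each spike rises from exactly the planted threshold", {
  p <- noise_free_params()
  proto <- quick_protocol()
  ss <- simulate_neuron_sweeps(p, proto)
  s <- sweep_at(ss, 300)
  v <- ss$voltage[, s]
  truth <- ss$truth$spikes[ss$truth$spikes$amplitude_pA == 300, ]
  onset_idx <- round(truth$onset_ms / proto$dt_ms) + 1
  expect_equal(v[onset_idx], rep(p$VT_mV, nrow(truth)), tolerance = 1e-12)
})

test_that("truth table carries grid-snapped effective slopes and half width", {
  p <- noise_free_params()
  tmpl <- satmg:::spike_template(p, 0.05)
  # A = 80 mV: rise 80/400 = 0.2 ms (4 samples, exact), drop = 92 mV over
  # 18 samples = 0.9 ms -> Sf_eff = 92/0.9
  expect_equal(tmpl$rise_ms, 0.2)
  expect_equal(tmpl$fall_ms, 0.9)
  expect_equal(tmpl$Sr_eff, 400)
  expect_equal(tmpl$Sf_eff, 92 / 0.9)
  expect_equal(tmpl$HW_eff, (80 / 2) * (1 / 400 + 0.9 / 92))
})

test_that("simulation is deterministic given a seed", {
  p <- neuron_params(noise_sd_mV = 0.2)
  proto <- quick_protocol()
  a <- simulate_neuron_sweeps(p, proto, seed = 42)
  b <- simulate_neuron_sweeps(p, proto, seed = 42)
  expect_identical(a$voltage, b$voltage)
  c <- simulate_neuron_sweeps(p, proto, seed = 43)
  expect_false(identical(a$voltage, c$voltage))
})

test_that("a template too wide for the planted ISI is rejected", {
  # gain 10 Hz/pA at 100 pA above rheobase -> ISI 1 ms < template width 1.1 ms
  p <- noise_free_params(gain_hz_per_pA = 10)
  proto <- quick_protocol()
  expect_error(simulate_neuron_sweeps(p, proto), "does not fit the ISI")
})

test_that("a sweep exactly at rheobase plants a single spike", {
  p <- noise_free_params()
  proto <- make_step_protocol(start_pA = 200, stop_pA = 200)
  ss <- simulate_neuron_sweeps(p, proto)
  st <- detect_spikes(ss$voltage[, 1], proto$sample_rate_hz)
  expect_equal(nrow(st), 1)
})

test_that("print method reports sweep and spike counts", {
  ss <- simulate_neuron_sweeps(noise_free_params(), quick_protocol())
  expect_output(print(ss), "planted spikes")
})
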