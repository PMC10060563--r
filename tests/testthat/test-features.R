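proto10k <- step_protocol()

test_that("a flat sweep contains no spikes and an empty sweep is rejected", {
  expect_identical(detect_spikes(rep(-70, 9000), proto10k), numeric(0))
  expect_error(detect_spikes(numeric(0), proto10k), "empty")
})

test_that("pasted waveforms are detected at their paste times and match the brute-force scan", {
  v <- make_pasted_trace(c(100, 200, 300))
  st <- detect_spikes(v, proto10k)
  expect_length(st, 3)
  expect_true(all(abs(st * 1000 - c(100, 200, 300)) <= 0.5))
  expect_equal(st, oracle_brute_spikes(v, 0.1))
})

test_that("vectorized spike detection matches the per-sample brute-force criterion on noisy LIF sweeps", {
  set.seed(99)
  for (k in 1:3) {
    np <- neuron_params(rm_mohm = runif(1, 80, 200), noise_sd_mv = 0.5)
    rec <- simulate_neuron(np, proto10k, seed = k)
    for (j in seq_len(ncol(rec$sweeps))) {
      v <- rec$sweeps[, j]
      expect_equal(detect_spikes(v, proto10k), oracle_brute_spikes(v, 0.1))
    }
  }
})

test_that("detected spike counts on a noiseless recording equal the simulator ground truth", {
  np <- neuron_params(rm_mohm = 100, cm_pf = 100, noise_sd_mv = 0)
  rec <- simulate_neuron(np, proto10k)
  fi <- compute_fi_curve(rec)
  expect_s3_class(fi, "fi_curve")
  expect_equal(nrow(fi), 10)
  expect_equal(fi$n_spikes, rec$ground_truth$spike_counts_step)
  expect_equal(fi$rate_hz, fi$n_spikes / 0.5)
  # zero at and below the analytic rheobase (200 pA: the steady state only
  # reaches threshold asymptotically), positive and non-decreasing above
  expect_true(all(fi$n_spikes[fi$current_pA <= 200] == 0))
  above <- fi$n_spikes[fi$current_pA > 200]
  expect_true(all(above > 0) && all(diff(above) >= 0))
})

test_that("all-subthreshold recordings give an all-zero f-I curve and a flagged rheobase", {
  np <- neuron_params(rm_mohm = 20, noise_sd_mv = 0)   # rheobase 1000 pA
  rec <- simulate_neuron(np, proto10k)
  fi <- compute_fi_curve(rec)
  expect_true(all(fi$n_spikes == 0))
  rb <- estimate_rheobase(fi)
  expect_true(is.na(rb$rheobase_pA))
  expect_equal(rb$flag, "no_spikes")
})

test_that("spline rheobase lands in the bracketing interval and matches a dense-grid evaluation", {
  fi <- structure(data.frame(current_pA = seq(-300, 600, by = 100),
                             n_spikes = c(0, 0, 0, 0, 0, 4, 8, 11, 13, 15),
                             rate_hz = c(0, 0, 0, 0, 0, 4, 8, 11, 13, 15) / 0.5),
                  class = c("fi_curve", "data.frame"))
  rb <- estimate_rheobase(fi)
  expect_equal(rb$flag, "ok")
  expect_true(rb$rheobase_pA > 100 && rb$rheobase_pA <= 200)
  # independent dense-grid oracle on the same monotone interpolant
  f <- stats::splinefun(seq(0, 600, by = 100), c(0, 0, 4, 8, 11, 13, 15),
                        method = "hyman")
  grid <- seq(0, 600, by = 1)
  expect_equal(rb$rheobase_pA, grid[which(f(grid) >= 1)[1]])
})

test_that("an always-spiking cell returns the smallest tested current with a QC flag", {
  fi <- structure(data.frame(current_pA = seq(0, 400, by = 100),
                             n_spikes = c(2, 5, 8, 10, 12),
                             rate_hz = c(2, 5, 8, 10, 12) / 0.5),
                  class = c("fi_curve", "data.frame"))
  rb <- estimate_rheobase(fi)
  expect_equal(rb$rheobase_pA, 0)
  expect_equal(rb$flag, "all_spiking")
})

test_that("rheobase estimates bracket the analytic value within one current-grid step", {
  for (rm in c(100, 150, 250)) {
    np <- neuron_params(rm_mohm = rm, noise_sd_mv = 0)
    rec <- simulate_neuron(np, proto10k)
    rb <- estimate_rheobase(compute_fi_curve(rec))
    analytic <- lif_rheobase_pA(np)
    expect_equal(rb$flag, "ok")
    expect_lte(abs(rb$rheobase_pA - analytic), 100)
    expect_true(rb$rheobase_pA > rb$bracket_pA[1] &&
                  rb$rheobase_pA <= rb$bracket_pA[2])
  }
})

test_that("input resistance follows R_in = dV/I and recovers R_m within tolerance", {
  # hand value: -30 mV at -300 pA is 100 MOhm
  np <- neuron_params(rm_mohm = 100, noise_sd_mv = 0)
  rec <- simulate_neuron(np, proto10k)
  rin <- compute_input_resistance(rec)
  expect_equal(rin$rin_mohm, 1000 * rin$delta_v_mv / -300)
  expect_lt(abs(rin$rin_mohm - 100) / 100, 0.02)
  # recovery across the R_m grid, noiseless within 2%, 0.5 mV noise within 3%
  for (rm in c(50, 100, 200, 300)) {
    rec0 <- simulate_neuron(neuron_params(rm_mohm = rm, cm_pf = 80,
                                          noise_sd_mv = 0), proto10k)
    expect_lt(abs(compute_input_resistance(rec0)$rin_mohm - rm) / rm, 0.02)
    recn <- simulate_neuron(neuron_params(rm_mohm = rm, cm_pf = 80,
                                          noise_sd_mv = 0.5), proto10k,
                            seed = rm)
    expect_lt(abs(compute_input_resistance(recn)$rin_mohm - rm) / rm, 0.03)
  }
})

test_that("a zero deflection is flagged implausible and a missing -300 pA sweep is rejected", {
  flat <- structure(list(sweeps = matrix(-70, 9000, 10),
                         protocol = proto10k, cell_id = "flat",
                         animal_id = "x", ground_truth = NULL),
                    class = "recording")
  rin <- compute_input_resistance(flat)
  expect_equal(rin$rin_mohm, 0)
  expect_true("implausible_rin" %in% rin$flags)
  p2 <- step_protocol(currents_pA = c(-100, 100))
  rec2 <- simulate_neuron(neuron_params(), p2)
  expect_error(compute_input_resistance(rec2), "-300")
})

test_that("passive features recover tau and RMP and AP amplitude is threshold-to-peak", {
  np <- neuron_params(rm_mohm = 100, cm_pf = 100, el_mv = -70,
                      vth_mv = -50, noise_sd_mv = 0)
  rec <- simulate_neuron(np, proto10k)
  pa <- compute_passive_and_ap_features(rec)
  expect_lt(abs(pa$tau_ms - 10) / 10, 0.05)
  expect_equal(pa$rmp_mv, -70, tolerance = 1e-6)
  # waveform peaks at +30 mV with threshold at vth = -50: amplitude 80 mV
  expect_lt(abs(pa$ap_amp_mv - 80), 2)
  expect_lt(abs(pa$ap_thr_mv - -50), 2)
  expect_true(pa$ap_halfwidth_ms > 0.2 && pa$ap_halfwidth_ms < 2)
})

test_that("tau recovery holds across an R_m grid (tau = R_m * C_m)", {
  for (rm in c(50, 100, 200, 300)) {
    np <- neuron_params(rm_mohm = rm, cm_pf = 100, noise_sd_mv = 0)
    rec <- simulate_neuron(np, proto10k)
    pa <- compute_passive_and_ap_features(rec)
    expect_lt(abs(pa$tau_ms - rm * 100 / 1000) / (rm * 100 / 1000), 0.05)
  }
})

test_that("extract_cell_features assembles a 10-point f-I curve with QC flags and rejects malformed input", {
  np <- neuron_params(rm_mohm = 120, noise_sd_mv = 0.3)
  rec <- simulate_neuron(np, proto10k, seed = 1, cell_id = "c1",
                         animal_id = "a1")
  cf <- extract_cell_features(rec)
  expect_s3_class(cf, "cell_features")
  expect_equal(nrow(cf$fi), 10)
  expect_true(cf$qc_pass)
  ft <- features_table(list(cf))
  expect_equal(nrow(ft), 1)
  expect_equal(ft$cell_id, "c1")
  expect_error(extract_cell_features(list(sweeps = 1)), "not a recording")
  bad <- rec; bad$sweeps <- bad$sweeps[, 1:5]
  expect_error(extract_cell_features(bad), "sweeps")
})

test_that("0.5 mV measurement noise shifts the R_in estimate by less than 3%", {
  np0 <- neuron_params(rm_mohm = 150, noise_sd_mv = 0)
  recn <- simulate_neuron(neuron_params(rm_mohm = 150, noise_sd_mv = 0.5),
                          proto10k, seed = 2)
  r0 <- compute_input_resistance(simulate_neuron(np0, proto10k))$rin_mohm
  rn <- compute_input_resistance(recn)$rin_mohm
  expect_lt(abs(rn - r0) / r0, 0.03)
})
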