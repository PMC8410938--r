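# Forward-model generator: kernels, rendering, behaviour, determinism.

test_that("zero-amplitude kernels give identically zero voltage", {
  kk <- default_region_kernels("paw")
  for (n in names(kk)) { kk[[n]]$A_dep <- 0; kk[[n]]$A_hyp <- 0 }
  cfg <- tiny_config(region_kernels = kk)
  tr <- generate_voltage_truth(cfg, seed = 1)
  expect_true(all(tr$V == 0))
})

test_that("depolarisation kernel peaks at the configured amplitude and latency", {
  cfg <- tiny_config()  # S1FL: 0.195 % peaking 59.83 ms post-stimulus
  tr <- generate_voltage_truth(cfg, seed = 1)
  expect_equal(unname(tr$peak_amp["S1FL"]), 0.195)
  expect_equal(unname(tr$peak_time_ms["S1FL"]), 59.83, tolerance = 1e-9)
  # sampled on the 10 ms frame grid the max is within quantisation of truth
  v <- tr$V["S1FL", ]
  expect_lt(abs(max(v) - 0.195), 0.195 * 0.01)
  expect_equal(tr$time_ms[which.max(v)], 60)
  # causal: zero before stimulus onset + delay
  expect_true(all(v[tr$time_ms <= 10] == 0))
})

test_that("kernels of two stimuli sum linearly (analytic oracle)", {
  kk <- list(S1FL = list(A_dep = 0.2, onset_delay = 10, peak_latency = 59.83,
                         decay_tau = 90, A_hyp = 0, hyp_onset = 100,
                         hyp_peak_time = 180, hyp_decay_tau = 250))
  cfg <- tiny_config(stim_frames = c(125L, 165L), stim_factors = c(1, 1),
                     region_kernels = kk)
  tr <- generate_voltage_truth(cfg, seed = 1)
  v <- tr$V["S1FL", ]
  # oracle: evaluate the two analytic kernels at both sampled peak frames
  rise <- (function(p, d) {
    uniroot(function(r) log(d / r) * r * d / (d - r) - p, c(1e-6, d - 1e-6),
            tol = 1e-12)$root
  })(49.83, 90)
  t1 <- (seq_len(cfg$n_frames) - 125) * 10
  t2 <- (seq_len(cfg$n_frames) - 165) * 10
  k1 <- 0.2 * oracle_doe(t1, 10, rise, 90)
  k2 <- 0.2 * oracle_doe(t2, 10, rise, 90)
  expect_equal(v, k1 + k2, tolerance = 1e-9)
  # second kernel peak equals the first after removing the first's residue
  p1 <- which.max(k1); p2 <- p1 + 40L
  expect_lt(abs((v[p2] - k1[p2]) - v[p1]), 1e-9)
})

test_that("invalid configurations are rejected", {
  kk <- default_region_kernels("paw")
  kk$S1FL$hyp_peak_time <- 5  # <= onset_delay
  expect_error(tiny_config(region_kernels = kk), "hyp_peak_time")
  expect_error(tiny_config(heartbeat = list(f_hb = 60)), "f_hb")
  expect_error(tiny_config(dark_frames = c(1L, 130L)), "dark_frames")
  expect_error(tiny_config(stim_frames = c(125L, 125L)), "increasing")
  expect_error(synthetic_config(raw_shape = c(50L, 80L)), "divisible")
})

test_that("rendered counts follow the channel model in the constant case", {
  kk <- default_region_kernels("none")
  cfg <- clean_config(region_kernels = kk, stimulus = "none",
                      heartbeat = list(donor_mod_depth = 0,
                                       acceptor_mod_depth = 0),
                      gain_coupling = list(g_D = 0.5, g_A = 0.5))
  sim <- simulate_trial(cfg, seed = 3, behavior = FALSE)
  op <- cfg$optics
  dark <- cfg$dark_frames[1]:cfg$dark_frames[2]
  lit <- setdiff(seq_len(cfg$n_frames), dark)
  # dark frames: offset only, in both channels
  expect_true(all(sim$seq$donor[, , dark] == op$camera_offset_counts))
  expect_true(all(sim$seq$acceptor[, , dark] == op$camera_offset_counts))
  # lit frames spatially constant at offset + base
  expect_true(all(sim$seq$donor[, , lit] ==
                    op$camera_offset_counts + op$donor_base_counts))
  expect_true(all(sim$seq$acceptor[, , lit] ==
                    op$camera_offset_counts + op$acceptor_base_counts))
})

test_that("vessel pixels render dark in all lit frames", {
  cfg <- tiny_config(optics = list(noise_sd_counts = 0), stimulus = "none")
  sim <- simulate_trial(cfg, seed = 4, behavior = FALSE)
  vm <- sim$truth$vessel_mask
  expect_gt(sum(vm), 0)
  lit_frame <- sim$seq$donor[, , 150]
  expect_true(all(lit_frame[vm] == cfg$optics$camera_offset_counts))
  expect_true(all(lit_frame[!vm] > cfg$optics$camera_offset_counts))
})

test_that("channel heartbeat amplitudes reflect the configured modulation depths", {
  cfg <- clean_config(stimulus = "none",
                      heartbeat = list(donor_mod_depth = 0.02,
                                       acceptor_mod_depth = 0.01),
                      gain_coupling = list(g_D = 0.5, g_A = 0.5))
  sim <- simulate_trial(cfg, seed = 5, behavior = FALSE)
  b <- subtract_dark_offset(bin_sequence(sim$seq, 4))
  nrm <- normalize_prestim(b)
  g <- estimate_heartbeat_gain(nrm, median_filter = FALSE, clip = NULL)
  expect_false(g$fallback)
  expect_equal(g$f_hb, 10)
  # closed-form sinusoid amplitude ratio 0.01 / 0.02, up to 12-bit rounding
  expect_equal(mean(g$gain), 0.5, tolerance = 5e-3)
  expect_equal(g$acceptor_amp / g$donor_amp, 0.5, tolerance = 5e-3)
})

test_that("rendering is deterministic in the seed and sensitive to it", {
  cfg <- tiny_config()
  a <- simulate_trial(cfg, seed = 11, behavior = FALSE)
  b <- simulate_trial(cfg, seed = 11, behavior = FALSE)
  d <- simulate_trial(cfg, seed = 12, behavior = FALSE)
  expect_identical(a$seq$donor, b$seq$donor)
  expect_identical(a$seq$acceptor, b$seq$acceptor)
  expect_false(identical(a$seq$donor, d$seq$donor))
})

test_that("behaviour stacks are static outside movement epochs", {
  cfg <- tiny_config(behavior_noise_sd = 0)
  st <- generate_behavior_stack(cfg, movement_epochs = list(), seed = 1)
  expect_true(all(st == as.vector(st[, , 1])))

  st2 <- generate_behavior_stack(cfg, movement_epochs = list(c(120L, 140L)),
                                 seed = 1, area_frac = 0.05)
  # inside the epoch a known fraction of pixels changes, outside none
  delta <- abs(st2[, , 130] - st2[, , 50])
  expect_gte(mean(delta > 0), 0.05)
  expect_true(all(st2[, , 30] == st2[, , 50]))
  expect_error(generate_behavior_stack(cfg, list(c(1L, 300L)), seed = 1),
               "epochs")
  expect_error(generate_behavior_stack(cfg, list(), seed = 1, area_frac = 2),
               "area_frac")
})

test_that("sessions are reproducible byte-for-byte and list every trial", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_session(cfg, n_trials = 3, out_dir = d1, seed = 9)
  generate_session(cfg, n_trials = 3, out_dir = d2, seed = 9)
  m1 <- load_session(d1)
  expect_length(m1$trials, 3)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  d3 <- withr::local_tempdir()
  generate_session(cfg, n_trials = 3, out_dir = d3, seed = 10)
  t1 <- read_trial(m1, 1)$seq$donor
  t3 <- read_trial(load_session(d3), 1)$seq$donor
  expect_false(identical(t1, t3))
})
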