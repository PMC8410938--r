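# Evoked-response metrics: peak, inclusion, hyperpolarisation, decay,
# paired-pulse adaptation and the cylinder asymmetry index.

test_that("peak detection handles flat traces, ties and windows", {
  flat <- rep(0.3, 200)
  pk <- detect_peak(flat, 125)
  expect_equal(pk$peak_amp, 0)
  expect_equal(pk$baseline_mean, 0.3)
  expect_false(pk$included)  # degenerate: sd 0, amp 0

  # two equal maxima at 40 and 80 ms -> earliest wins
  y <- rep(0, 200); y[129] <- 0.2; y[133] <- 0.2
  pk2 <- detect_peak(y, 125)
  expect_equal(pk2$peak_time_ms, 40)
  expect_equal(pk2$peak_amp, 0.2)

  # window endpoints are inclusive: responses at exactly 20 and 100 ms count
  y3 <- rep(0, 200); y3[127] <- 0.5
  expect_equal(detect_peak(y3, 125)$peak_time_ms, 20)
  y4 <- rep(0, 200); y4[135] <- 0.5
  expect_equal(detect_peak(y4, 125)$peak_time_ms, 100)
  # a response just outside is invisible
  y5 <- rep(0, 200); y5[136] <- 0.5
  expect_equal(detect_peak(y5, 125)$peak_amp, 0)

  expect_error(detect_peak(rep(0, 130), 125), "does not cover")
})

test_that("peak amplitude is measured relative to the 10-frame baseline", {
  y <- rep(1, 200)
  y[115:124] <- 1.05  # baseline window elevated
  y[131] <- 1.45
  pk <- detect_peak(y, 125)
  expect_equal(pk$baseline_mean, 1.05)
  expect_equal(pk$peak_amp, 0.4)
})

test_that("generator truth amplitudes are recovered from noiseless traces", {
  cfg <- tiny_config(stimulus = "whisker")
  v <- generate_voltage_truth(cfg, seed = 1)$V["S1BF", ]
  pk <- detect_peak(v, 125)
  expect_equal(pk$peak_amp, 0.156, tolerance = 0.01)  # frame quantisation
  expect_equal(pk$peak_time_ms, 50)
  expect_true(pk$included)
})

test_that("the 2-SD inclusion rule is boundary-inclusive", {
  expect_true(trial_inclusion(0.2, 0.05))
  expect_false(trial_inclusion(0.09, 0.05))
  expect_true(trial_inclusion(0.1, 0.05))    # exactly 2 SD counts
  expect_false(trial_inclusion(0, 0))        # degenerate
  expect_error(trial_inclusion(0.1, -1), ">= 0")
})

test_that("inclusion false-positive rate matches a brute-force Monte-Carlo", {
  n <- 4000
  set.seed(101)
  # independent oracle: plain-arithmetic evaluation of the rule on white noise
  oracle_hits <- vapply(seq_len(n), function(i) {
    y <- rnorm(200)
    b <- y[115:124]
    (max(y[127:135]) - mean(b)) >= 2 * sd(b)
  }, logical(1))
  set.seed(202)
  impl_hits <- vapply(seq_len(n), function(i) {
    detect_peak(rnorm(200), 125)$included
  }, logical(1))
  p1 <- mean(oracle_hits); p2 <- mean(impl_hits)
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  expect_lt(abs(p1 - p2), 4 * se + 1e-12)
})

test_that("hyperpolarisation is the post-peak minimum, magnitude convention", {
  # monotone decay back to baseline, never below -> amplitude 0 at window end
  y <- rep(0, 200)
  y[127:135] <- seq(0.2, 0.1, length.out = 9)
  y[136:155] <- seq(0.1, 0, length.out = 20)
  pk <- detect_peak(y, 125)
  hy <- measure_hyperpolarisation(y, 125, pk$peak_time_ms)
  expect_equal(hy$hyp_amp, 0)
  expect_gte(hy$hyp_time_ms, 150)

  # configured -0.1 % trough at 180 ms
  y2 <- rep(0, 200); y2[130] <- 0.2; y2[143] <- -0.1
  pk2 <- detect_peak(y2, 125)
  hy2 <- measure_hyperpolarisation(y2, 125, pk2$peak_time_ms)
  expect_equal(hy2$hyp_amp, 0.1)
  expect_equal(hy2$hyp_time_ms, 180)

  # ties resolve to the earliest frame
  y3 <- rep(0, 200); y3[130] <- 0.2; y3[140] <- -0.1; y3[148] <- -0.1
  hy3 <- measure_hyperpolarisation(y3, 125, 50)
  expect_equal(hy3$hyp_time_ms, 150)
})

test_that("half-decay time interpolates between frames", {
  # triangle: peak A at 60 ms, linear to zero at 160 ms -> half at 110 ms
  y <- rep(0, 200)
  y[127:131] <- seq(0.2, 1, length.out = 5)
  y[132:141] <- 1 - seq_len(10) * 0.1
  pk <- detect_peak(y, 125)
  expect_equal(pk$peak_time_ms, 60)
  expect_equal(decay50(y, 125, pk), 110)

  # exponential decay: half-life tau * ln 2 (one-frame tolerance)
  tau <- 35
  y2 <- rep(0, 200)
  y2[131] <- 1
  t_post <- seq_len(60) * 10
  y2[131 + seq_len(60)] <- exp(-t_post / tau)
  pk2 <- detect_peak(y2, 125)
  expect_equal(decay50(y2, 125, pk2), 60 + tau * log(2), tolerance = 10 / 60)

  # plateau never dropping below half -> flagged undefined
  y3 <- rep(0, 200); y3[130:200] <- 1
  pk3 <- detect_peak(y3, 125)
  expect_true(is.na(decay50(y3, 125, pk3)))
})

test_that("paired-pulse ratio is 1 for identical non-overlapping responses", {
  pulse <- c(seq(0.05, 0.2, length.out = 4), seq(0.18, 0, length.out = 12))
  y <- rep(0, 200)
  y[127 + seq_along(pulse)] <- pulse         # response to stim at 125
  y[167 + seq_along(pulse)] <- pulse         # identical response at 165
  pp <- paired_pulse(y, c(125L, 165L))
  expect_equal(pp$interstim_ms, 400)
  expect_equal(pp$amp1, pp$amp2)
  expect_equal(pp$ratio, 1)

  # absent second response -> ratio 0; adaptation shows as ratio < 1
  y2 <- y; y2[167 + seq_along(pulse)] <- 0
  expect_equal(paired_pulse(y2, c(125L, 165L))$ratio, 0)
  y3 <- y; y3[167 + seq_along(pulse)] <- 0.5 * pulse
  expect_lt(paired_pulse(y3, c(125L, 165L))$ratio, 1)

  # amp1 <= 0 flags the ratio undefined
  y4 <- rep(0, 200); y4[115:124] <- 1; y4[112:114] <- 1
  expect_warning(pp4 <- paired_pulse(y4, c(125L, 165L)), "undefined")
  expect_true(is.na(pp4$ratio))
})

test_that("overlapping paired-pulse amplitudes match the analytic-kernel oracle", {
  rise <- 15; decay <- 60; onset <- 10; A <- 0.2
  frames <- seq_len(200)
  k1 <- A * oracle_doe((frames - 125) * 10, onset, rise, decay)
  k2 <- A * oracle_doe((frames - 135) * 10, onset, rise, decay)
  y <- k1 + k2  # stimuli 100 ms apart, linear superposition
  pp <- paired_pulse(y, c(125L, 135L))
  # brute-force evaluation of the same windows/baselines on the summed trace
  amp1 <- max(y[127:135]) - mean(y[123:124])
  amp2 <- max(y[137:145]) - mean(y[133:134])
  expect_equal(pp$amp1, amp1)
  expect_equal(pp$amp2, amp2)
  expect_equal(pp$ratio, amp2 / amp1)
})

test_that("asymmetry index follows both formula variants", {
  expect_equal(asymmetry_index(10, 10, 0), 0.5)
  expect_equal(asymmetry_index(10, 10, 0, variant = "plus"), 0.5)
  expect_equal(asymmetry_index(10, 0, 0), 1)
  expect_equal(asymmetry_index(10, 10, 10), (10 - 5) / 30)
  expect_equal(asymmetry_index(10, 10, 10, variant = "plus"), 0.5)
  expect_error(asymmetry_index(0, 0, 0), "> 0")
  expect_error(asymmetry_index(-1, 2, 0), ">= 0")
})

test_that("metrics are scale-equivariant and shift-invariant", {
  set.seed(9)
  y <- rep(0, 200)
  y[127:170] <- 0.2 * exp(-(seq_len(44) - 5)^2 / 40) -
    0.05 * exp(-(seq_len(44) - 30)^2 / 90)
  y <- y + rnorm(200, 0, 0.005)
  m0 <- response_metrics(y, 125)
  for (k in c(0.5, 3)) {
    mk <- response_metrics(k * y, 125)
    expect_equal(mk$peak_amp, k * m0$peak_amp)
    expect_equal(mk$hyp_amp, k * m0$hyp_amp)
    expect_equal(mk$peak_time_ms, m0$peak_time_ms)
    expect_equal(mk$hyp_time_ms, m0$hyp_time_ms)
    expect_equal(mk$decay50_ms, m0$decay50_ms)
  }
  ms <- response_metrics(y + 5, 125)
  for (col in c("peak_amp", "peak_time_ms", "hyp_amp", "hyp_time_ms",
                "decay50_ms")) {
    expect_equal(ms[[col]], m0[[col]])
  }
  pp0 <- paired_pulse(y, c(125L, 165L))
  ppk <- paired_pulse(2 * y + 1, c(125L, 165L))
  expect_equal(ppk$ratio, pp0$ratio)
})

test_that("metrics recover kernel parameters over many noisy traces", {
  # paper-like region-trace noise (~0.01 %dR/R per frame)
  set.seed(77)
  cfg <- tiny_config()
  v <- generate_voltage_truth(cfg, seed = 1)$V["S1FL", ]
  n <- 250
  peaks <- times <- numeric(n)
  for (i in seq_len(n)) {
    y <- v + rnorm(200, 0, 0.0105)
    pk <- detect_peak(y, 125)
    peaks[i] <- pk$peak_amp; times[i] <- pk$peak_time_ms
  }
  expect_lt(abs(median(peaks) - 0.195) / 0.195, 0.05)
  expect_lte(abs(median(times) - 60), 10)
})
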