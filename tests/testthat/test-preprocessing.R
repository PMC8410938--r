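# Binning, dark offset, normalisation, equalisation and dR/R conversion.

test_that("binning averages blocks exactly and preserves the global mean", {
  fr <- matrix(runif(1200 * 1920, 0, 4095), 1200, 1920)
  b <- bin_spatial(fr, 4)  # the standard acquisition frame
  expect_equal(dim(b), c(300L, 480L))
  expect_equal(b[1, 1], mean(fr[1:4, 1:4]))
  expect_equal(b[300, 480], mean(fr[1197:1200, 1917:1920]))
  expect_equal(mean(b), mean(fr), tolerance = 1e-12)

  expect_equal(as.vector(bin_spatial(matrix(3.7, 8, 8), 4)), rep(3.7, 4))
  cb <- matrix(c(0, 1), 4, 4)  # alternating rows
  expect_equal(as.numeric(bin_spatial(cb, 4)), 0.5)
  expect_error(bin_spatial(matrix(0, 10, 8), 4), "crop to 8 x 8")
})

test_that("dark-offset subtraction removes the per-pixel camera offset", {
  o <- matrix(runif(12 * 20, 80, 120), 12, 20)
  stack <- array(as.vector(o), c(12, 20, 50))
  stack[, , 11:50] <- stack[, , 11:50] + 500
  sq <- dual_channel_seq(stack, stack, dark_frames = c(1L, 10L),
                         stim_frames = 40L)
  out <- subtract_dark_offset(sq)
  expect_equal(max(abs(out$donor[, , 1:10])), 0)
  expect_equal(out$donor[, , 11:50], array(500, c(12, 20, 40)))
})

test_that("residual dark-frame bias shrinks as sd/sqrt(n_dark)", {
  set.seed(42)
  n_dark <- 25; sigma <- 10; npix <- 4000
  # Monte-Carlo oracle: offset estimate error has sd sigma / sqrt(25)
  noise <- matrix(rnorm(npix * n_dark, 0, sigma), npix)
  est_err <- rowMeans(noise)  # offset estimate - true offset
  expect_equal(sd(est_err), sigma / sqrt(n_dark), tolerance = 0.1)
  # implementation path agrees
  stack <- array(100, c(40, 100, 30))
  stack[, , 1:25] <- stack[, , 1:25] + rnorm(40 * 100 * 25, 0, sigma)
  sq <- dual_channel_seq(stack, stack, dark_frames = c(1L, 25L),
                         stim_frames = 28L)
  out <- subtract_dark_offset(sq)
  resid <- out$donor[, , 26] - 0  # lit frame was exactly the offset level
  expect_equal(sd(as.vector(resid)), sigma / sqrt(n_dark), tolerance = 0.15)
})

test_that("pre-stimulus normalisation yields unit baseline", {
  stack <- array(200, c(4, 5, 60))
  stack[, , 1:2] <- 0
  stack[2, 3, 50] <- 202
  sq <- dual_channel_seq(stack, stack, dark_frames = c(1L, 2L),
                         stim_frames = 45L)
  nrm <- normalize_prestim(sq, baseline_window = c(5L, 40L))
  expect_equal(nrm$donor_norm[1, 1, 30], 1)
  expect_equal(nrm$donor_norm[2, 3, 50], 1.01)  # 202 / 200
  bl <- rowMeans(nrm$donor_norm[, , 5:40], dims = 2)
  expect_lt(max(abs(bl - 1)), 1e-9)
})

test_that("non-positive baseline pixels are flagged vessel-like", {
  stack <- array(200, c(4, 5, 60)); stack[, , 1:2] <- 0
  stack[1, 1, ] <- 0  # dead pixel
  sq <- dual_channel_seq(stack, stack, dark_frames = c(1L, 2L),
                         stim_frames = 45L)
  expect_warning(nrm <- normalize_prestim(sq, c(5L, 40L)), "non-positive")
  expect_false(nrm$valid_mask[1, 1])
  expect_true(nrm$valid_mask[2, 2])
})

test_that("binning and dark-offset subtraction commute", {
  set.seed(7)
  stack <- array(runif(16 * 16 * 20, 0, 400), c(16, 16, 20))
  sq <- function(s) dual_channel_seq(s, s, dark_frames = c(1L, 5L),
                                     stim_frames = 15L)
  a <- bin_sequence(subtract_dark_offset(sq(stack)), 4)$donor
  b <- subtract_dark_offset(sq(bin_spatial(stack, 4)))$donor
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("heartbeat gain estimation recovers exact sinusoid ratios", {
  nt <- 200; fr <- 100
  t_abs <- (seq_len(nt) - 1) / fr
  hb <- sin(2 * pi * 10 * t_abs + 0.3)
  mk <- function(depth) {
    arr <- array(0, c(6, 8, nt))
    arr[] <- rep(1 + depth * hb, each = 48)
    arr
  }
  # identical sinusoids -> gain 1 everywhere
  nrm <- manual_norm_seq(mk(0.02), mk(0.02), stim_frames = 150L,
                         baseline_window = c(31L, 120L))
  g <- estimate_heartbeat_gain(nrm)
  expect_false(g$fallback)
  expect_equal(g$f_hb, 10)
  expect_lt(max(abs(g$gain - 1)), 1e-9)
  # donor depth 0.02, acceptor 0.01 -> gain 0.5, closed form
  nrm2 <- manual_norm_seq(mk(0.02), mk(0.01), stim_frames = 150L,
                          baseline_window = c(31L, 120L))
  g2 <- estimate_heartbeat_gain(nrm2, median_filter = FALSE, clip = NULL)
  expect_lt(max(abs(g2$gain - 0.5)), 1e-9)
  # band excluding the injected frequency -> fallback with warning
  expect_warning(g3 <- estimate_heartbeat_gain(nrm2, hb_band = c(20, 30)),
                 "falling back")
  expect_true(g3$fallback)
  expect_true(all(g3$gain == 1))
})

test_that("equalisation matches channel heartbeat amplitudes", {
  nt <- 200; fr <- 100
  t_abs <- (seq_len(nt) - 1) / fr
  hb <- sin(2 * pi * 10 * t_abs + 1.1)
  mk <- function(depth) {
    arr <- array(0, c(6, 8, nt)); arr[] <- rep(1 + depth * hb, each = 48); arr
  }
  nrm <- manual_norm_seq(mk(0.02), mk(0.01), stim_frames = 150L,
                         baseline_window = c(31L, 120L))
  g <- estimate_heartbeat_gain(nrm, median_filter = FALSE, clip = NULL)
  eq <- apply_equalization(nrm, g)
  amp_at_10 <- function(x) {
    y <- x[3, 3, 31:120]; y <- y - mean(y)
    2 * Mod(fft(y)[10]) / 90  # bin 9 = 10 Hz over a 0.9 s segment
  }
  expect_equal(amp_at_10(eq$donor_norm) / amp_at_10(eq$acceptor_norm), 1,
               tolerance = 0.01)
  # gain 1 is the identity
  eq1 <- apply_equalization(nrm, matrix(1, 6, 8))
  expect_equal(eq1$donor_norm, nrm$donor_norm)
})

test_that("dR/R arithmetic, baseline zeroing and common-mode rejection are exact", {
  nt <- 60
  d <- array(1, c(3, 4, nt)); a <- array(1, c(3, 4, nt))
  a[2, 2, 50] <- 1.01; d[2, 2, 50] <- 0.99
  nrm <- manual_norm_seq(d, a, stim_frames = 45L, baseline_window = c(5L, 40L))
  rs <- compute_drr(nrm, r0_window = c(5L, 40L))
  expect_equal(rs$drr[2, 2, 50], (1.01 / 0.99 - 1) * 100)
  expect_equal(rs$drr[1, 1, 30], 0)
  # baseline-zero invariant at every valid pixel
  r0 <- rowMeans(rs$drr[, , 5:40], dims = 2)
  expect_lt(max(abs(r0[rs$valid_mask])), 1e-9)
  # purely multiplicative common-mode artifact cancels exactly
  cm <- 1 + 0.05 * sin(seq_len(nt))
  d2 <- array(rep(cm, each = 12), c(3, 4, nt))
  nrm2 <- manual_norm_seq(d2, d2, stim_frames = 45L,
                          baseline_window = c(5L, 40L))
  rs2 <- compute_drr(nrm2, r0_window = c(5L, 40L))
  expect_true(all(abs(rs2$drr[, , 3:nt]) < 1e-12))
})

test_that("ratiometric conversion amplifies anticorrelated signals", {
  nt <- 60; delta <- 0.002
  d <- array(1, c(2, 2, nt)); a <- array(1, c(2, 2, nt))
  d[, , 50] <- 1 - delta; a[, , 50] <- 1 + delta
  nrm <- manual_norm_seq(d, a, stim_frames = 45L, baseline_window = c(5L, 40L))
  rs <- compute_drr(nrm, r0_window = c(5L, 40L))
  expect_gt(rs$drr[1, 1, 50] / 100, delta)            # > single-channel dF/F
  expect_equal(rs$drr[1, 1, 50] / 100, 2 * delta, tolerance = 0.01)
})

test_that("equalisation suppresses heartbeat-band dR/R power at least tenfold", {
  cfg <- tiny_config(optics = list(noise_sd_counts = 2), vessel_spec = list(),
                     stimulus = "none")
  sim <- simulate_trial(cfg, seed = 21, behavior = FALSE)
  b <- subtract_dark_offset(bin_sequence(sim$seq, 4))
  nrm <- normalize_prestim(b)
  g <- estimate_heartbeat_gain(nrm)
  band_power <- function(rs) {
    tr <- colMeans(matrix(rs$drr, ncol = cfg$n_frames)[as.vector(rs$valid_mask), 31:120])
    y <- tr - mean(tr)
    am <- 2 * Mod(fft(y)[2:45]) / 90
    sum(am[8:10]^2)  # bins around the 10 Hz heartbeat
  }
  p_before <- band_power(compute_drr(nrm))
  p_after <- band_power(compute_drr(apply_equalization(nrm, g)))
  expect_lt(p_after, p_before / 10)
})

test_that("the full preprocessing chain recovers a clean step response", {
  kk <- list(S1FL = list(A_dep = 0.2, onset_delay = 10, peak_latency = 59.83,
                         decay_tau = 90, A_hyp = 0, hyp_onset = 100,
                         hyp_peak_time = 180, hyp_decay_tau = 250))
  cfg <- clean_config(region_kernels = kk)
  sim <- simulate_trial(cfg, seed = 31, behavior = FALSE)
  ratio <- preprocess_trial(sim$seq)
  labels <- rasterize_atlas(sim$truth$layout, dim(ratio$drr)[1:2])
  tr <- region_trace(ratio, labels, "S1FL")
  v <- sim$truth$V["S1FL", ]
  # quantisation-limited agreement (12-bit counts; ~0.05 % steps per pixel,
  # reduced by averaging over the region)
  expect_lt(max(abs(tr$drr_pct[30:200] - v[30:200])), 0.06)
})
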