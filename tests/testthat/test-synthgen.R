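# Generator: paradigm structure, ground truth, determinism, calibration.

test_that("single-frequency stimulation delivers the exact pulse count", {
  cfg <- generator_config(n_cells = 10, background_rate = 0,
                          reverb_fraction = 0, stim_response_prob = 1,
                          seed = 1)
  out <- generate_raster(cfg, stim_pattern("single", frequency = 3))
  w <- epoch_window(out$timeline, "stim")
  for (t in out$raster$spikes)
    expect_equal(sum(t >= w[1] & t < w[2]), 30)   # 3 Hz x 10 s
})

test_that("doublet stimulation delivers the enumerated pulse count", {
  # independent oracle: enumerate doublet repeats fitting in [0, 10)
  d <- 0.16; P <- 0.46
  oracle <- 0L
  k <- 0L
  repeat {
    s <- k * P
    if (s >= 10) break
    oracle <- oracle + 1L                   # first spike of the doublet
    if (s + d < 10) oracle <- oracle + 1L   # second spike
    k <- k + 1L
  }
  expect_equal(oracle, 44L)   # 22 complete doublets
  cfg <- generator_config(n_cells = 5, background_rate = 0,
                          reverb_fraction = 0, stim_response_prob = 1,
                          seed = 2)
  out <- generate_raster(cfg, stim_pattern("doublet", doublet_isi = d,
                                           pattern_period = P))
  w <- epoch_window(out$timeline, "stim")
  for (t in out$raster$spikes)
    expect_equal(sum(t >= w[1] & t < w[2]), oracle)
})

test_that("reverb_fraction 0 leaves poststim statistically at baseline", {
  cfg <- generator_config(n_cells = 500, reverb_fraction = 0, seed = 3)
  out <- generate_raster(cfg, stim_pattern("single", frequency = 8))
  v <- segment(out$raster, out$timeline)
  n_pre <- sum(lengths(v$prestim$spikes))
  n_post <- sum(lengths(v$poststim$spikes))
  # equal-duration epochs, same Poisson rate: two-sample rate test
  p <- stats::poisson.test(c(n_pre, n_post), c(60, 60))$p.value
  expect_gt(p, 0.01)
})

test_that("identical config and seed give bit-identical rasters", {
  cfg <- generator_config(n_cells = 40, seed = 11)
  pat <- stim_pattern("single", frequency = 5)
  a <- generate_raster(cfg, pat)
  b <- generate_raster(cfg, pat)
  expect_identical(a$raster$spikes, b$raster$spikes)
  expect_identical(a$truth$reverb_cells, b$truth$reverb_cells)
  cfg2 <- generator_config(n_cells = 40, seed = 12)
  expect_false(identical(generate_raster(cfg2, pat)$raster$spikes,
                         a$raster$spikes))
})

test_that("prestim firing rate recovers background_rate within 3 SE", {
  cfg <- generator_config(n_cells = 400, background_rate = 0.2,
                          reverb_fraction = 0, seed = 5)
  out <- generate_raster(cfg, stim_pattern("single", frequency = 5))
  v <- segment(out$raster, out$timeline)
  n <- sum(lengths(v$prestim$spikes))
  expected <- 0.2 * 60 * 400
  se <- sqrt(expected)   # Poisson
  expect_lt(abs(n - expected), 3 * se)
})

test_that("ground truth is internally consistent", {
  cfg <- generator_config(n_cells = 100, reverb_fraction = 0.25,
                          reverb_jitter_sd = 0, stim_response_prob = 1,
                          background_rate = 0, seed = 7)
  pat <- stim_pattern("single", frequency = 3)
  out <- generate_raster(cfg, pat)
  tr <- out$truth
  expect_true(all(tr$reverb_cells %in% tr$active_cells))
  expect_equal(length(tr$reverb_cells),
               round(0.25 * length(tr$active_cells)))
  # jitter 0, response 1: each reverb cell carries at least
  # reverb_duration/period - 1 pattern-locked ISIs in the poststim epoch
  v <- segment(out$raster, out$timeline)
  isis <- compute_isis(v$poststim)
  min_locked <- 20 * 3 - 1
  for (i in tr$reverb_cells) {
    locked <- sum(abs(isis[[as.character(i)]] - 1 / 3) <= 0.02)
    expect_gte(locked, min_locked)
  }
})

test_that("refractory floor removes near-zero ISIs", {
  cfg <- generator_config(n_cells = 50, background_rate = 2, seed = 8)
  out <- generate_raster(cfg, stim_pattern("single", frequency = 8))
  isis <- unlist(compute_isis(out$raster))
  expect_true(all(isis >= 0.005 - 1e-12))
})

test_that("invalid worlds are rejected", {
  cfg <- generator_config(n_cells = 5)
  expect_error(generate_raster(cfg, stim_pattern("single", frequency = 30)),
               "unresolvable")
  expect_error(generate_raster(cfg, stim_pattern("single", frequency = 3,
                                                 duration = 12)),
               "stim epoch")
  expect_error(generator_config(reverb_fraction = 1.2), "reverb_fraction")
  expect_error(stim_pattern("doublet", doublet_isi = 0.5,
                            pattern_period = 0.4), "smaller")
})

test_that("recruitment recovery is monotone in reverb_fraction", {
  rec <- vapply(c(0, 0.1, 0.25, 0.5), function(f) {
    cfg <- generator_config(n_cells = 100, reverb_fraction = f,
                            reverb_jitter_sd = 0, stim_response_prob = 1,
                            seed = 31)
    out <- generate_raster(cfg, stim_pattern("single", frequency = 5))
    v <- segment(out$raster, out$timeline)
    act <- select_active(out$raster, out$timeline)
    m <- lapply(v[c("prestim", "stim", "poststim")], function(ep)
      match_cells_at_period(compute_isis(ep)[as.character(act$cells)],
                            0.2, 0.02))
    reverberation_stats(m$prestim, m$stim, m$poststim,
                        n_active = length(act$cells))$pct_cells_increase
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})
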