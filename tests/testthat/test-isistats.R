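# ISI statistics: histograms, matching, reverberation report, peaks.

test_that("ISIs are successive differences; short trains give none", {
  r <- spike_raster(list(c(0, 0.33, 0.66), 0.5, numeric(0)), duration = 1)
  isis <- compute_isis(r)
  expect_equal(isis[[1]], c(0.33, 0.33))
  expect_equal(isis[[2]], numeric(0))
  expect_equal(isis[[3]], numeric(0))
  r3 <- regular_raster(1 / 3, 10 + 1e-6, total = 11)
  expect_equal(length(r3$spikes[[1]]), 31)
  expect_equal(compute_isis(r3)[[1]], rep(1 / 3, 30))
})

test_that("a perfect 3 Hz train peaks in the bin containing 0.33 s", {
  h <- build_histogram(rep(1 / 3, 1000), 0.02)
  b <- modal_bin(h)
  expect_true(h$edges[b] <= 1 / 3 && 1 / 3 < h$edges[b + 1])
  expect_equal(round(h$mids[b], 2), 0.33)
  expect_equal(sum(h$counts), h$n_isis)
})

test_that("identical ISIs give a single nonzero bin; empty input is legal", {
  h <- build_histogram(rep(0.25, 50), 0.02)
  expect_equal(sum(h$counts > 0), 1L)
  h0 <- build_histogram(numeric(0), 0.02)
  expect_equal(h0$n_isis, 0L)
  expect_true(is.na(modal_bin(h0)))
})

test_that("exponential ISIs match the exponential pdf (chi-square GOF)", {
  withr::with_seed(41, {
    x <- stats::rexp(1e4, rate = 1)
    h <- build_histogram(x, 0.05)
    p_bin <- diff(stats::pexp(h$edges, rate = 1))
    # merge the sparse tail so expected counts stay > 5
    keep <- which(p_bin * 1e4 >= 5)
    obs <- c(h$counts[keep], 1e4 - sum(h$counts[keep]))
    pr <- c(p_bin[keep], 1 - sum(p_bin[keep]))
    gof <- stats::chisq.test(obs, p = pr)
    expect_gt(gof$p.value, 0.01)
  })
})

test_that("the +/- 1 bin matching rule is symmetric around the period", {
  m <- match_cells_at_period(list(a = 0.34), 1 / 3, 0.02, min_matches = 1)
  expect_equal(m$n_isis, 1L)
  m2 <- match_cells_at_period(list(a = 0.40), 1 / 3, 0.02, min_matches = 1)
  expect_equal(m2$n_isis, 0L)
})

test_that("match_cells_at_period equals the brute-force oracle", {
  withr::with_seed(43, {
    # 100 cells of Poisson 1 Hz activity over 60 s
    spikes <- lapply(1:100, function(i) {
      t <- cumsum(stats::rexp(200, 1))
      t[t < 60]
    })
    r <- spike_raster(spikes, duration = 60)
    expect_lte(n_spikes(r), 1e4)
    for (period in c(0.125, 1 / 3, 1)) {
      fast <- match_cells_at_period(r, period, 0.02)
      slow <- match_cells_bruteforce(r, period, 0.02)
      expect_identical(fast$n_isis, slow$n_isis)
      expect_identical(fast$n_cells, slow$n_cells)
      expect_identical(fast$cells, slow$cells)
      expect_identical(fast$per_cell, slow$per_cell)
    }
  })
})

test_that("percent-increase statistics follow the defining formula", {
  mk <- function(n_isis, n_cells = 0) structure(
    list(n_isis = n_isis, n_cells = n_cells, per_cell = integer(0),
         cells = character(0)), class = "period_match")
  expect_equal(reverberation_stats(mk(10), mk(50), mk(10),
                                   n_active = 100)$pct_increase_total, 0)
  expect_equal(reverberation_stats(mk(5), mk(50), mk(30),
                                   n_active = 100)$pct_increase_total, 50)
  # unequal durations are rate-normalized to 60 s before comparison
  r <- reverberation_stats(mk(10), mk(50), mk(30), n_active = 100,
                           durations = c(pre = 60, stim = 10, post = 90))
  expect_equal(r$pct_increase_total, 100 * (30 * 60 / 90 - 10) / 50)
  expect_true(r$unequal_pre_post)
  # undefined when nothing matched during stimulation
  r0 <- reverberation_stats(mk(5), mk(0), mk(30), n_active = 100)
  expect_true(is.na(r0$pct_increase_total))
  expect_match(r0$note, "undefined")
  # cell recruitment normalized by the active population
  r2 <- reverberation_stats(mk(0, 2), mk(0, 40), mk(0, 14), n_active = 50)
  expect_equal(r2$pct_cells_increase, 100 * (14 - 2) / 50)
})

test_that("null worlds give pct_increase_total centered on zero", {
  vals <- vapply(1:12, function(s) {
    out <- demo_recording(seed = 100 + s, n_cells = 80, frequency = 8,
                          reverb_fraction = 0)
    v <- segment(out$raster, out$timeline)
    act <- select_active(out$raster, out$timeline)
    m <- lapply(v[c("prestim", "stim", "poststim")], function(ep)
      match_cells_at_period(compute_isis(ep)[as.character(act$cells)],
                            1 / 8, 0.02))
    reverberation_stats(m$prestim, m$stim, m$poststim,
                        n_active = length(act$cells))$pct_increase_total
  }, numeric(1))
  ci <- mean(vals) + c(-1, 1) * 2 * stats::sd(vals) / sqrt(length(vals))
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("doublet component decomposition reports d, P-d and P", {
  d <- 0.16; P <- 0.46
  pat <- stim_pattern("doublet", doublet_isi = d, pattern_period = P)
  # no failures: peaks at d and P-d only, nothing at P
  isis <- unlist(lapply(doublet_train(d, P, 10, n_cells = 50), diff))
  h <- build_histogram(isis, 0.02)
  dec <- decompose_components(h, pat)
  expect_equal(dec$component, c("d", "P-d", "P"))
  expect_true(all(dec$is_peak[1:2]))
  expect_equal(dec$mass[3], 0)
  # 10% per-spike dropout: the P peak emerges
  withr::with_seed(47, {
    isis2 <- unlist(lapply(doublet_train(d, P, 10, dropout = 0.1,
                                         n_cells = 200), diff))
  })
  dec2 <- decompose_components(build_histogram(isis2, 0.02), pat)
  expect_true(all(dec2$is_peak))
  expect_gt(dec2$mass[3], 0)
  expect_lt(dec2$mass[3], dec2$mass[1])
  # second doublet spike always dropped: only the P interval remains
  t <- pattern_spike_times(pat)
  firsts <- t[abs((t / P) - round(t / P)) < 1e-9]
  dec3 <- decompose_components(build_histogram(diff(firsts), 0.02), pat)
  expect_false(dec3$is_peak[1])
  expect_false(dec3$is_peak[2])
  expect_true(dec3$is_peak[3])
  # single-frequency patterns report just the period
  dec4 <- decompose_components(build_histogram(rep(1 / 3, 10), 0.02),
                               stim_pattern("single", frequency = 3))
  expect_equal(nrow(dec4), 1L)
  expect_equal(dec4$period_s, 1 / 3)
})

test_that("peak locations are quantization-free for period-locked trains", {
  h <- build_histogram(rep(c(0.16, 0.30), 500), 0.02)
  pk <- isi_peaks(h)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$location, c(0.16, 0.30), tolerance = 1e-9)
})
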