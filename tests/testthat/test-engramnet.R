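# Training-set construction, classifier training, sliding-window scan.

test_that("positive count equals active cells x complete cycles", {
  # 1 s cycle, 10 s stim -> 10 cycles per cell
  cfg <- generator_config(n_cells = 500, background_rate = 0,
                          reverb_fraction = 0, stim_response_prob = 1,
                          seed = 51)
  pat <- stim_pattern("doublet", doublet_isi = 0.1, pattern_period = 1)
  out <- generate_raster(cfg, pat)
  ts <- build_training_set(out$raster, out$timeline, seed = 1)
  expect_equal(sum(ts$y == "pattern"), 5000L)
  expect_equal(sum(ts$y == "null"), 5000L)
  expect_equal(ts$n_bins, 50L)
})

test_that("isi_shuffle permutes gaps, preserving multiset and offset", {
  # spikes [0, 0.1, 0.5] in a 1 s window at 20 ms bins: bins {1, 6, 26}
  v <- integer(50); v[c(1, 6, 26)] <- 1L
  outs <- withr::with_seed(53, {
    replicate(200, paste(which(engramr:::shuffle_sequence(v) == 1L),
                         collapse = ","))
  })
  expect_setequal(unique(outs), c("1,6,26", "1,21,26"))
  expect_true(all(table(outs) > 50))   # both permutations well represented
})

test_that("degenerate sequences fall back to randomized ISIs", {
  # clean doublet cycle: one ISI, no distinct permutation
  v <- integer(23); v[c(1, 9)] <- 1L
  withr::with_seed(54, {
    for (i in 1:50) {
      s <- engramr:::shuffle_sequence(v)
      expect_equal(sum(s), 2L)
      expect_equal(which(s == 1L)[1], 1L)     # first-spike offset kept
      expect_false(identical(s, v))
    }
    # single spike: uniform random placement
    v1 <- integer(23); v1[5] <- 1L
    draws <- replicate(100, which(engramr:::shuffle_sequence(v1) == 1L))
    expect_gt(length(unique(draws)), 10)
  })
})

test_that("cycle windows exceeding the sequence cap are rejected", {
  out <- clean_doublet_world(55, n_cells = 2)
  pat <- stim_pattern("doublet", doublet_isi = 0.5, pattern_period = 5,
                      duration = 10)
  expect_error(
    build_training_set(out$raster, out$timeline, pattern = pat, seed = 1),
    "sequence cap")
})

test_that("BPTT gradients match finite differences", {
  withr::with_seed(57, {
    p <- engramr:::rnn_init(1, 3, seed = 2)
    X <- matrix(stats::rbinom(8 * 5, 1, 0.4), 8, 5)
    y <- rep(c(0, 1), 4)
    lg <- engramr:::rnn_loss_grads(p, X, y)
    num_grad <- function(k, i) {
      eps <- 1e-6
      p1 <- p; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- p; p2[[k]][i] <- p2[[k]][i] - eps
      (engramr:::rnn_loss_grads(p1, X, y)$loss -
         engramr:::rnn_loss_grads(p2, X, y)$loss) / (2 * eps)
    }
    for (k in names(p)) {
      idx <- seq_len(min(length(p[[k]]), 4))
      for (i in idx) {
        a <- lg$grads[[k]][i]
        n <- num_grad(k, i)
        expect_lt(abs(a - n), 1e-4 * max(1, abs(n)))
      }
    }
  })
})

test_that("the classifier reaches 100% on clean doublet training patterns", {
  out <- clean_doublet_world(59)
  ts <- build_training_set(out$raster, out$timeline, seed = 2)
  expect_equal(ts$n_duplicate_negatives, 0L)
  clf <- train_engram_classifier(
    ts, classifier_spec(max_epochs = 30, seed = 3),
    validation = build_training_set(clean_doublet_world(60)$raster,
                                    out$timeline, seed = 4))
  expect_true(clf$converged)
  expect_equal(clf$train_accuracy, 1)
  expect_equal(clf$pattern_accuracy, 1)
  expect_gte(clf$validation_accuracy, 0.99)
})

test_that("indistinguishable classes train to chance and are flagged", {
  withr::with_seed(61, {
    X <- matrix(stats::rbinom(60 * 10, 1, 0.2), 60, 10)
    ts <- structure(list(X = rbind(X, X),
                         y = factor(rep(c("pattern", "null"), each = 60),
                                    levels = c("null", "pattern")),
                         n_bins = 10L, bin_width = 0.02,
                         null_kind = "isi_shuffle",
                         pattern = stim_pattern("doublet",
                                                doublet_isi = 0.06,
                                                pattern_period = 0.2),
                         meta = NULL, n_duplicate_negatives = 60L),
                    class = "training_set")
    clf <- train_engram_classifier(
      ts, classifier_spec(hidden = 8, max_epochs = 15, seed = 5))
    expect_false(clf$converged)
    expect_lt(clf$train_accuracy, 0.7)
    expect_gt(clf$train_accuracy, 0.3)
  })
})

test_that("training is deterministic given a seed", {
  out <- clean_doublet_world(63, n_cells = 6)
  ts <- build_training_set(out$raster, out$timeline, seed = 2)
  spec <- classifier_spec(hidden = 16, max_epochs = 10, seed = 7)
  a <- train_engram_classifier(ts, spec)
  b <- train_engram_classifier(ts, spec)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("scan finds replay, skips empty cells, peaks in the stim epoch", {
  out <- clean_doublet_world(65, n_cells = 20)
  ts <- build_training_set(out$raster, out$timeline, seed = 2)
  clf <- train_engram_classifier(ts, classifier_spec(max_epochs = 30,
                                                     seed = 3))
  # cell 1: exact whole-pattern replay in the poststim epoch
  pw <- epoch_window(out$timeline, "poststim")
  pat <- out$timeline$pattern
  replay <- pattern_spike_times(pat, onset = pw[1] + 2, duration = 10)
  stim_spikes <- out$raster$spikes[[1]]
  r <- spike_raster(list(sort(c(stim_spikes, replay)), numeric(0)),
                    duration = out$raster$duration)
  dm <- scan_raster(r, clf, window_step = 0.02, threshold = 0.5,
                    timeline = out$timeline)
  ev1 <- dm$events[dm$events$cell_id == 1, ]
  post <- ev1[ev1$epoch == "poststim", ]
  expect_gte(nrow(post), 1)
  expect_true(any(post$start_s < pw[1] + 12 & post$end_s > pw[1] + 2))
  expect_true(all(post$peak_conf > 0.5))
  # the stimulation region itself is detected
  expect_true(any(ev1$epoch == "stim"))
  # empty cell: no events, zero confidence
  expect_equal(sum(dm$events$cell_id == 2), 0L)
  expect_true(all(dm$confidence[2, ] == 0))
})

test_that("halving the step does not lose merged events", {
  out <- clean_doublet_world(67, n_cells = 8)
  ts <- build_training_set(out$raster, out$timeline, seed = 2)
  clf <- train_engram_classifier(ts, classifier_spec(max_epochs = 20,
                                                     seed = 3))
  dm4 <- scan_raster(out$raster, clf, window_step = 0.04)
  dm2 <- scan_raster(out$raster, clf, window_step = 0.02)
  short4 <- sum(dm4$events$end_s - dm4$events$start_s < 0.04)
  expect_gte(nrow(dm2$events), nrow(dm4$events) - short4)
})

test_that("engram_increase handles both denominators and empty epochs", {
  tl <- toy_timeline(stim_pattern("single", frequency = 5),
                     prestim = 20, poststim = 20)
  ev <- function(n_pre, n_post, n_stim = 0) {
    n <- n_pre + n_stim + n_post
    s <- c(stats::runif(n_pre, 10, 29), stats::runif(n_stim, 30, 39),
           stats::runif(n_post, 40, 59))
    data.frame(cell_id = rep(1L, n), start_s = s, end_s = s + 0.2,
               peak_conf = rep(1, n), peak_s = s,
               epoch = rep(c("prestim", "stim", "poststim"),
                           c(n_pre, n_stim, n_post)))
  }
  expect_equal(engram_increase(ev(0, 0), tl)$pct_increase, 0)
  expect_equal(engram_increase(ev(2, 10), tl)$pct_increase, 400)
  e <- ev(2, 10, n_stim = 4)
  expect_equal(engram_increase(e, tl, denominator = "stim")$pct_increase,
               100 * (10 * 60 / 20 - 2 * 60 / 20) / 4)
})
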