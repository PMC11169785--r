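test_that("make_layout places electrodes at centroids with zero jitter and is seeded", {
  lay <- make_layout(1, two_roi_centroids(), jitter_sd = 0, seed = 1)
  expect_equal(nrow(lay$positions), 2)
  expect_equal(lay$positions[1, ], two_roi_centroids()$roiA)
  expect_equal(lay$positions[2, ], two_roi_centroids()$roiB)

  l1 <- make_layout(3, default_roi_centroids(), jitter_sd = 2, seed = 1)
  l2 <- make_layout(3, default_roi_centroids(), jitter_sd = 2, seed = 1)
  expect_identical(l1$positions, l2$positions)
  expect_equal(length(l1$ids), 24)
  expect_false(identical(l1$positions,
                         make_layout(3, default_roi_centroids(), 2, seed = 2)$positions))

  # law of large numbers: sample mean of jittered positions near the centroid
  big <- make_layout(500, list(o = c(0, 0, 0)), jitter_sd = 5, seed = 7)
  expect_true(all(abs(colMeans(big$positions)) < 4 * 5 / sqrt(500)))

  expect_error(make_layout(1, list()), class = "ecog_config_error")
})

test_that("make_labels runs a seeded Markov chain over the state set", {
  expect_equal(make_labels(5, "A", 0.5, seed = 3)$labels, rep("A", 5))
  expect_equal(make_labels(10, c("A", "B"), 1, seed = 9)$labels,
               rep(make_labels(10, c("A", "B"), 1, seed = 9)$labels[1], 10))
  lab <- make_labels(1000, c("A", "B"), 0.5, seed = 3)
  frac <- mean(lab$labels == "A")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
  expect_identical(lab$labels, make_labels(1000, c("A", "B"), 0.5, seed = 3)$labels)
  expect_error(make_labels(5, character(0)), class = "ecog_config_error")
})

test_that("synthesized carriers express effect multipliers in the band envelope", {
  lay <- make_layout(1, two_roi_centroids(), jitter_sd = 0, seed = 1)
  lab <- make_labels(6, c("Talking", "WatchingTV"), 0.5, seed = 5, block_s = 20)
  eff <- effect_map("roiA", "alpha", "Talking", 2.0)
  rec <- synthesize_recording(lay, lab, effects = eff,
                              noise = noise_spec(noise_sd = 0, drift_amplitude = 0),
                              fs = 250, base_amp = 4, seed = 2)
  env <- band_envelope(rec, c(8, 12))
  L <- 20 * 250
  block_mean <- vapply(seq_len(6), function(b) {
    mean(env[1, ((b - 1) * L + 251):(b * L - 250)])
  }, numeric(1))
  talk <- lab$labels == "Talking"
  ratio <- mean(block_mean[talk]) / mean(block_mean[!talk])
  expect_gt(ratio, 2 * 0.95)
  expect_lt(ratio, 2 * 1.05)
  # unmapped ROI is state-independent
  envB <- band_envelope(rec, c(8, 12))[2, ]
  bmB <- vapply(seq_len(6), function(b) mean(envB[((b - 1) * L + 251):(b * L - 250)]), numeric(1))
  expect_lt(abs(mean(bmB[talk]) / mean(bmB[!talk]) - 1), 0.02)
})

test_that("synthesis is bit-deterministic and channel-stable under the seed", {
  lay <- make_layout(2, two_roi_centroids(), jitter_sd = 1, seed = 1)
  lab <- make_labels(3, c("A", "B"), 0.5, seed = 1, block_s = 10)
  r1 <- synthesize_recording(lay, lab, fs = 250, seed = 42)
  r2 <- synthesize_recording(lay, lab, fs = 250, seed = 42)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, synthesize_recording(lay, lab, fs = 250, seed = 43)$data))
})

test_that("effect locality: unmapped ROIs carry no state effect at realistic noise", {
  lay <- make_layout(1, two_roi_centroids(), jitter_sd = 0, seed = 2)
  lab <- make_labels(50, c("Talking", "WatchingTV"), 0.5, seed = 4, block_s = 20)
  eff <- effect_map("roiA", "highgamma", "Talking", 1.8)
  rec <- synthesize_recording(lay, lab, effects = eff,
                              noise = noise_spec(noise_sd = 10, drift_amplitude = 5),
                              fs = 250, base_amp = 2, seed = 6)
  env <- band_envelope(rec, c(70, 110))
  L <- 20 * 250
  bm <- vapply(seq_len(50), function(b) mean(env[2, ((b - 1) * L + 1):(b * L)]), numeric(1))
  talk <- lab$labels == "Talking"
  expect_gt(t.test(bm[talk], bm[!talk])$p.value, 0.01)
})

test_that("inject_artifacts adds square bursts to a counted channel subset", {
  lay <- make_layout(5, two_roi_centroids(), jitter_sd = 1, seed = 1)
  lab <- make_labels(2, "A", 1, seed = 1, block_s = 10)
  rec <- synthesize_recording(lay, lab, fs = 250, noise = noise_spec(noise_sd = 5), seed = 3)
  expect_identical(inject_artifacts(rec, list(), seed = 1)$data, rec$data)
  out <- inject_artifacts(rec, list(list(start_s = 5, duration_s = 3,
                                         channel_fraction = 0.2,
                                         amplitude_uv = 500)), seed = 2)
  changed <- which(rowSums(out$data != rec$data) > 0)
  expect_length(changed, ceiling(0.2 * 10))
  expect_error(inject_artifacts(rec, list(list(start_s = 19, duration_s = 5,
                                               channel_fraction = 0.2,
                                               amplitude_uv = 10))),
               class = "ecog_input_error")
})

test_that("layouts and effect maps round-trip through YAML", {
  lay <- make_layout(2, two_roi_centroids(), jitter_sd = 1, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_layout_yaml(lay, f)
  lay2 <- read_layout_yaml(f)
  expect_equal(lay2$ids, lay$ids)
  expect_equal(lay2$positions, lay$positions, tolerance = 1e-8)
  eff <- effect_map(c("roiA", "roiB"), c("alpha", "beta"),
                    c("Talking", "WatchingTV"), c(1.5, 0.8))
  f2 <- tempfile(fileext = ".yaml")
  write_effects_yaml(eff, f2)
  expect_equal(as.data.frame(read_effects_yaml(f2)), as.data.frame(eff),
               ignore_attr = TRUE)
})

test_that("recordings round-trip through the directory container", {
  lay <- make_layout(2, two_roi_centroids(), jitter_sd = 1, seed = 1)
  lab <- make_labels(1, "A", 1, seed = 1, block_s = 10)
  rec <- synthesize_recording(lay, lab, fs = 250, seed = 9)
  d <- tempfile()
  write_recording(rec, d)
  rec2 <- read_recording(d)
  expect_equal(rec2$data, rec$data, tolerance = 1e-9)
  expect_equal(rec2$fs, rec$fs)
  expect_equal(rec2$positions, rec$positions, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
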