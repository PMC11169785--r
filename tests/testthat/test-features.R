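test_that("band envelope recovers sinusoid amplitude and rejects out-of-band tones", {
  rec <- sine_recording(10, 5, fs = 500, dur = 30)
  env <- band_envelope(rec, c(8, 12))
  interior <- (500):(29 * 500)
  expect_lt(max(abs(env[1, interior] - 5)), 0.25)

  leak <- band_envelope(rec, c(70, 110))
  expect_lt(max(leak[1, interior]), 0.05 * 5)

  zero <- ecog_recording(matrix(0, 1, 5000), fs = 500)
  expect_equal(max(band_envelope(zero, c(8, 12))), 0)
  expect_error(band_envelope(rec, c(200, 300)), class = "ecog_config_error")
})

test_that("bin_envelopes averages 10-s bins and drops the trailing partial bin", {
  const <- matrix(3, 1, 25 * 500)
  v <- bin_envelopes(const, fs = 500, bin_s = 10)
  expect_equal(dim(v)[1], 2)
  expect_equal(as.numeric(v[, 1, 1]), c(3, 3))

  fs <- 500
  ramp <- matrix((0:(20 * fs - 1)) / fs, 1)
  v2 <- bin_envelopes(ramp, fs = fs, bin_s = 10)
  expect_equal(as.numeric(v2[1, 1, 1]), 5 - 1 / (2 * fs), tolerance = 1e-10)

  block <- matrix(1, 1, 120 * 500)
  expect_equal(dim(bin_envelopes(block, 500, 10))[1], 12)
  expect_error(bin_envelopes(matrix(1, 1, 100), 500, 10), class = "ecog_input_error")
})

test_that("the artifact rule drops exactly the segments it should", {
  lay <- make_layout(10, two_roi_centroids(), jitter_sd = 1, seed = 1)
  lab <- make_labels(4, "A", 1, seed = 1, block_s = 120)
  rec <- synthesize_recording(lay, lab, fs = 250,
                              noise = noise_spec(noise_sd = 10, drift_amplitude = 0),
                              base_amp = 0, seed = 2)
  expect_true(all(artifact_mask(rec, artifact_rule())))

  sds <- apply(rec$data, 1, sd)
  burst <- function(frac, dur, amp_mult) {
    inject_artifacts(rec, list(list(start_s = 150, duration_s = dur,
                                    channel_fraction = frac,
                                    amplitude_uv = amp_mult * max(sds))),
                     seed = 3)
  }
  # fraction 0.2 >= 0.10, 3 s > 2 s, 10 sd: only segment 2 dropped
  expect_equal(artifact_mask(burst(0.2, 3, 10), artifact_rule()),
               c(TRUE, FALSE, TRUE, TRUE), ignore_attr = TRUE)
  # 5% of channels: below the 10% fraction, kept
  expect_true(all(artifact_mask(burst(0.05, 3, 10), artifact_rule())))
  # 1.5 s burst: not "more than 2 s", kept
  expect_true(all(artifact_mask(burst(0.2, 1.5, 10), artifact_rule())))
  # amplitude below 3 SD: kept
  expect_true(all(artifact_mask(burst(0.2, 3, 0.5), artifact_rule())))
})

test_that("attach_labels maps blocks to bins and composes masks", {
  vals <- array(1, c(24, 2, 1), dimnames = list(NULL, NULL, "alpha"))
  tab <- ecogstate:::new_features(vals, 10, default_bands()[2, ],
                                  rep(NA_character_, 24), rep(TRUE, 24), NULL)
  lab <- structure(list(labels = c("Talking", "WatchingTV"), block_s = 120,
                        states = c("Talking", "WatchingTV", "Sleep")),
                   class = "behavior_labels")
  out <- attach_labels(tab, lab)
  expect_equal(out$labels, rep(c("Talking", "WatchingTV"), each = 12))
  expect_true(all(out$keep))

  lab2 <- structure(list(labels = c("Talking", "Sleep"), block_s = 120,
                         states = c("Talking", "WatchingTV", "Sleep")),
                    class = "behavior_labels")
  out2 <- attach_labels(tab, lab2, states_of_interest = c("Talking", "WatchingTV"))
  expect_equal(sum(out2$keep), 12)

  tab3 <- tab
  tab3$keep[1:12] <- FALSE   # e.g. artifact-dropped segment
  out3 <- attach_labels(tab3, lab2, states_of_interest = c("Talking", "WatchingTV"))
  expect_equal(sum(out3$keep), 0)
})

test_that("wider bands pass more broadband power and masks conserve bins", {
  set.seed(8)
  rec <- ecog_recording(matrix(rnorm(2 * 60 * 250), nrow = 2), fs = 250)
  ft <- extract_features(rec, bin_s = 10, rule = NULL, engine = "filter")
  expect_gt(mean(ft$values[, , "beta"]), mean(ft$values[, , "alpha"]))

  lay <- make_layout(10, two_roi_centroids(), jitter_sd = 1, seed = 1)
  lab <- make_labels(3, "A", 1, seed = 1, block_s = 120)
  clean <- synthesize_recording(lay, lab, fs = 250,
                                noise = noise_spec(noise_sd = 10,
                                                   drift_amplitude = 0),
                                seed = 2)
  dirty <- inject_artifacts(clean, list(list(start_s = 130, duration_s = 5,
                                             channel_fraction = 0.5,
                                             amplitude_uv = 2000)), seed = 1)
  f_clean <- extract_features(clean, labels = lab, engine = "spectral")
  f_dirty <- extract_features(dirty, labels = lab, engine = "spectral")
  expect_lte(sum(f_dirty$keep), sum(f_clean$keep))
  expect_equal(sum(f_dirty$keep) + sum(!f_dirty$keep), length(f_dirty$keep))
})

test_that("filter and spectral feature engines agree on binned values", {
  lay <- make_layout(2, two_roi_centroids(), jitter_sd = 1, seed = 3)
  lab <- make_labels(3, c("A", "B"), 0.5, seed = 2, block_s = 120)
  rec <- synthesize_recording(lay, lab, fs = 250,
                              effects = effect_map("roiA", "alpha", "A", 1.5),
                              seed = 5)
  f1 <- extract_features(rec, labels = lab, engine = "filter")
  f2 <- extract_features(rec, labels = lab, engine = "spectral")
  rel <- abs(f1$values - f2$values) / (abs(f1$values) + 1e-12)
  expect_lt(median(rel), 0.01)
  expect_lt(max(rel), 0.06)
})

test_that("feature tables round-trip through long CSV", {
  fx <- feature_fixture(n_blocks = 4, seed = 2)
  f <- tempfile(fileext = ".csv")
  features_to_csv(fx$table, f)
  df <- read.csv(f)
  expect_equal(nrow(df), prod(dim(fx$table$values)))
  expect_true(all(c("bin", "channel", "band", "value", "label", "kept") %in% names(df)))
  back <- features_from_csv(f)
  expect_equal(back$values, fx$table$values, tolerance = 1e-12)
  expect_equal(back$labels, fx$table$labels)
  expect_equal(back$keep, fx$table$keep)
  unlink(f)
})
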