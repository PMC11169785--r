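# Shared fixture builders; everything is generated in code at test time.

two_roi_centroids <- function() {
  list(roiA = c(0, 0, 0), roiB = c(60, 0, 0))
}

# A sinusoid recording: one channel per row of `freqs`, amplitude `amps`.
sine_recording <- function(freqs, amps, fs = 500, dur = 30) {
  t <- (seq_len(fs * dur) - 1) / fs
  data <- do.call(rbind, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  ecog_recording(matrix(data, nrow = length(freqs)), fs = fs)
}

# Gaussian feature table with optional per-(roi, band) class mean shifts.
# rois: named list roi -> electrode count. shifts: data.frame(roi, band,
# delta) applied to the first class of `states`.
feature_fixture <- function(n_blocks = 60, bins_per_block = 12,
                            rois = list(roiA = 3, roiB = 3),
                            bands = default_bands(),
                            shifts = NULL,
                            states = c("Talking", "WatchingTV"),
                            persistence = 0.5, seed = 1) {
  labels <- make_labels(n_blocks, states, persistence, seed = seed,
                        block_s = bins_per_block * 10)
  nbins <- n_blocks * bins_per_block
  nch <- sum(unlist(rois))
  roi_of <- rep(names(rois), times = unlist(rois))
  set.seed(seed + 1)
  values <- array(rnorm(nbins * nch * nrow(bands)),
                  c(nbins, nch, nrow(bands)),
                  dimnames = list(NULL, NULL, bands$name))
  bin_lab <- rep(labels$labels, each = bins_per_block)
  if (!is.null(shifts)) {
    for (i in seq_len(nrow(shifts))) {
      ch <- which(roi_of == shifts$roi[i])
      bd <- match(shifts$band[i], bands$name)
      sel <- bin_lab == states[1]
      values[sel, ch, bd] <- values[sel, ch, bd] + shifts$delta[i]
    }
  }
  tab <- ecogstate:::new_features(values, 10, bands,
                                  rep(NA_character_, nbins),
                                  rep(TRUE, nbins), NULL)
  tab <- attach_labels(tab, labels)
  assignment <- structure(list(
    electrode_roi = roi_of,
    retained_rois = names(rois),
    density = stats::setNames(as.integer(unlist(rois)), names(rois)),
    weight = rep(1, nch)), class = "roi_assignment")
  list(table = tab, assignment = assignment, labels = labels)
}

# Small fused-engine study config used by several tests.
small_study <- function(seed = 1, ...) {
  study_config(n_participants = 1, n_blocks = 20, fs = 250,
               states = c("Talking", "WatchingTV"), persistence = 0.5,
               seed = seed, ...)
}
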