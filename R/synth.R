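#' Default region-of-interest centroids
#'
#' Eight cortical regions covering sensorimotor, parietal, temporal and
#' frontal areas, with representative left-hemisphere coordinates in mm.
#' These are stand-in centroids for geometry-level testing, not an atlas
#' parcellation; supply your own map for real electrode localizations.
#'
#' @return Named list of 3-vectors (mm).
#' @export
default_roi_centroids <- function() {
  list(
    precentral        = c(-38,  -6,  50),
    postcentral       = c(-40, -22,  48),
    inferior_parietal = c(-44, -46,  46),
    supramarginal     = c(-56, -34,  30),
    superior_temporal = c(-56, -22,   6),
    middle_temporal   = c(-58, -34,  -4),
    inferior_temporal = c(-52, -46, -16),
    frontal_middle    = c(-36,  32,  34)
  )
}

#' Generate an electrode layout clustered around ROI centroids
#'
#' Places `n_per_roi` electrodes around each centroid with isotropic Gaussian
#' jitter, recording the generating ROI of each electrode as ground truth.
#'
#' @param n_per_roi Electrodes per centroid (>= 1).
#' @param roi_centroids Named list of 3-D centroids (mm); see
#'   [default_roi_centroids()].
#' @param jitter_sd Per-axis Gaussian jitter SD in mm (>= 0).
#' @param seed Integer seed; identical seeds give identical layouts.
#' @return An `electrode_layout`: list with `ids`, `positions` (n x 3 mm),
#'   `roi` (generating ROI per electrode) and `centroids`.
#' @export
make_layout <- function(n_per_roi, roi_centroids = default_roi_centroids(),
                        jitter_sd = 2, seed = 1) {
  if (length(roi_centroids) < 1L) stop_config("at least one ROI centroid required")
  if (n_per_roi < 1L) stop_config("n_per_roi must be >= 1")
  if (jitter_sd < 0) stop_config("jitter_sd must be >= 0")
  rois <- names(roi_centroids)
  if (is.null(rois) || any(!nzchar(rois))) stop_config("roi_centroids must be named")
  with_seed(seed, {
    pos <- do.call(rbind, lapply(rois, function(r) {
      ctr <- roi_centroids[[r]]
      matrix(rep(ctr, each = n_per_roi), ncol = 3) +
        matrix(rnorm(3 * n_per_roi, sd = jitter_sd), ncol = 3)
    }))
    roi_of <- rep(rois, each = n_per_roi)
    ids <- paste0(roi_of, "_", sequence(rep(n_per_roi, length(rois))))
    structure(list(ids = ids, positions = pos, roi = roi_of,
                   centroids = roi_centroids),
              class = "electrode_layout")
  })
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes, %d ROI centroids\n",
              length(x$ids), length(x$centroids)))
  invisible(x)
}

#' Generate behavioral block labels from a Markov chain
#'
#' Emulates coarse manual annotation of consecutive 2-min video blocks. The
#' chain has self-transition probability `persistence` and uniform
#' off-diagonal transitions; the start state is uniform.
#'
#' @param n_blocks Number of blocks.
#' @param states Character vector of state labels (e.g. `"Talking"`).
#' @param persistence Self-transition probability in \[0, 1\].
#' @param seed Integer seed.
#' @param block_s Block duration in seconds (default 120).
#' @return A `behavior_labels` object: list with `labels`, `block_s`, `states`.
#' @export
make_labels <- function(n_blocks, states, persistence = 0.6, seed = 1,
                        block_s = 120) {
  if (length(states) < 1L) stop_config("state set must be non-empty")
  if (n_blocks < 1L) stop_config("n_blocks must be >= 1")
  if (persistence < 0 || persistence > 1) stop_config("persistence must be in [0, 1]")
  if (block_s <= 0) stop_config("block_s must be > 0")
  k <- length(states)
  labs <- with_seed(seed, {
    out <- character(n_blocks)
    out[1] <- sample(states, 1L)
    if (n_blocks > 1L) {
      for (i in 2:n_blocks) {
        if (k == 1L || runif(1) < persistence) {
          out[i] <- out[i - 1]
        } else {
          out[i] <- sample(setdiff(states, out[i - 1]), 1L)
        }
      }
    }
    out
  })
  structure(list(labels = labs, block_s = block_s, states = states),
            class = "behavior_labels")
}

#' @export
print.behavior_labels <- function(x, ...) {
  cat(sprintf("<behavior_labels> %d blocks x %g s; states: %s\n",
              length(x$labels), x$block_s, paste(x$states, collapse = ", ")))
  print(table(factor(x$labels, levels = x$states)))
  invisible(x)
}

#' Declare planted spectro-spatial effects
#'
#' Ground-truth envelope-mean multipliers for the generator: during blocks of
#' `state`, the carrier of `band` in channels of `roi` is scaled by
#' `multiplier` (> 0; 1 means no effect).
#'
#' @param roi,band,state Character vectors (recycled to common length).
#' @param multiplier Positive numeric multipliers.
#' @return An `effect_map` data.frame.
#' @export
effect_map <- function(roi = character(), band = character(),
                       state = character(), multiplier = numeric()) {
  df <- data.frame(roi = roi, band = band, state = state,
                   multiplier = multiplier, stringsAsFactors = FALSE)
  if (nrow(df) && any(df$multiplier <= 0)) stop_config("multipliers must be > 0")
  class(df) <- c("effect_map", "data.frame")
  df
}

#' Noise model for synthetic recordings
#'
#' @param pink_exponent Spectral slope of the 1/f background (power ~
#'   f^-exponent).
#' @param noise_sd Broadband noise SD in microvolts.
#' @param drift_amplitude Amplitude of the slow sinusoidal drift (microvolts);
#'   exercises z-scoring and the temporal CV buffer.
#' @param drift_period Drift period in seconds.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(pink_exponent = 1, noise_sd = 20,
                       drift_amplitude = 25, drift_period = 900) {
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (drift_period <= 0) stop_config("drift_period must be > 0")
  structure(list(pink_exponent = pink_exponent, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, drift_period = drift_period),
            class = "noise_spec")
}

# Spectral weights for a pink-noise block and the matching scale factor
# that yields expected time-domain SD = sd.
pink_weights <- function(L, fs, alpha, sd) {
  half <- L %/% 2L
  f <- (1:half) * fs / L
  w <- f^(-alpha / 2)
  evar <- (2 * sum(2 * w[1:(half - 1L)]^2) + w[half]^2) / L^2
  list(w = w, scale = sd / sqrt(evar), half = half)
}

# Hermitian pink-noise spectrum for one block, from the C++ stream keyed by
# `seed` (bulk normal draws bypass R's RNG for speed; fully deterministic).
pink_spectrum <- function(L, pw, seed) {
  half <- pw$half
  g <- cpp_randn(2L * (half - 1L) + 1L, seed)
  S <- complex(length.out = L)
  S[2:half] <- complex(real = g[seq(1, by = 2, length.out = half - 1L)],
                       imaginary = g[seq(2, by = 2, length.out = half - 1L)]) *
    (pw$w[1:(half - 1L)] * pw$scale)
  S[half + 1L] <- g[2L * (half - 1L) + 1L] * pw$w[half] * pw$scale
  S[L:(L - half + 2L)] <- Conj(S[2:half])
  S
}

# Pink-noise block in the time domain. Power ~ f^-alpha, SD ~ sd.
pink_block <- function(L, fs, alpha, sd, seed) {
  if (sd == 0) return(numeric(L))
  pw <- pink_weights(L, fs, alpha, sd)
  Re(fft(pink_spectrum(L, pw, seed), inverse = TRUE)) / L
}

# Carrier frequencies snapped to the block frequency grid: the geometric
# band center rounded to the nearest multiple of 1/block_s, so every block
# holds an integer number of cycles (phase-coherent blocks, no spectral
# leakage across the block grid). The shift is at most 1/(2 block_s) Hz.
snapped_centers <- function(bands, block_s) {
  f <- band_center(bands$low, bands$high)
  pmax(round(f * block_s), 1) / block_s
}

#' Synthesize a labeled multichannel recording
#'
#' Each channel is a sum of per-band sinusoidal carriers (at the geometric
#' center of each band, snapped to the nearest multiple of `1/block_s` Hz so
#' each block holds an integer number of cycles), pink background noise, and
#' a slow sinusoidal drift:
#' `x(t) = sum_b m(t) a_b sin(2 pi f_b t + phi) + pink(t) + drift(t)`, where
#' the multiplier `m(t)` is the effect-map entry for the channel's ROI, band
#' and the current block's state (1 when unmapped). One random stream per
#' recording is split into per-channel substreams keyed by channel index, so
#' adding channels never reshuffles existing ones.
#'
#' @param layout An [make_layout()] electrode layout.
#' @param labels A [make_labels()] block labeling.
#' @param bands A [default_bands()] table; `fs` must exceed twice the highest
#'   band edge.
#' @param effects An [effect_map()] (possibly empty).
#' @param noise A [noise_spec()].
#' @param fs Sampling rate in Hz (default 500).
#' @param base_amp Carrier amplitude(s) in microvolts, recycled across bands.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An [ecog_recording()].
#' @export
synthesize_recording <- function(layout, labels, bands = default_bands(),
                                 effects = effect_map(), noise = noise_spec(),
                                 fs = 500, base_amp = 1.5, seed = 1) {
  stopifnot(inherits(layout, "electrode_layout"), inherits(labels, "behavior_labels"))
  bands <- default_bands(bands)
  if (fs < 2 * max(bands$high)) {
    stop_config("fs must be at least twice the highest band edge")
  }
  if (nrow(effects)) {
    bad_roi <- setdiff(effects$roi, names(layout$centroids))
    bad_band <- setdiff(effects$band, bands$name)
    if (length(bad_roi)) stop_config("effect references unknown ROI: ", paste(bad_roi, collapse = ", "))
    if (length(bad_band)) stop_config("effect references unknown band: ", paste(bad_band, collapse = ", "))
  }
  nb <- length(labels$labels)
  L <- round(labels$block_s * fs)
  n <- nb * L
  nch <- length(layout$ids)
  amps <- rep_len(base_amp, nrow(bands))
  t <- (seq_len(n) - 1) / fs
  centers <- snapped_centers(bands, labels$block_s)
  sin_b <- lapply(centers, function(f) sin(2 * pi * f * t))
  cos_b <- lapply(centers, function(f) cos(2 * pi * f * t))
  pw <- if (noise$noise_sd > 0) pink_weights(L, fs, noise$pink_exponent, noise$noise_sd) else NULL

  # per-(band) block multipliers by ROI: list[band][[roi]] -> length-nb vector
  mult_for <- function(roi, band) {
    m <- rep(1, nb)
    if (nrow(effects)) {
      sel <- effects$roi == roi & effects$band == band
      if (any(sel)) {
        for (i in which(sel)) {
          m[labels$labels == effects$state[i]] <- effects$multiplier[i]
        }
      }
    }
    m
  }

  X <- matrix(0, nrow = nch, ncol = n)
  for (c in seq_len(nch)) {
    with_seed(child_seed(seed, c), {
      phis <- runif(nrow(bands), 0, 2 * pi)
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        carrier <- cos(phis[b]) * sin_b[[b]] + sin(phis[b]) * cos_b[[b]]
        m <- mult_for(layout$roi[c], bands$name[b])
        if (all(m == 1)) {
          sig <- sig + amps[b] * carrier
        } else {
          sig <- sig + (amps[b] * rep(m, each = L)) * carrier
        }
      }
      if (noise$noise_sd > 0) {
        for (blk in seq_len(nb)) {
          idx <- ((blk - 1L) * L + 1L):(blk * L)
          sig[idx] <- sig[idx] +
            Re(fft(pink_spectrum(L, pw, child_seed(child_seed(seed, c), blk)),
                   inverse = TRUE)) / L
        }
      }
      if (noise$drift_amplitude > 0) {
        psi <- runif(1, 0, 2 * pi)
        sig <- sig + noise$drift_amplitude * sin(2 * pi * t / noise$drift_period + psi)
      }
      X[c, ] <- sig
    })
  }
  ecog_recording(X, fs = fs, positions = layout$positions,
                 meta = list(seed = seed, block_s = labels$block_s,
                             states = labels$states, roi = layout$roi))
}

#' Add high-amplitude square artifact bursts
#'
#' Adds a constant offset of the given amplitude to a seeded random subset of
#' channels over each time window; used to exercise the artifact-rejection
#' rule. The input recording is not modified.
#'
#' @param rec An [ecog_recording()].
#' @param segments List of bursts; each a list/vector with `start_s`,
#'   `duration_s`, `channel_fraction` (0 < f <= 1) and `amplitude_uv`.
#' @param seed Integer seed for channel selection.
#' @return A new [ecog_recording()] with bursts added.
#' @export
inject_artifacts <- function(rec, segments, seed = 1) {
  stopifnot(inherits(rec, "ecog_recording"))
  out <- rec
  if (!length(segments)) return(out)
  nch <- n_channels(rec)
  dur <- duration_s(rec)
  with_seed(seed, {
    for (seg in segments) {
      seg <- as.list(seg)
      names(seg) <- names(seg) %||% c("start_s", "duration_s", "channel_fraction", "amplitude_uv")
      if (seg$start_s < 0 || seg$start_s + seg$duration_s > dur) {
        stop_input("artifact segment outside recording bounds")
      }
      if (seg$channel_fraction <= 0 || seg$channel_fraction > 1) {
        stop_input("channel_fraction must be in (0, 1]")
      }
      k <- ceiling(seg$channel_fraction * nch)
      chans <- sample(nch, k)
      i0 <- floor(seg$start_s * rec$fs) + 1L
      i1 <- min(ncol(rec$data), i0 + round(seg$duration_s * rec$fs) - 1L)
      out$data[chans, i0:i1] <- out$data[chans, i0:i1] + seg$amplitude_uv
    }
  })
  out
}

#' Round-trip an electrode layout or effect map through YAML
#'
#' @param x An `electrode_layout` or `effect_map`.
#' @param path File to write or read.
#' @return `read_layout_yaml` returns an `electrode_layout`;
#'   `read_effects_yaml` an `effect_map`.
#' @export
write_layout_yaml <- function(x, path) {
  stopifnot(inherits(x, "electrode_layout"))
  yaml::write_yaml(list(
    ids = x$ids, roi = x$roi,
    positions = lapply(seq_along(x$ids), function(i) as.numeric(x$positions[i, ])),
    centroids = lapply(x$centroids, as.numeric)
  ), path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(ids = as.character(y$ids),
                 positions = do.call(rbind, lapply(y$positions, as.numeric)),
                 roi = as.character(y$roi),
                 centroids = lapply(y$centroids, as.numeric)),
            class = "electrode_layout")
}

#' @rdname write_layout_yaml
#' @export
write_effects_yaml <- function(x, path) {
  yaml::write_yaml(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])), path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_effects_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) return(effect_map())
  do.call(rbind, lapply(y, function(e) effect_map(e$roi, e$band, e$state, e$multiplier)))
}
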