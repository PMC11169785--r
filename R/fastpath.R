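# Fused frequency-domain execution engine for synthetic studies.
#
# Mathematically the same chain as synthesize_recording() -> preprocess() ->
# extract_features(), exploiting three structural facts of the generator:
# carriers sit on the block frequency grid (single FFT bin per band), pink
# noise is defined by its block spectrum, and zero-phase filtering is a
# squared-magnitude multiplication in the frequency domain. Per block and
# channel pair this costs one inverse FFT (to the time domain, for the
# common-median reference and the artifact rule) and one forward FFT (for
# the band envelopes), instead of time-domain synthesis plus several IIR
# passes. The slow drift term is omitted: the 1 Hz high-pass removes it
# exactly (|H|^2 < 1e-40 at typical drift frequencies).

# Squared-magnitude response of an IIR filter at normalized frequencies
# w = 2*pi*f/fs (zero-phase application).
iir_h2 <- function(coefs, w) {
  ew <- exp(-1i * outer(w, 0:(max(length(coefs$b), length(coefs$a)) - 1)))
  b <- c(coefs$b, numeric(ncol(ew) - length(coefs$b)))
  a <- c(coefs$a, numeric(ncol(ew) - length(coefs$a)))
  Mod((ew %*% b) / (ew %*% a))^2
}

# Full preprocessing response (bandpass + notches) over positive block bins.
preprocess_h2 <- function(cfg, fs, L) {
  half <- L %/% 2L
  w <- 2 * pi * (1:half) * (fs / L) / fs
  H2 <- iir_h2(butter_coefs(4, cfg$bp_low, cfg$bp_high, fs), w)
  nyq <- fs / 2
  for (f0 in cfg$notch_base * seq_len(cfg$notch_harmonics)) {
    if (f0 < 0.98 * nyq) H2 <- H2 * iir_h2(notch_coefs(f0, fs), w)
  }
  as.numeric(H2)
}

# Smallest 5-smooth multiple of `mult` that is >= n (keeps FFT lengths free
# of large prime factors).
smooth_length <- function(n, mult) {
  mult * stats::nextn(ceiling(n / mult), factors = c(2, 3, 5))
}

# Segment keep-mask of the artifact rule on a samples x channels matrix
# (cumulative supra-threshold variant; the hot path of artifact_mask()).
artifact_keep_fast <- function(X, fs, rule) {
  w <- round(rule$segment_s * fs)
  sds <- cpp_col_sd(X)
  usable <- which(sds > 0)
  counts <- cpp_supra_counts(X, as.integer(w),
                             rule$sd_multiplier * sds[usable],
                             as.integer(usable))
  affected <- rowSums(counts / fs > rule$min_duration_s)
  affected / length(usable) < rule$channel_fraction
}

# Simulate, preprocess and featurize one participant entirely in the
# frequency domain. Returns the same ecog_features object as the reference
# chain (up to block-edge filtering differences).
fused_participant_features <- function(cfg, layout, labels, seed) {
  fs <- cfg$fs
  if (fs != cfg$target_fs) {
    stop_config("fused engine requires fs == target_fs; use engine = 'filter'")
  }
  bands <- cfg$bands
  block_s <- cfg$block_s
  L <- round(block_s * fs)
  half <- L %/% 2L
  nblk <- cfg$n_blocks
  nch <- length(layout$ids)
  bpb <- round(block_s / cfg$bin_s)
  amps <- rep_len(cfg$base_amp, nrow(bands))
  kb <- pmax(round(band_center(bands$low, bands$high) * block_s), 1)

  pw <- if (cfg$noise$noise_sd > 0) {
    pink_weights(L, fs, cfg$noise$pink_exponent, cfg$noise$noise_sd)
  } else NULL
  phis <- t(vapply(seq_len(nch), function(c) {
    with_seed(child_seed(seed, c), runif(nrow(bands), 0, 2 * pi))
  }, numeric(nrow(bands))))

  # per-(channel, band) block multipliers
  mult <- function(c, b) {
    m <- rep(1, nblk)
    if (nrow(cfg$effects)) {
      sel <- cfg$effects$roi == layout$roi[c] & cfg$effects$band == bands$name[b]
      for (i in which(sel)) {
        m[labels$labels == cfg$effects$state[i]] <- cfg$effects$multiplier[i]
      }
    }
    m
  }
  A <- array(0, c(nch, nrow(bands), nblk))
  for (c in seq_len(nch)) for (b in seq_len(nrow(bands))) {
    A[c, b, ] <- amps[b] * mult(c, b)
  }

  # preprocessing response over the full circular spectrum (DC -> 0)
  H2p <- preprocess_h2(cfg, fs, L)
  H2full <- numeric(L)
  H2full[2:(half + 1L)] <- H2p
  H2full[L:(L - half + 2L)] <- H2p[1:(half - 1L)]

  # band slices on positive bins; envelopes are reconstructed at a reduced
  # rate Lr/block_s (capped: spectrum folding = exact time subsampling)
  wpos <- 2 * pi * (1:half) * (fs / L) / fs
  slices <- lapply(seq_len(nrow(bands)), function(b) {
    H2 <- as.numeric(iir_h2(butter_coefs(4, bands$low[b], bands$high[b], fs), wpos))
    sup <- which(H2 > 1e-4)
    Lr <- max(2L * bpb, min(smooth_length(length(sup), bpb), 6144L))
    list(sup = sup, H2 = H2[sup], Lr = Lr)
  })
  sup_list <- lapply(slices, function(s) as.integer(s$sup))
  h2_list <- lapply(slices, function(s) s$H2)
  Lrs <- vapply(slices, function(s) as.integer(s$Lr), integer(1))

  pairs <- split(seq_len(nch), ceiling(seq_len(nch) / 2))
  phase <- exp(1i * phis)                       # nch x nbands
  seeds_c <- vapply(seq_len(nch), function(c) child_seed(seed, c), numeric(1))
  Tm <- matrix(0, L * nblk, nch)  # samples x channels (for artifact rule)
  values <- array(NA_real_, c(nblk * bpb, nch, nrow(bands)),
                  dimnames = list(NULL, NULL, bands$name))
  for (blk in seq_len(nblk)) {
    idx1 <- (blk - 1L) * L + 1L
    rows <- ((blk - 1L) * bpb + 1L):(blk * bpb)
    carriers <- t(-1i * (L / 2) * A[, , blk] * phase)  # nbands x nch
    S <- cpp_block_spectra_packed(
      L, if (is.null(pw)) numeric(0) else pw$w,
      if (is.null(pw)) 0 else pw$scale,
      vapply(seeds_c, child_seed, numeric(1), stream = blk),
      H2full, as.integer(kb), carriers)
    idx <- idx1:(idx1 + L - 1L)
    for (p in seq_along(pairs)) {
      pr <- pairs[[p]]
      z <- fft(S[, p], inverse = TRUE) / L
      Tm[idx, pr[1]] <- Re(z)
      if (length(pr) == 2L) Tm[idx, pr[2]] <- Im(z)
    }
    # common-median reference in the time domain; the CMR'd spectrum is the
    # filtered spectrum minus the median signal's spectrum
    med <- cpp_cmr_range(Tm, idx1, L, as.integer(seq_len(nch)))
    Mf <- fft(med)
    for (p in seq_along(pairs)) {
      pr <- pairs[[p]]
      two <- length(pr) == 2L
      W <- S[, p] - (if (two) (1 + 1i) else 1) * Mf
      Sbs <- cpp_unpack_slices(W, sup_list, h2_list, Lrs, two)
      for (b in seq_len(nrow(bands))) {
        Z <- mvfft(Sbs[[b]], inverse = TRUE)
        em <- cpp_env_bin_means(Z, as.integer(bpb), 2 / L)
        values[rows, pr[1], b] <- em[, 1]
        if (two) values[rows, pr[2], b] <- em[, 2]
      }
    }
  }

  keep <- rep(TRUE, nblk * bpb)
  if (!is.null(cfg$rule)) {
    seg_keep <- if (cfg$rule$contiguous) {
      artifact_mask(ecog_recording(t(Tm), fs = fs), cfg$rule)
    } else {
      artifact_keep_fast(Tm, fs, cfg$rule)
    }
    bps <- round(cfg$rule$segment_s / cfg$bin_s)
    for (s in which(!seg_keep)) {
      lo <- (s - 1L) * bps + 1L
      hi <- min(length(keep), s * bps)
      if (lo <= length(keep)) keep[lo:hi] <- FALSE
    }
  }
  tab <- new_features(values, cfg$bin_s, bands, rep(NA_character_, nblk * bpb),
                      keep, layout$positions,
                      meta = list(seed = seed, engine = "fused"))
  attach_labels(tab, labels)
}
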