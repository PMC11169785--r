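#' Configuration for a full synthetic decoding study
#'
#' Bundles every stage's parameters and validates them against each other
#' before any computation. Defaults describe the reference study design:
#' five participants, 60 annotated 2-min blocks each, eight ROIs with three
#' electrodes per ROI, five canonical bands, 7-fold buffered
#' cross-validation, FDR at 0.01.
#'
#' @param n_participants Number of synthetic participants.
#' @param n_blocks Annotated 2-min blocks per participant.
#' @param block_s Block duration (s).
#' @param states Generated state labels (Markov chain over these).
#' @param class_pair The two states entering the main two-class analysis.
#' @param persistence Markov self-transition probability.
#' @param fs Synthesis sampling rate (Hz).
#' @param bands Band table.
#' @param base_amp Carrier amplitude(s), microvolts.
#' @param noise A [noise_spec()].
#' @param effects Planted [effect_map()].
#' @param n_per_roi,jitter_sd,roi_centroids Electrode layout parameters.
#' @param sigma_mm,roi_threshold,min_density ROI projection parameters.
#' @param bp_low,bp_high,notch_base,notch_harmonics,target_fs Preprocessing
#'   parameters (`bp_high`/`target_fs` default to values consistent with
#'   `fs`).
#' @param bin_s Feature bin duration (s).
#' @param rule An [artifact_rule()] or `NULL`.
#' @param n_folds,buffer_folds Cross-validation scheme.
#' @param conf_alpha Chance-level confidence (default 0.05).
#' @param fdr_alpha FDR level (default 0.01).
#' @param engine Execution engine: `"fused"` (default; the frequency-domain
#'   fast path for synthetic studies), `"spectral"` (explicit recording, then
#'   per-block spectral features) or `"filter"` (the reference time-domain
#'   chain).
#' @param multiclass States for the optional multiclass analysis, or `NULL`
#'   to skip.
#' @param additivity_band Band for the optional incremental-ROI analysis, or
#'   `NULL` to skip.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_participants = 5, n_blocks = 60, block_s = 120,
                         states = c("Talking", "WatchingTV", "UsingElectronics"),
                         class_pair = c("Talking", "WatchingTV"),
                         persistence = 0.6,
                         fs = 500, bands = default_bands(), base_amp = 1.5,
                         noise = noise_spec(), effects = effect_map(),
                         n_per_roi = 3, jitter_sd = 2,
                         roi_centroids = default_roi_centroids(),
                         sigma_mm = 10, roi_threshold = exp(-2), min_density = 3,
                         bp_low = 1, bp_high = NULL, notch_base = 60,
                         notch_harmonics = 3, target_fs = NULL,
                         bin_s = 10, rule = artifact_rule(),
                         n_folds = 7, buffer_folds = 1,
                         conf_alpha = 0.05, fdr_alpha = 0.01,
                         engine = "fused",
                         multiclass = NULL, additivity_band = NULL,
                         seed = 1) {
  bands <- default_bands(bands)
  if (is.null(target_fs)) target_fs <- min(fs, 500)
  if (is.null(bp_high)) bp_high <- min(200, 0.46 * target_fs)
  if (fs < 2 * max(bands$high)) stop_config("fs too low for the band table")
  if (bp_high >= target_fs / 2) stop_config("bp_high must be below the target Nyquist")
  if (abs(block_s / bin_s - round(block_s / bin_s)) > 1e-9) {
    stop_config("block_s must be a multiple of bin_s")
  }
  if (!all(class_pair %in% states)) stop_config("class_pair must be generated states")
  if (!is.null(multiclass) && !all(multiclass %in% states)) {
    stop_config("multiclass states must be generated states")
  }
  n_bins <- n_blocks * block_s / bin_s
  if (n_bins < 2 * n_folds) stop_config("too few bins for the fold scheme")
  cfg <- list(n_participants = n_participants, n_blocks = n_blocks,
              block_s = block_s, states = states, class_pair = class_pair,
              persistence = persistence, fs = fs, bands = bands,
              base_amp = base_amp, noise = noise, effects = effects,
              n_per_roi = n_per_roi, jitter_sd = jitter_sd,
              roi_centroids = roi_centroids, sigma_mm = sigma_mm,
              roi_threshold = roi_threshold, min_density = min_density,
              bp_low = bp_low, bp_high = bp_high, notch_base = notch_base,
              notch_harmonics = notch_harmonics, target_fs = target_fs,
              bin_s = bin_s, rule = rule, n_folds = n_folds,
              buffer_folds = buffer_folds, conf_alpha = conf_alpha,
              fdr_alpha = fdr_alpha, engine = engine,
              multiclass = multiclass, additivity_band = additivity_band,
              seed = seed)
  class(cfg) <- "study_config"
  cfg
}

#' Simulate, preprocess and featurize one synthetic participant
#'
#' Generates the layout, block labels and recording for participant `i` of a
#' [study_config()], runs the preprocessing and feature chain with the
#' configured engine, and maps electrodes to ROIs.
#'
#' @param cfg A [study_config()].
#' @param i Participant index (drives all derived seeds).
#' @return List with `layout`, `labels`, `features` (an `ecog_features`) and
#'   `assignment` (a `roi_assignment`).
#' @export
simulate_participant <- function(cfg, i) {
  layout <- make_layout(cfg$n_per_roi, cfg$roi_centroids, cfg$jitter_sd,
                        seed = child_seed(cfg$seed, 1000 + i))
  labels <- make_labels(cfg$n_blocks, cfg$states, cfg$persistence,
                        seed = child_seed(cfg$seed, 2000 + i),
                        block_s = cfg$block_s)
  rec_seed <- child_seed(cfg$seed, 3000 + i)
  if (cfg$engine == "fused") {
    feats <- fused_participant_features(cfg, layout, labels, rec_seed)
  } else {
    rec <- synthesize_recording(layout, labels, cfg$bands, cfg$effects,
                                cfg$noise, fs = cfg$fs,
                                base_amp = cfg$base_amp, seed = rec_seed)
    pcfg <- preprocess_config(bp_low = cfg$bp_low, bp_high = cfg$bp_high,
                              notch_base = cfg$notch_base,
                              notch_harmonics = cfg$notch_harmonics,
                              target_fs = cfg$target_fs)
    rec <- preprocess(rec, pcfg)
    feats <- extract_features(rec, cfg$bands, cfg$bin_s, cfg$rule, labels,
                              engine = cfg$engine)
  }
  proj <- projection_matrix(layout, cfg$sigma_mm)
  assignment <- assign_rois(proj, cfg$roi_threshold, cfg$min_density)
  list(layout = layout, labels = labels, features = feats,
       assignment = assignment)
}

#' Run the full decoding pipeline on synthetic participants
#'
#' Simulate -> preprocess -> featurize -> map to ROIs -> cross-validated
#' LDA per (ROI, band) -> pooled group statistics; optionally the
#' multiclass and incremental-ROI analyses. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [study_config()].
#' @param verbose Print stage-boundary progress.
#' @return A `decoding_bundle`: list with `fold_results` (long per-fold
#'   data.frame), `feature_results` (per ROI x band with p-values and
#'   significance flags), `chance`, `anova`, `participant_acc` and
#'   `participant_md` matrices, `sign_consistent` (fraction of features
#'   whose mean difference keeps one sign across participants),
#'   `multiclass`, `additivity`, `config`, `provenance`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  folds <- fold_spec(cfg$n_folds, cfg$buffer_folds)
  fold_rows <- list(); mc_rows <- list(); add_rows <- list()
  for (i in seq_len(cfg$n_participants)) {
    part <- simulate_participant(cfg, i)
    say("participant %d: %d/%d bins kept, %d ROIs retained", i,
        sum(part$features$keep), length(part$features$keep),
        length(part$assignment$retained_rois))
    ev_seed <- child_seed(cfg$seed, 4000 + i)
    for (roi in part$assignment$retained_rois) {
      for (band in cfg$bands$name) {
        ev <- evaluate_feature(part$features, part$assignment, roi, band,
                               folds, cfg$class_pair, seed = ev_seed)
        md_el <- attr(ev, "mean_diff_by_electrode")
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          participant = i, roi = roi, band = band, fold = ev$fold,
          accuracy = ev$accuracy, n_test = ev$n_test, mean_diff = ev$mean_diff)
      }
    }
    if (!is.null(cfg$multiclass)) {
      mc <- evaluate_multiclass(part$features, part$assignment,
                                cfg$multiclass, folds,
                                seed = child_seed(cfg$seed, 5000 + i))
      mc$participant <- i
      mc_rows[[length(mc_rows) + 1L]] <- mc
    }
    if (!is.null(cfg$additivity_band)) {
      ac <- incremental_roi_curve(part$features, part$assignment,
                                  cfg$additivity_band, folds, cfg$class_pair,
                                  seed = child_seed(cfg$seed, 6000 + i))
      ac$participant <- i
      add_rows[[length(add_rows) + 1L]] <- ac
    }
  }
  fold_df <- do.call(rbind, fold_rows)
  say("pooling %d fold-level records", nrow(fold_df))

  chance <- finite_chance_level(round(median(fold_df$n_test)),
                                n_classes = 2, conf_alpha = cfg$conf_alpha)
  combos <- unique(fold_df[, c("roi", "band")])
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(j) {
    sel <- fold_df$roi == combos$roi[j] & fold_df$band == combos$band[j]
    acc <- fold_df$accuracy[sel]; md <- fold_df$mean_diff[sel]
    data.frame(roi = combos$roi[j], band = combos$band[j],
               n_points = sum(sel), mean_acc = mean(acc),
               ci95_lo = mean(acc) - 1.96 * sd(acc) / sqrt(length(acc)),
               ci95_hi = mean(acc) + 1.96 * sd(acc) / sqrt(length(acc)),
               p_acc = as.numeric(ttest_accuracy(acc, chance)),
               mean_diff = mean(md),
               p_diff = as.numeric(ttest_meandiff(md)))
  }))
  res <- joint_significance(res, chance, cfg$fdr_alpha)
  anova <- tryCatch(anova_roi_band(fold_df), ecog_input_error = function(e) NULL)

  part_mat <- function(col) {
    agg <- stats::aggregate(fold_df[[col]],
                            by = fold_df[c("participant", "roi", "band")], mean)
    key <- paste(agg$roi, agg$band, sep = ":")
    out <- matrix(NA_real_, cfg$n_participants, nrow(combos),
                  dimnames = list(paste0("P", seq_len(cfg$n_participants)),
                                  paste(combos$roi, combos$band, sep = ":")))
    out[cbind(agg$participant, match(key, colnames(out)))] <- agg$x
    out
  }
  pacc <- part_mat("accuracy")
  pmd <- part_mat("mean_diff")
  sgn <- apply(pmd, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && (all(v > 0) || all(v < 0))
  })

  bundle <- list(
    fold_results = fold_df, feature_results = res, chance = chance,
    anova = anova, participant_acc = pacc, participant_md = pmd,
    sign_consistent = mean(sgn),
    multiclass = if (length(mc_rows)) do.call(rbind, mc_rows) else NULL,
    additivity = if (length(add_rows)) do.call(rbind, add_rows) else NULL,
    config = cfg,
    provenance = list(seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("ecogstate")),
                      timestamp = NA)
  )
  class(bundle) <- "decoding_bundle"
  bundle
}

#' @export
print.decoding_bundle <- function(x, ...) {
  cat(sprintf("<decoding_bundle> %d features, %d fold records, chance = %.3f\n",
              nrow(x$feature_results), nrow(x$fold_results), x$chance))
  cat(sprintf("  jointly significant features: %d/%d; sign-consistent: %.1f%%\n",
              sum(x$feature_results$sig_joint), nrow(x$feature_results),
              100 * x$sign_consistent))
  invisible(x)
}

#' @export
summary.decoding_bundle <- function(object, ...) {
  print(object)
  print(object$anova)
  top <- object$feature_results[order(-object$feature_results$mean_acc), ]
  cat("Top features by mean accuracy:\n")
  print(utils::head(top[, c("roi", "band", "mean_acc", "p_acc", "mean_diff",
                            "p_diff", "sig_joint")], 5), row.names = FALSE)
  invisible(object)
}

#' Export a result bundle to disk
#'
#' Writes the tidy CSVs (fold records, feature table, participant matrices,
#' multiclass, additivity), the ANOVA as JSON, a YAML config snapshot and a
#' log, and returns a manifest with md5 checksums.
#'
#' @param bundle A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
export_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(obj, name) {
    f <- file.path(outdir, name)
    data.table::fwrite(as.data.frame(obj), f)
    written <<- c(written, f)
  }
  if (!is.null(bundle$fold_results)) put(bundle$fold_results, "folds.csv")
  if (!is.null(bundle$feature_results)) put(bundle$feature_results, "features.csv")
  if (!is.null(bundle$participant_acc)) {
    put(cbind(participant = rownames(bundle$participant_acc),
              as.data.frame(bundle$participant_acc)), "participant_accuracy.csv")
    put(cbind(participant = rownames(bundle$participant_md),
              as.data.frame(bundle$participant_md)), "participant_meandiff.csv")
  }
  if (!is.null(bundle$multiclass)) put(bundle$multiclass, "multiclass.csv")
  if (!is.null(bundle$additivity)) put(bundle$additivity, "additivity.csv")
  if (!is.null(bundle$anova)) {
    f <- file.path(outdir, "anova.json")
    jsonlite::write_json(unclass(bundle$anova), f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
  }
  cfgf <- file.path(outdir, "config.yaml")
  cfg <- bundle$config
  yaml::write_yaml(list(seed = cfg$seed, n_participants = cfg$n_participants,
                        n_blocks = cfg$n_blocks, fs = cfg$fs,
                        engine = cfg$engine, n_folds = cfg$n_folds,
                        buffer_folds = cfg$buffer_folds,
                        fdr_alpha = cfg$fdr_alpha,
                        chance = bundle$chance), cfgf)
  written <- c(written, cfgf)
  logf <- file.path(outdir, "log.txt")
  writeLines(c(sprintf("seed: %s", cfg$seed),
               sprintf("features: %d", nrow(bundle$feature_results %||% data.frame())),
               sprintf("fold records: %d", nrow(bundle$fold_results %||% data.frame()))),
             logf)
  written <- c(written, logf)
  manifest <- data.frame(file = basename(written),
                         md5 = as.character(tools::md5sum(written)),
                         row.names = NULL)
  data.table::fwrite(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}

#' Plot a decoding bundle
#'
#' `which = "accuracy"`: per-feature mean accuracy with 95% CI and the
#' finite chance line. `which = "meandiff"`: per-feature class-mean
#' differences. `which = "additivity"`: incremental-ROI curves.
#'
#' @param x A `decoding_bundle`.
#' @param which One of `"accuracy"`, `"meandiff"`, `"additivity"`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.decoding_bundle <- function(x, which = "accuracy", ...) {
  res <- x$feature_results
  if (which == "accuracy") {
    ord <- order(res$roi, res$band)
    res <- res[ord, ]
    mids <- graphics::barplot(res$mean_acc, las = 2, cex.names = 0.5,
                              names.arg = paste(res$roi, res$band, sep = ":"),
                              ylab = "accuracy", ylim = c(0, 1),
                              col = ifelse(res$sig_joint, "firebrick", "grey70"))
    graphics::segments(mids, res$ci95_lo, mids, res$ci95_hi)
    graphics::abline(h = x$chance, lty = 2)
  } else if (which == "meandiff") {
    ord <- order(res$roi, res$band)
    res <- res[ord, ]
    graphics::barplot(res$mean_diff, las = 2, cex.names = 0.5,
                      names.arg = paste(res$roi, res$band, sep = ":"),
                      ylab = "mean difference (z units)",
                      col = ifelse(res$sig_joint, "firebrick", "grey70"))
    graphics::abline(h = 0)
  } else if (which == "additivity" && !is.null(x$additivity)) {
    ad <- x$additivity
    graphics::plot(range(ad$size), range(ad$test_accuracy), type = "n",
                   xlab = "number of ROIs", ylab = "test accuracy")
    for (p in unique(ad$participant)) {
      sub <- ad[ad$participant == p, ]
      graphics::lines(sub$size, sub$test_accuracy, type = "b", col = p)
    }
  }
  invisible(x)
}
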