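#' Temporally ordered cross-validation folds with a buffer
#'
#' Bins are split into `n_folds` contiguous blocks in temporal order (sizes
#' differing by at most one). For test fold k the training set is every fold
#' whose index differs from k by more than `buffer_folds` — the buffer
#' applies on both temporal sides, with no wraparound — so at least one full
#' fold separates any training bin from any test bin.
#'
#' @param n_bins Number of (kept) bins.
#' @param n_folds Number of folds (default 7).
#' @param buffer_folds Buffer width in folds (default 1; 0 gives standard
#'   contiguous k-fold).
#' @return A `fold_scheme`: list with `n_folds`, `buffer_folds`,
#'   `fold_of_bin`, `folds` (bin indices per fold) and `train_folds` (per
#'   test fold).
#' @export
make_folds <- function(n_bins, n_folds = 7, buffer_folds = 1) {
  if (n_bins < 2 * n_folds) stop_input("too few bins for ", n_folds, " folds")
  sizes <- rep(n_bins %/% n_folds, n_folds)
  extra <- n_bins %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of_bin <- rep(seq_len(n_folds), times = sizes)
  folds <- split(seq_len(n_bins), fold_of_bin)
  train_folds <- lapply(seq_len(n_folds), function(k) {
    which(abs(seq_len(n_folds) - k) > buffer_folds)
  })
  structure(list(n_folds = n_folds, buffer_folds = buffer_folds,
                 fold_of_bin = fold_of_bin, folds = folds,
                 train_folds = train_folds),
            class = "fold_scheme")
}

#' Lightweight fold-scheme specification
#'
#' Records the fold count and buffer width; materialized by [make_folds()]
#' once the number of kept bins is known.
#'
#' @param n_folds,buffer_folds See [make_folds()].
#' @return A `fold_spec` list.
#' @export
fold_spec <- function(n_folds = 7, buffer_folds = 1) {
  structure(list(n_folds = n_folds, buffer_folds = buffer_folds),
            class = "fold_spec")
}

resolve_folds <- function(scheme, n_bins) {
  if (inherits(scheme, "fold_scheme")) return(scheme)
  make_folds(n_bins, scheme$n_folds, scheme$buffer_folds)
}

#' Balance classes by seeded downsampling
#'
#' Subsamples each class (uniformly, without replacement) to the minimum
#' class count. Deterministic for a given seed.
#'
#' @param bin_indices Candidate bin indices.
#' @param labels Label per bin (full vector, indexed by `bin_indices`).
#' @param classes Classes to balance (default: those present).
#' @param seed Integer seed.
#' @return Sorted subset of `bin_indices` with equal class counts.
#' @export
balance_classes <- function(bin_indices, labels, classes = NULL, seed = 1) {
  lab <- labels[bin_indices]
  if (is.null(classes)) classes <- sort(unique(lab))
  counts <- table(factor(lab, levels = classes))
  if (any(counts == 0)) {
    stop_input("cannot balance: class absent: ",
               paste(names(counts)[counts == 0], collapse = ", "))
  }
  m <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(classes, function(cl) {
      idx <- bin_indices[lab == cl]
      if (length(idx) == m) idx else sample(idx, m)
    }))
    sort(keep)
  })
}

#' Z-score training and test sets independently
#'
#' Each set is standardized with its own per-feature mean and sample SD
#' (n - 1 convention). Constant features are set to zero with a warning.
#'
#' @param train,test Numeric matrices with matching columns and >= 2 rows
#'   each.
#' @return List with standardized `train` and `test`.
#' @export
zscore_split <- function(train, test) {
  zs <- function(M, which) {
    M <- as.matrix(M)
    if (nrow(M) < 2L) stop_input(which, " set needs >= 2 rows")
    mu <- colMeans(M)
    s <- apply(M, 2, sd)
    bad <- s == 0 | !is.finite(s)
    if (any(bad)) {
      warning("constant feature(s) in ", which, " set; z-scores set to 0")
      s[bad] <- 1
    }
    Z <- sweep(sweep(M, 2, mu), 2, s, "/")
    Z[, bad] <- 0
    Z
  }
  list(train = zs(train, "train"), test = zs(test, "test"))
}

# One fold of the standard protocol: balance train and test independently,
# z-score independently, fit shared-covariance LDA, score the test bins.
fold_eval <- function(M, lab, train_idx, test_idx, classes, seed, lambda = 1e-3) {
  have <- function(idx) all(classes %in% lab[idx])
  if (!length(test_idx) || !have(test_idx) || !have(train_idx)) return(NULL)
  tr <- balance_classes(train_idx, lab, classes, seed = child_seed(seed, 1))
  te <- balance_classes(test_idx, lab, classes, seed = child_seed(seed, 2))
  z <- zscore_split(M[tr, , drop = FALSE], M[te, , drop = FALSE])
  fit <- fit_lda_shared(z$train, lab[tr], classes = classes, lambda = lambda)
  pred <- predict(fit, z$test)
  list(accuracy = mean(pred == lab[te]), n_test = length(te), fit = fit)
}

#' Cross-validated decoding of one (ROI, band) feature
#'
#' Runs the buffered cross-validation protocol on the electrodes of one ROI
#' and one frequency band: per fold, class-balance the training and test
#' bins separately, z-score the two sets independently, fit a
#' shared-covariance LDA, and score the held-out bins. The per-fold class
#' mean difference (first class of `class_pair` minus the second, in z
#' units) is the consistency statistic; its electrode average is the scalar
#' summary.
#'
#' @param table A labeled `ecog_features` object.
#' @param assignment An [assign_rois()] result.
#' @param roi,band Retained ROI and band name.
#' @param scheme A [fold_spec()] or [make_folds()] scheme.
#' @param class_pair Length-2 character vector; the sign convention is
#'   `class_pair[1]` minus `class_pair[2]`.
#' @param seed Integer seed (drives balancing only).
#' @param lambda Ridge fraction for the LDA covariance.
#' @return A `feature_eval` data.frame with columns `fold`, `accuracy`,
#'   `n_test`, `mean_diff`, plus attribute `mean_diff_by_electrode`
#'   (folds x electrodes).
#' @export
evaluate_feature <- function(table, assignment, roi, band,
                             scheme = fold_spec(),
                             class_pair = c("Talking", "WatchingTV"),
                             seed = 1, lambda = 1e-3) {
  stopifnot(length(class_pair) == 2L)
  M <- roi_feature_slice(table, assignment, roi, band)
  lab_all <- table$labels[attr(M, "bins")]
  sel <- which(lab_all %in% class_pair)
  M <- M[sel, , drop = FALSE]
  lab <- lab_all[sel]
  if (!all(class_pair %in% lab)) {
    stop_input("both classes must be present for ", roi, "/", band)
  }
  sch <- resolve_folds(scheme, nrow(M))
  rows <- list()
  md_mat <- NULL
  for (k in seq_len(sch$n_folds)) {
    test_idx <- sch$folds[[k]]
    train_idx <- unlist(sch$folds[sch$train_folds[[k]]], use.names = FALSE)
    res <- fold_eval(M, lab, train_idx, test_idx, class_pair,
                     seed = child_seed(seed, k), lambda = lambda)
    if (is.null(res)) {
      message("fold ", k, " skipped for ", roi, "/", band, " (class missing)")
      next
    }
    md <- res$fit$means[class_pair[1], ] - res$fit$means[class_pair[2], ]
    rows[[length(rows) + 1L]] <- data.frame(
      fold = k, accuracy = res$accuracy, n_test = res$n_test,
      mean_diff = mean(md))
    md_mat <- rbind(md_mat, md)
  }
  out <- do.call(rbind, rows)
  rownames(md_mat) <- NULL
  attr(out, "mean_diff_by_electrode") <- md_mat
  attr(out, "roi") <- roi
  attr(out, "band") <- band
  class(out) <- c("feature_eval", "data.frame")
  out
}

all_assigned_electrodes <- function(assignment) {
  which(!is.na(assignment$electrode_roi))
}

band_matrix <- function(table, band, electrodes) {
  bi <- match(band, table$bands$name)
  if (is.na(bi)) stop_input("unknown band: ", band)
  bins <- which(table$keep)
  M <- table$values[bins, electrodes, bi, drop = FALSE]
  dim(M) <- c(length(bins), length(electrodes))
  attr(M, "bins") <- bins
  M
}

#' Multiclass decoding per frequency band using all assigned electrodes
#'
#' Extends the two-class protocol to three (or more) states: per band, the
#' features are all electrodes assigned to any retained ROI; balancing
#' downsamples every class to the minimum count.
#'
#' @param table A labeled `ecog_features` object.
#' @param assignment An [assign_rois()] result.
#' @param classes Character vector of state labels (>= 2).
#' @param scheme A [fold_spec()] or fold scheme.
#' @param bands Band names (default: all in the table).
#' @param seed,lambda As in [evaluate_feature()].
#' @return data.frame with columns `band`, `fold`, `accuracy`, `n_test`.
#' @export
evaluate_multiclass <- function(table, assignment, classes,
                                scheme = fold_spec(), bands = NULL,
                                seed = 1, lambda = 1e-3) {
  if (length(classes) < 2L) stop_input("need >= 2 classes")
  if (is.null(bands)) bands <- table$bands$name
  el <- all_assigned_electrodes(assignment)
  if (!length(el)) stop_input("no assigned electrodes")
  out <- list()
  for (band in bands) {
    M <- band_matrix(table, band, el)
    lab_all <- table$labels[attr(M, "bins")]
    sel <- which(lab_all %in% classes)
    Mb <- M[sel, , drop = FALSE]
    lab <- lab_all[sel]
    missing <- setdiff(classes, unique(lab))
    if (length(missing)) stop_input("class with zero bins: ", paste(missing, collapse = ", "))
    sch <- resolve_folds(scheme, nrow(Mb))
    for (k in seq_len(sch$n_folds)) {
      res <- fold_eval(Mb, lab, unlist(sch$folds[sch$train_folds[[k]]], use.names = FALSE),
                       sch$folds[[k]], classes,
                       seed = child_seed(seed, k), lambda = lambda)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- data.frame(band = band, fold = k,
                                            accuracy = res$accuracy,
                                            n_test = res$n_test)
    }
  }
  do.call(rbind, out)
}

#' Incremental-ROI additivity curve
#'
#' Ranks retained ROIs by accuracy on a validation fold held out inside the
#' training partition (the training fold most distant from the test fold,
#' itself buffered), then reports buffered test accuracy as electrodes from
#' the top-1, top-2, ... ROIs are concatenated into one feature set.
#'
#' @param table A labeled `ecog_features` object.
#' @param assignment An [assign_rois()] result with >= 2 retained ROIs.
#' @param band Band name.
#' @param scheme A [fold_spec()]; needs >= 3 folds to host validation and
#'   test sets.
#' @param class_pair Two state labels.
#' @param seed,lambda As in [evaluate_feature()].
#' @return data.frame with columns `size`, `roi_added`, `test_accuracy`
#'   (mean over folds), plus attribute `roi_ranking` (with validation
#'   accuracies).
#' @export
incremental_roi_curve <- function(table, assignment, band,
                                  scheme = fold_spec(),
                                  class_pair = c("Talking", "WatchingTV"),
                                  seed = 1, lambda = 1e-3) {
  rois <- assignment$retained_rois
  if (length(rois) < 2L) {
    if (length(rois) == 1L) {
      ev <- evaluate_feature(table, assignment, rois, band, scheme,
                             class_pair, seed, lambda)
      return(data.frame(size = 1L, roi_added = rois,
                        test_accuracy = mean(ev$accuracy)))
    }
    stop_input("no retained ROIs")
  }
  nf <- if (inherits(scheme, "fold_scheme")) scheme$n_folds else scheme$n_folds
  if (nf < 3L) stop_config("incremental analysis needs >= 3 folds")
  el_by_roi <- lapply(rois, function(r) which(assignment$electrode_roi == r))
  names(el_by_roi) <- rois
  el_all <- unlist(el_by_roi, use.names = FALSE)
  M <- band_matrix(table, band, el_all)
  col_of <- rep(seq_along(rois), times = lengths(el_by_roi))
  lab_all <- table$labels[attr(M, "bins")]
  sel <- which(lab_all %in% class_pair)
  M <- M[sel, , drop = FALSE]
  lab <- lab_all[sel]
  sch <- resolve_folds(scheme, nrow(M))
  buffer <- sch$buffer_folds

  # validation accuracies: ROI x fold
  val_acc <- matrix(NA_real_, length(rois), sch$n_folds,
                    dimnames = list(rois, NULL))
  for (k in seq_len(sch$n_folds)) {
    tf <- sch$train_folds[[k]]
    v <- tf[which.max(abs(tf - k))]
    inner <- tf[abs(tf - v) > buffer & tf != v]
    if (!length(inner)) next
    val_idx <- sch$folds[[v]]
    inner_idx <- unlist(sch$folds[inner], use.names = FALSE)
    for (r in seq_along(rois)) {
      res <- fold_eval(M[, col_of == r, drop = FALSE], lab, inner_idx, val_idx,
                       class_pair, seed = child_seed(seed, 100 + k), lambda = lambda)
      if (!is.null(res)) val_acc[r, k] <- res$accuracy
    }
  }
  ranking <- order(-rowMeans(val_acc, na.rm = TRUE))
  curve <- data.frame(size = seq_along(rois), roi_added = rois[ranking],
                      test_accuracy = NA_real_)
  for (s in seq_along(rois)) {
    cols <- col_of %in% ranking[seq_len(s)]
    accs <- numeric(0)
    for (k in seq_len(sch$n_folds)) {
      res <- fold_eval(M[, cols, drop = FALSE], lab,
                       unlist(sch$folds[sch$train_folds[[k]]], use.names = FALSE),
                       sch$folds[[k]], class_pair,
                       seed = child_seed(seed, k), lambda = lambda)
      if (!is.null(res)) accs <- c(accs, res$accuracy)
    }
    curve$test_accuracy[s] <- mean(accs)
  }
  attr(curve, "roi_ranking") <- data.frame(roi = rois[ranking],
                                           val_accuracy = rowMeans(val_acc, na.rm = TRUE)[ranking])
  curve
}
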