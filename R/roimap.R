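#' Gaussian electrode-to-ROI projection matrix
#'
#' Entry (i, j) is a 3-D isotropic Gaussian of the distance between electrode
#' i and ROI centroid j: `exp(-||p_i - c_j||^2 / (2 sigma^2))`, so an
#' electrode exactly at a centroid scores 1.
#'
#' @param layout An [make_layout()] electrode layout (or any list with
#'   `positions` and `centroids`).
#' @param sigma_mm Gaussian width in mm (default 10).
#' @return A `roi_projection`: electrodes x ROIs weight matrix with
#'   attributes `sigma_mm`.
#' @export
projection_matrix <- function(layout, sigma_mm = 10) {
  if (sigma_mm <= 0) stop_config("sigma_mm must be > 0")
  if (!length(layout$centroids)) stop_config("no ROI centroids")
  ctr <- do.call(rbind, lapply(layout$centroids, as.numeric))
  pos <- layout$positions
  d2 <- outer(rowSums(pos^2), rowSums(ctr^2), "+") - 2 * pos %*% t(ctr)
  W <- exp(-pmax(d2, 0) / (2 * sigma_mm^2))
  dimnames(W) <- list(layout$ids, names(layout$centroids))
  structure(W, sigma_mm = sigma_mm, class = c("roi_projection", "matrix", "array"))
}

#' Threshold the projection and enforce the density rule
#'
#' Each electrode is assigned to its argmax-weight ROI when that weight
#' reaches `threshold` (ties break to the earlier ROI in column order). ROIs
#' with fewer than `min_density` assigned electrodes are then discarded and
#' the assignment recomputed over the surviving ROIs, iterating to a fixed
#' point.
#'
#' @param proj A [projection_matrix()].
#' @param threshold Minimum weight to count as close (default `exp(-2)`,
#'   about a 2-sigma radius).
#' @param min_density Minimum electrodes per retained ROI (default 3).
#' @return A `roi_assignment`: list with `electrode_roi` (ROI name or `NA`
#'   per electrode), `retained_rois`, `density`, and `weight` (the winning
#'   weight per electrode).
#' @export
assign_rois <- function(proj, threshold = exp(-2), min_density = 3) {
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0, 1)")
  if (min_density < 1) stop_config("min_density must be >= 1")
  rois <- colnames(proj)
  retained <- rois
  assignment <- rep(NA_character_, nrow(proj))
  repeat {
    W <- proj[, retained, drop = FALSE]
    best <- apply(W, 1, which.max)
    wbest <- W[cbind(seq_len(nrow(W)), best)]
    assignment <- ifelse(wbest >= threshold, retained[best], NA_character_)
    density <- table(factor(assignment, levels = retained))
    keep <- names(density)[density >= min_density]
    if (identical(keep, retained) || !length(keep)) {
      retained <- keep
      if (!length(keep)) assignment <- rep(NA_character_, nrow(proj))
      break
    }
    retained <- keep
  }
  if (!length(retained)) warning("no electrodes assigned to any ROI")
  density <- table(factor(assignment, levels = retained))
  structure(list(electrode_roi = assignment,
                 retained_rois = retained,
                 density = stats::setNames(as.integer(density), names(density)),
                 weight = if (length(retained)) {
                   W <- proj[, retained, drop = FALSE]
                   apply(W, 1, max)
                 } else rep(NA_real_, nrow(proj))),
            class = "roi_assignment")
}

#' @export
print.roi_assignment <- function(x, ...) {
  cat(sprintf("<roi_assignment> %d/%d electrodes assigned; %d ROIs retained\n",
              sum(!is.na(x$electrode_roi)), length(x$electrode_roi),
              length(x$retained_rois)))
  if (length(x$density)) print(x$density)
  invisible(x)
}

#' Slice the feature table for one (ROI, band)
#'
#' Returns the kept-bin x electrode matrix of envelope means for the
#' electrodes assigned to `roi`, in layout order.
#'
#' @param table An `ecog_features` object.
#' @param assignment An [assign_rois()] result.
#' @param roi Retained ROI name.
#' @param band Band name present in the table.
#' @return Numeric matrix, kept bins x n assigned electrodes, with the kept
#'   bin indices as attribute `bins`.
#' @export
roi_feature_slice <- function(table, assignment, roi, band) {
  stopifnot(inherits(table, "ecog_features"))
  if (!(roi %in% assignment$retained_rois)) stop_input("ROI not retained: ", roi)
  bi <- match(band, table$bands$name)
  if (is.na(bi)) stop_input("unknown band: ", band)
  cols <- which(assignment$electrode_roi == roi)
  bins <- which(table$keep)
  M <- table$values[bins, cols, bi, drop = FALSE]
  dim(M) <- c(length(bins), length(cols))
  attr(M, "bins") <- bins
  M
}

#' Export an ROI assignment as a data frame / CSV
#'
#' @param assignment An [assign_rois()] result.
#' @param layout The matching electrode layout.
#' @param path Optional CSV path to write.
#' @return data.frame with electrode, x, y, z, roi, weight.
#' @export
assignment_table <- function(assignment, layout, path = NULL) {
  df <- data.frame(electrode = layout$ids,
                   x = layout$positions[, 1], y = layout$positions[, 2],
                   z = layout$positions[, 3],
                   roi = assignment$electrode_roi,
                   weight = assignment$weight)
  if (!is.null(path)) data.table::fwrite(df, path)
  df
}
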