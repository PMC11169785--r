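#' Construct a raw multichannel recording
#'
#' The container used across the pipeline: a channels x samples voltage
#' matrix (microvolts) plus sampling rate, 3-D electrode positions (mm) and a
#' per-channel good mask.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param positions Optional channels x 3 matrix of electrode coordinates (mm).
#' @param good Optional logical vector, one entry per channel; defaults to all
#'   `TRUE`.
#' @param meta Optional named list of provenance (seed, generator settings).
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, fs, positions = NULL, good = NULL, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop_input("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop_input("fs must be a positive scalar")
  nch <- nrow(data)
  if (is.null(good)) good <- rep(TRUE, nch)
  if (length(good) != nch) stop_input("good mask length must equal channel count")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || ncol(positions) != 3L) {
      stop_input("positions must be a channels x 3 matrix")
    }
  }
  structure(list(data = data, fs = fs, positions = positions,
                 good = as.logical(good), meta = meta),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), %d good channels\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, sum(x$good)))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Write / read a recording container
#'
#' Serializes a recording to a directory of plain files: `data.tsv` (samples in
#' rows, channels in columns), `positions.tsv`, and `meta.json` (fs, good mask,
#' provenance). The format is text-based and portable.
#'
#' @param rec An [ecog_recording()].
#' @param path Directory to create or read.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [ecog_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecog_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(t(rec$data)),
                     file.path(path, "data.tsv"), sep = "\t")
  if (!is.null(rec$positions)) {
    data.table::fwrite(data.table::as.data.table(rec$positions),
                       file.path(path, "positions.tsv"), sep = "\t")
  }
  meta <- c(list(fs = rec$fs, good = rec$good), rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  data <- t(as.matrix(data.table::fread(file.path(path, "data.tsv"))))
  dimnames(data) <- NULL
  pos_file <- file.path(path, "positions.tsv")
  positions <- if (file.exists(pos_file)) {
    p <- as.matrix(data.table::fread(pos_file)); dimnames(p) <- NULL; p
  } else NULL
  extra <- meta[setdiff(names(meta), c("fs", "good"))]
  ecog_recording(data, fs = meta$fs, positions = positions,
                 good = as.logical(meta$good), meta = extra)
}
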