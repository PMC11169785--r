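#' Canonical ECoG frequency-band table
#'
#' The five bands used throughout the analysis: theta (4-8 Hz), alpha
#' (8-12 Hz), beta (8-32 Hz), low gamma (32-55 Hz) and high gamma (70-110 Hz).
#' Note the beta band is defined as 8-32 Hz, overlapping alpha; the overlap is
#' intentional and kept as published for this analysis family.
#'
#' @param bands Optional data.frame with columns `name`, `low`, `high` to
#'   validate and use instead of the defaults.
#' @return A `band_table` data.frame with columns `name`, `low`, `high`.
#' @export
#' @examples
#' default_bands()
default_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name = c("theta", "alpha", "beta", "lowgamma", "highgamma"),
      low  = c(4, 8, 8, 32, 70),
      high = c(8, 12, 32, 55, 110),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high)) {
    stop_config("every band must satisfy low < high")
  }
  if (anyDuplicated(bands$name)) stop_config("band names must be unique")
  class(bands) <- c("band_table", "data.frame")
  bands
}

#' Carrier frequency of a band
#'
#' Geometric mean of the band edges; sits well inside the passband of the
#' analysis filter, which matters for narrow log-spaced bands.
#'
#' @param low,high Band edges in Hz.
#' @return Center frequency in Hz.
#' @export
band_center <- function(low, high) sqrt(low * high)
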