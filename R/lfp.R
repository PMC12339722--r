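#' Local field potential trace
#'
#' A light container for one microwire's LFP: a numeric sample vector in
#' microvolts plus its sampling rate and identifiers. All preprocessing
#' functions take and return this class.
#'
#' @param samples Numeric vector, microvolts. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param wire_id Wire label.
#' @param region Anatomical region label.
#' @return An `lfp_trace` object.
#' @export
lfp_trace <- function(samples, fs, wire_id = "w1", region = "unknown") {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  structure(
    list(samples = as.numeric(samples), fs = fs,
         wire_id = wire_id, region = region),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> wire %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$wire_id, x$region, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.lfp_trace <- function(x) length(x$samples)

duration_s <- function(lfp) length(lfp$samples) / lfp$fs
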