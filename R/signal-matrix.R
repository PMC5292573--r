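#' Multichannel signal container
#'
#' Bundles a channels-by-samples numeric matrix with an optional sampling
#' rate and channel labels.  All estimators in the package accept either a
#' `signal_matrix` or a plain numeric matrix with rows as channels.
#'
#' @param data numeric matrix, rows = channels, columns = samples.  A
#'   numeric vector is treated as a single channel.
#' @param fs sampling rate in Hz, or `NULL` when unknown.  Required by the
#'   spectral estimators ([welch_cross_spectra()]) and by
#'   [design_windowed_sinc()].
#' @param labels optional character vector of channel names; defaults to
#'   `ch1, ch2, ...` when omitted.
#'
#' @return An object of class `signal_matrix` with fields `data`, `fs`,
#'   `labels`.
#' @examples
#' x <- signal_matrix(matrix(rnorm(200), nrow = 2), fs = 100)
#' x
#' @export
signal_matrix <- function(data, fs = NULL, labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    fcnet_stop("data must be a numeric matrix (channels x samples)",
               "fcnet_param")
  if (nrow(data) < 1 || ncol(data) < 2)
    fcnet_stop("need at least 1 channel and 2 samples", "fcnet_param")
  if (any(!is.finite(data)))
    fcnet_stop("signal values must all be finite", "fcnet_param")
  if (!is.null(fs)) {
    if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
      fcnet_stop("fs must be a single positive number (Hz)", "fcnet_param")
  }
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data))
    fcnet_stop("labels must have one entry per channel", "fcnet_param")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "signal_matrix")
}

# Coerce matrix-like input into a signal_matrix.
as_signal_matrix <- function(x, fs = NULL) {
  if (inherits(x, "signal_matrix")) return(x)
  signal_matrix(x, fs = fs)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d channel(s) x %d samples", nrow(x$data),
              ncol(x$data)))
  if (!is.null(x$fs)) cat(sprintf(", fs = %g Hz", x$fs))
  cat("\n  channels:", paste(utils::head(x$labels, 8), collapse = ", "))
  if (length(x$labels) > 8) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$data)
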