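# Delimited-text readers and writers.  Rows are channels; TSV or CSV is
# chosen from the file extension unless forced.  All numeric output uses
# 17 significant digits so write/read round-trips are lossless.

detect_delimiter <- function(path, delimiter) {
  switch(delimiter,
         auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
         tab = "\t",
         comma = ",")
}

#' Read a multichannel signal matrix from delimited text
#'
#' Reads a rectangular numeric body with rows as channels.  Ragged rows
#' and non-numeric cells fail fast with the offending coordinates.
#'
#' @param path file path; `.csv` implies comma separation under
#'   `delimiter = "auto"`, anything else tab.
#' @param delimiter `"auto"`, `"tab"` or `"comma"`.
#' @param labels if `TRUE` the first column holds channel labels.
#' @param fs optional sampling rate to attach (Hz).
#' @param transpose if `TRUE` the file is column-major (columns =
#'   channels) and is transposed after reading; label parsing is not
#'   supported in that orientation.
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(path, delimiter = c("auto", "tab", "comma"),
                               labels = FALSE, fs = NULL,
                               transpose = FALSE) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path))
    fcnet_stop(sprintf("file not found: %s", path), "fcnet_format")
  if (transpose && labels)
    fcnet_stop("labels are only supported for rows-as-channels input",
               "fcnet_param")
  sep <- detect_delimiter(path, delimiter)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    fcnet_stop("file is empty", "fcnet_format")
  toks <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1)
    fcnet_stop(sprintf("ragged rows: row %d has %d fields, expected %d",
                       which(widths != widths[1])[1],
                       widths[widths != widths[1]][1], widths[1]),
               "fcnet_format")
  lab <- NULL
  if (labels) {
    lab <- vapply(toks, `[[`, character(1), 1)
    toks <- lapply(toks, `[`, -1)
  }
  num <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    bad <- which(is.na(v) & toks[[i]] != "NA")
    if (length(bad))
      fcnet_stop(sprintf("non-numeric value '%s' at row %d, column %d",
                         toks[[i]][bad[1]], i, bad[1]),
                 "fcnet_parse")
    v
  })
  mat <- do.call(rbind, num)
  if (transpose) mat <- t(mat)
  signal_matrix(mat, fs = fs, labels = lab)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a matrix or metric vector as labelled TSV
#'
#' Square (or rectangular) matrices are written with a header row and a
#' leading label column; vectors as two-column (label, value) TSV; a
#' `signal_matrix` as label-prefixed rows without a header, so it
#' round-trips through [read_signal_matrix()] with `labels = TRUE`.
#' Values carry 17 significant digits, so a write/read round-trip is
#' bit-exact.
#'
#' @param values numeric matrix or vector, or a `signal_matrix`.
#' @param path output file path.
#' @param labels row labels; defaults to existing names or `V1, V2, ...`.
#' @param col_labels column labels for matrices; defaults to `labels`
#'   when dimensions agree.
#' @return Invisibly, `path`.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(values, path, labels = NULL, col_labels = NULL) {
  is_signal <- inherits(values, "signal_matrix")
  if (is_signal) {
    if (is.null(labels)) labels <- values$labels
    values <- values$data
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    fcnet_stop(sprintf("cannot open '%s' for writing", path),
                               "fcnet_io"))
  on.exit(close(con))
  if (is_signal) {
    body <- apply(values, 1, function(r) paste(fmt17(r), collapse = "\t"))
    writeLines(paste(labels, body, sep = "\t"), con)
    return(invisible(path))
  }
  if (is.null(dim(values))) {
    if (is.null(labels)) {
      labels <- names(values)
      if (is.null(labels)) labels <- paste0("V", seq_along(values))
    }
    writeLines(paste(labels, fmt17(values), sep = "\t"), con)
  } else {
    values <- unclass(values)
    if (is.null(labels)) {
      labels <- rownames(values)
      if (is.null(labels)) labels <- paste0("V", seq_len(nrow(values)))
    }
    if (is.null(col_labels)) {
      col_labels <- colnames(values)
      if (is.null(col_labels))

        col_labels <- if (ncol(values) == length(labels)) labels else
          paste0("V", seq_len(ncol(values)))
    }
    writeLines(paste(c("", col_labels), collapse = "\t"), con)
    body <- apply(values, 1, function(r) paste(fmt17(r), collapse = "\t"))
    writeLines(paste(labels, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix()]
#'
#' @param path file path (TSV with header row and leading label column).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    fcnet_stop(sprintf("file not found: %s", path), "fcnet_format")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  toks <- strsplit(lines[-1], "\t", fixed = TRUE)
  lab <- vapply(toks, `[[`, character(1), 1)
  mat <- do.call(rbind, lapply(toks, function(r) as.numeric(r[-1])))
  dimnames(mat) <- list(lab, header)
  mat
}

#' Read an FIR kernel file (one coefficient per line)
#'
#' @param path file path.
#' @return Numeric coefficient vector.
#' @export
read_kernel <- function(path) {
  if (!file.exists(path))
    fcnet_stop(sprintf("file not found: %s", path), "fcnet_format")
  v <- suppressWarnings(as.numeric(readLines(path)))
  if (any(is.na(v)) || length(v) < 1)
    fcnet_stop("kernel file must hold one numeric coefficient per line",
               "fcnet_parse")
  v
}
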