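#' Read a recording from disk
#'
#' Two dialects are supported: a delimited numeric matrix (TSV, one row per
#' channel, first column the 10-20 label) and EDF (European Data Format).
#' The matrix dialect does not store the sampling rate in the data file;
#' `fs` must be supplied either as an argument or through the YAML sidecar
#' written by [write_recording()] (`<path>.yml` with keys `fs` and
#' `reference`).
#'
#' @param path file path.
#' @param format `"matrix"` or `"edf"`; default guessed from the extension.
#' @param fs sampling rate in Hz (matrix dialect only; overrides sidecar).
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf"),
                           fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         matrix = read_recording_matrix(path, fs = fs),
         edf = read_edf(path))
}

#' Write a recording to disk
#'
#' @param rec an [recording()].
#' @param path destination; `.edf` extension selects EDF, anything else the
#'   TSV matrix dialect (which also writes a `<path>.yml` sidecar carrying
#'   `fs` and `reference`).
#' @param format `"matrix"` or `"edf"` to override extension guessing.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "matrix", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  switch(format,
         matrix = write_recording_matrix(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

write_recording_matrix <- function(rec, path) {
  # %.17g keeps doubles lossless across the round trip
  lines <- vapply(seq_len(nrow(rec$data)), function(i) {
    paste(c(rec$labels[i], sprintf("%.17g", rec$data[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  yaml::write_yaml(list(fs = rec$fs, reference = rec$reference),
                   paste0(path, ".yml"))
  invisible(path)
}

read_recording_matrix <- function(path, fs = NULL) {
  reference <- "as-recorded"
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(fs)) fs <- meta$fs
    if (!is.null(meta$reference)) reference <- meta$reference
  }
  if (is.null(fs)) {
    stop("matrix dialect carries no sampling rate: pass fs= or provide the ",
         sidecar, " sidecar")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty recording file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != ncols[1])) {
    stop("ragged matrix file (row ", which(ncols != ncols[1])[1],
         " has ", ncols[which(ncols != ncols[1])[1]], " fields, expected ",
         ncols[1], ")")
  }
  labels <- vapply(parts, `[[`, character(1), 1L)
  data <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (anyNA(data)) stop("non-numeric samples in ", path)
  known <- labels %in% montage_32()
  if (!all(known)) {
    warning("channel labels not in the 10-20 montage: ",
            paste(labels[!known], collapse = ", "), " (retained)")
  }
  recording(data, fs = fs, labels = labels, reference = reference)
}

#' Standard 32-channel 10-20 montage labels
#'
#' The actiCAP-style 32-electrode layout used as the generator default;
#' includes the sensorimotor sites C3/Cz/C4 and the frontal, parietal and
#' occipital control sites.
#'
#' @return Character vector of 32 labels.
#' @export
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
}
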