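#' Multichannel EEG recording
#'
#' Container for a channels-by-samples matrix with a sampling rate, ordered
#' 10-20 channel labels and a reference tag. All samples must be finite.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV).
#' @param fs sampling rate in Hz, `> 0`.
#' @param labels character vector of unique channel names, one per row.
#' @param reference reference tag, `"as-recorded"` or `"average"`.
#' @return An `eeg_recording` object.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100, labels = c("C3", "C4"))
#' rec
#' @export
recording <- function(data, fs, labels,
                      reference = c("as-recorded", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop("label count (", length(labels), ") != channel count (",
         nrow(data), ")")
  }
  if (anyDuplicated(labels)) {
    stop("duplicated channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

#' Extract one channel's series
#'
#' @param rec an [recording()].
#' @param electrode channel label or row index.
#' @return Numeric vector of samples (µV).
#' @export
channel <- function(rec, electrode) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(electrode)) {
    if (!electrode %in% rec$labels) {
      stop("unknown electrode label: ", electrode)
    }
  }
  rec$data[electrode, ]
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean from every sample. The result has
#' channel-mean exactly zero at each sample and is tagged with reference
#' `"average"`. Idempotent and linear.
#'
#' @param rec an [recording()] with at least 2 channels.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) {
    stop("average reference requires at least 2 channels")
  }
  centered <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  recording(centered, rec$fs, rec$labels, reference = "average")
}

#' Screen a recording for artifact-free segments
#'
#' Returns the maximal contiguous sample ranges in which every channel stays
#' strictly below `amplitude_limit` in absolute value and no channel is
#' constant for `flat_limit` or more consecutive samples (flatline, e.g. an
#' unplugged electrode). An automated stand-in for manual artifact
#' inspection; per-channel rejection fractions are reported via attribute
#' `"rejection_fraction"`.
#'
#' @param rec an [recording()].
#' @param amplitude_limit absolute amplitude threshold in µV (default 100).
#' @param flat_limit flatline length threshold in seconds (default 0.1).
#' @return Data frame with 0-based `onset` and `length` columns, segments
#'   disjoint and sorted; zero rows when nothing survives.
#' @export
screen_artifacts <- function(rec, amplitude_limit = 100, flat_limit = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (amplitude_limit <= 0 || flat_limit <= 0) stop("limits must be > 0")
  n <- n_samples(rec)
  flat_n <- max(2L, ceiling(flat_limit * rec$fs))
  bad <- matrix(FALSE, nrow(rec$data), n)
  bad[abs(rec$data) >= amplitude_limit] <- TRUE
  for (ch in seq_len(nrow(rec$data))) {
    if (n < flat_n) break
    d <- diff(rec$data[ch, ]) == 0
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= flat_n - 1L)) {
      bad[ch, starts[k]:(ends[k] + 1L)] <- TRUE
    }
  }
  bad_any <- apply(bad, 2L, any)
  segs <- runs_false(bad_any)
  attr(segs, "rejection_fraction") <- rowMeans(bad)
  segs
}

# maximal runs of FALSE in a logical vector -> data.frame(onset 0-based, length)
runs_false <- function(bad) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(onset = starts[keep] - 1L, length = r$lengths[keep])
}

#' Extract fixed-length epochs from a recording
#'
#' Sample indexing is 0-based and intervals half-open `[onset, onset + length)`.
#' Out-of-bounds onsets are dropped with a message; an empty result is an
#' error.
#'
#' @param rec an [recording()].
#' @param onsets integer vector of 0-based onset samples.
#' @param length epoch length in samples.
#' @param condition `"rest"` or `"task"`.
#' @return An `epoch_set`: list with `condition`, `segments` (data frame of
#'   `onset`, `length`) and `source` (the recording).
#' @export
extract_epochs <- function(rec, onsets, length,
                           condition = c("task", "rest")) {
  stopifnot(inherits(rec, "eeg_recording"))
  condition <- match.arg(condition)
  length <- as.integer(length)
  if (length <= 0L) stop("epoch length must be > 0")
  onsets <- as.integer(onsets)
  n <- n_samples(rec)
  ok <- onsets >= 0L & (onsets + length) <= n
  if (any(!ok)) {
    message(sum(!ok), " of ", base::length(onsets),
            " onsets out of bounds; dropped")
  }
  onsets <- onsets[ok]
  if (base::length(onsets) == 0L) stop("no epochs remain after bounds check")
  structure(list(condition = condition,
                 segments = data.frame(onset = onsets, length = length),
                 source = rec),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d %s epochs of %d samples\n",
              nrow(x$segments), x$condition, x$segments$length[1]))
  invisible(x)
}

# pull one epoch's single-channel series (0-based onset)
epoch_series <- function(epochs, i, electrode) {
  seg <- epochs$segments[i, ]
  channel(epochs$source, electrode)[(seg$onset + 1L):(seg$onset + seg$length)]
}
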