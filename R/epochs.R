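#' Epoched multichannel EEG
#'
#' Container for a block of EEG epochs: a trials x channels x samples array of
#' amplitudes in microvolts, the sampling rate, the epoch start time relative
#' to test-sequence onset, the channel labels, and a per-trial event table
#' (participant, block, trial, adaptation condition, numerosity).
#'
#' All times are in milliseconds with 0 = test-sequence onset; sample windows
#' throughout the package are half-open `[start, stop)`.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param sfreq sampling rate in samples/s.
#' @param t0 epoch start in ms relative to test onset.
#' @param labels channel labels (length = dim 2 of `data`).
#' @param events data.frame with one row per trial; columns `participant`,
#'   `block`, `trial`, `adaptation` (\"High\"/\"Low\") and `numerosity`.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, sfreq = 500, t0 = -500, labels, events) {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("data must be a trials x channels x samples array")
  if (!all(is.finite(data)))
    stop("non-finite sample values in epoch data")
  if (dim(data)[2] != length(labels))
    stop("channel axis (", dim(data)[2], ") does not match labels (",
         length(labels), ")")
  if (!is.data.frame(events) || nrow(events) != dim(data)[1])
    stop("events must be a data.frame with one row per trial")
  req <- c("participant", "block", "trial", "adaptation", "numerosity")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events missing column(s): ", paste(miss, collapse = ", "))
  if (!all(events$adaptation %in% c("High", "Low")))
    stop("adaptation labels must be \"High\" or \"Low\"")
  if (sfreq <= 0) stop("sfreq must be positive")
  structure(list(data = data, sfreq = sfreq, t0 = t0,
                 labels = as.character(labels),
                 events = as.data.frame(events, stringsAsFactors = FALSE)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d trials x %d channels x %d samples, %g Hz, [%g, %g) ms\n",
              d[1], d[2], d[3], x$sfreq, x$t0, x$t0 + d[3] / x$sfreq * 1000))
  invisible(x)
}

#' Per-sample times of an epoch array or evoked response (ms)
#' @param x an `epoch_array` or `evoked`.
#' @return numeric vector of sample times.
#' @export
epoch_times <- function(x) {
  n <- if (inherits(x, "epoch_array")) dim(x$data)[3] else ncol(x$data)
  x$t0 + (seq_len(n) - 1) / x$sfreq * 1000
}

# indices of samples in the half-open window [start, stop) ms
.window_idx <- function(x, start, stop) {
  tt <- epoch_times(x)
  which(tt >= start - 1e-9 & tt < stop - 1e-9)
}

#' Subset trials of an epoch array
#' @param epochs an [epoch_array()].
#' @param keep logical or integer index over trials.
#' @return The subsetted `epoch_array`.
#' @export
subset_epochs <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_array"))
  epoch_array(epochs$data[keep, , , drop = FALSE], epochs$sfreq, epochs$t0,
              epochs$labels, epochs$events[keep, , drop = FALSE])
}

#' Write / read an epoch store
#'
#' The store is a single RDS file holding the epoch data (trials x channels x
#' samples, microvolts), the event table, channel labels and the `sfreq` /
#' `t0` attributes. `read_epochs(write_epochs(x))` is the identity on data,
#' labels, sfreq and t0.
#'
#' @param epochs an [epoch_array()].
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [epoch_array()] and fails naming the missing field if the store lacks a
#'   required attribute.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  saveRDS(list(data = epochs$data, events = epochs$events,
               labels = epochs$labels, sfreq = epochs$sfreq,
               t0_ms = epochs$t0), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("epoch store not found: ", path)
  obj <- readRDS(path)
  req <- c("data", "events", "labels", "sfreq", "t0_ms")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("epoch store missing required attribute(s): ",
         paste(miss, collapse = ", "))
  epoch_array(obj$data, sfreq = obj$sfreq, t0 = obj$t0_ms,
              labels = obj$labels, events = obj$events)
}

#' Behavioral table I/O
#'
#' Per-trial behavioral records: participant, block, trial, adaptation
#' condition, true numerosity and the (non-negative integer) verbal estimate,
#' stored as plain CSV.
#'
#' @param behavior data.frame with columns `participant`, `block`, `trial`,
#'   `adaptation`, `true_numerosity`, `estimate`.
#' @param path file path.
#' @return `write_behavior` returns `path` invisibly; `read_behavior` the
#'   validated data.frame.
#' @export
write_behavior <- function(behavior, path) {
  validate_behavior(behavior)
  utils::write.csv(behavior, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("behavioral table not found: ", path)
  validate_behavior(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_behavior
#' @export
validate_behavior <- function(behavior) {
  req <- c("participant", "block", "trial", "adaptation",
           "true_numerosity", "estimate")
  miss <- setdiff(req, names(behavior))
  if (length(miss))
    stop("behavioral table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(behavior$adaptation %in% c("High", "Low")))
    stop("adaptation labels must be \"High\" or \"Low\"")
  if (!all(behavior$true_numerosity %in% c(14L, 16L, 18L, 20L, 22L)))
    stop("true_numerosity outside {14, 16, 18, 20, 22}")
  if (any(behavior$estimate < 0) || any(behavior$estimate != round(behavior$estimate)))
    stop("estimates must be non-negative integers")
  behavior
}

#' Named result container for channel- or pair-wise tests
#'
#' @param names feature names (channels or channel pairs).
#' @param statistic observed test statistic per feature.
#' @param p raw p values.
#' @param p_adjusted FDR-adjusted p values.
#' @param significant logical significance mask at level `q`.
#' @param n_permutations,q,seed provenance of the test.
#' @return An object of class `result_set`.
#' @export
result_set <- function(names, statistic, p, p_adjusted, significant,
                       n_permutations = NA_integer_, q = NA_real_,
                       seed = NA_integer_) {
  stopifnot(length(names) == length(p), length(p) == length(p_adjusted),
            length(p) == length(significant))
  if (any(p < 0 | p > 1) || any(p_adjusted < 0 | p_adjusted > 1))
    stop("p values must lie in [0, 1]")
  if (any(p_adjusted < p - 1e-12))
    stop("adjusted p below raw p")
  if (!is.na(q) && any(significant & p_adjusted > q + 1e-12))
    stop("significance mask inconsistent with q")
  structure(list(names = as.character(names), statistic = statistic,
                 p = p, p_adjusted = p_adjusted,
                 significant = as.logical(significant),
                 provenance = list(n_permutations = n_permutations,
                                   q = q, seed = seed)),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d features, %d significant (q = %g, %s permutations)\n",
              length(x$names), sum(x$significant), x$provenance$q,
              format(x$provenance$n_permutations)))
  if (any(x$significant))
    cat("  significant:", paste(x$names[x$significant], collapse = ", "), "\n")
  invisible(x)
}
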