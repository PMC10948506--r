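#' Selective trial averaging
#'
#' Averages the epochs matching an adaptation condition (and optionally a
#' numerosity subset) into an evoked response.
#'
#' @param epochs an [epoch_array()].
#' @param condition adaptation condition ("High"/"Low"), or `NULL` for all.
#' @param numerosity numerosity subset, or `NULL` for all.
#' @return An object of class `evoked`: channels x samples matrix `data`,
#'   plus `sfreq`, `t0`, `labels`, `condition`, `numerosities`, `n_trials`.
#' @export
compute_evoked <- function(epochs, condition = NULL, numerosity = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  keep <- rep(TRUE, nrow(epochs$events))
  if (!is.null(condition)) keep <- keep & epochs$events$adaptation == condition
  if (!is.null(numerosity)) keep <- keep & epochs$events$numerosity %in% numerosity
  if (!any(keep))
    stop("no trials match condition=", condition %||% "*",
         " numerosity=", paste(numerosity %||% "*", collapse = ","))
  dat <- epochs$data[keep, , , drop = FALSE]
  avg <- colMeans(dat, dims = 1)         # channels x samples
  rownames(avg) <- epochs$labels
  structure(list(data = avg, sfreq = epochs$sfreq, t0 = epochs$t0,
                 labels = epochs$labels, condition = condition,
                 numerosities = sort(unique(epochs$events$numerosity[keep])),
                 n_trials = sum(keep)),
            class = "evoked")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Event-related potential to the test onset
#'
#' Averages trials of numerosities 14, 16, 18 and 20 (22 is excluded: its
#' second flash falls inside the ERP window), trims the result to
#' `[-100, 200)` ms and subtracts the per-channel baseline mean over
#' `[-100, 0)` ms.
#'
#' @param epochs an [epoch_array()] covering `[-100, 200)` ms.
#' @param condition adaptation condition.
#' @param numerosities trial subset entering the average.
#' @return An `evoked` with 150 samples at 500 Hz, baseline-corrected.
#' @export
compute_erp <- function(epochs, condition,
                        numerosities = c(14, 16, 18, 20)) {
  ev <- compute_evoked(epochs, condition, numerosities)
  idx <- .window_idx(ev, -100, 200)
  if (length(idx) != round(0.3 * ev$sfreq))
    stop("epoch does not cover the [-100, 200) ms ERP window")
  base <- .window_idx(ev, -100, 0)
  out <- ev
  out$data <- ev$data[, idx, drop = FALSE] -
    rowMeans(ev$data[, base, drop = FALSE])
  out$t0 <- -100
  out
}

#' Average an evoked response over a channel cluster
#'
#' @param evoked an `evoked`.
#' @param channels channel names to average (unweighted).
#' @return Numeric vector, one value per sample.
#' @export
cluster_timecourse <- function(evoked, channels = c("PO3", "PO4", "POz",
                                                    "PO7", "PO8", "O1", "O2")) {
  stopifnot(inherits(evoked, "evoked"))
  miss <- setdiff(channels, evoked$labels)
  if (length(miss)) stop("unknown channel: ", paste(miss, collapse = ", "))
  colMeans(evoked$data[match(channels, evoked$labels), , drop = FALSE])
}

#' Pointwise paired comparison of two sets of ERP timecourses
#'
#' Paired sign-flip permutation test at every time sample, with
#' Benjamini-Hochberg FDR correction across samples.
#'
#' @param high,low participants x samples matrices of cluster timecourses,
#'   participant-paired (same row order).
#' @param n_permutations,q,seed permutation test parameters.
#' @return A [result_set()] with one entry per time sample.
#' @export
compare_erp <- function(high, low, n_permutations = 15000, q = 0.05,
                        seed = NULL) {
  high <- as.matrix(high); low <- as.matrix(low)
  if (!all(dim(high) == dim(low))) stop("high/low dimensions differ")
  if (nrow(high) < 2) stop("need >= 2 participants")
  pt <- paired_permutation_test(high, low, n_permutations = n_permutations,
                                seed = seed)
  bh <- fdr_bh(pt$p, q = q)
  result_set(names = paste0("t", seq_len(ncol(high))),
             statistic = pt$statistic, p = pt$p,
             p_adjusted = bh$p_adjusted, significant = bh$significant,
             n_permutations = n_permutations, q = q,
             seed = seed %||% NA_integer_)
}
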