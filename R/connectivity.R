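#' Apply the surface-Laplacian spatial filter
#'
#' Spherical-spline surface Laplacian (see [laplacian_matrix()]) applied to
#' every sample of an epoch array or evoked response. Linear in the input;
#' output units are arbitrary (current source density up to a constant).
#'
#' @param x an [epoch_array()] or `evoked`.
#' @param mont the matching [montage()].
#' @param ... passed to [laplacian_matrix()].
#' @return Object of the same class, Laplacian-transformed.
#' @export
surface_laplacian <- function(x, mont, ...) {
  L <- laplacian_matrix(mont, ...)
  if (inherits(x, "epoch_array")) {
    if (!identical(x$labels, mont$labels))
      stop("epoch channels do not match the montage")
    out <- x
    for (i in seq_len(dim(x$data)[1])) out$data[i, , ] <- L %*% x$data[i, , ]
    out
  } else if (inherits(x, "evoked")) {
    if (!identical(x$labels, mont$labels))
      stop("evoked channels do not match the montage")
    out <- x
    out$data <- L %*% x$data
    out
  } else stop("x must be an epoch_array or evoked")
}

# analytic signal of each column via FFT half-spectrum doubling
.analytic <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Narrowband instantaneous phase and envelope at a tagging frequency
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass centered at
#' `f_tag` with half-bandwidth `half_bw` (default 2 Hz), followed by the
#' Hilbert analytic signal. The forward-backward response, the squared
#' magnitude `|H|^2` of the 2nd-order Butterworth with zero phase, is applied
#' in the frequency domain fused with the Hilbert half-spectrum mask (one FFT
#' round trip per evoked response); its boundary behavior differs from
#' time-domain filtering only near the epoch edges, and samples within
#' `edge_ms` of each end of the test window are marked invalid to exclude
#' those filter and Hilbert edge artifacts.
#'
#' @param evoked an `evoked` (or any channels x samples `evoked`-like
#'   object covering the test window).
#' @param f_tag center frequency (Hz), below Nyquist.
#' @param half_bw half-bandwidth of the pass band (Hz).
#' @param edge_ms excluded margin at each end of the test window (ms).
#' @param test_window the analysis window (ms) whose interior is valid.
#' @return An object of class `analytic_signal`: `phase` (channels x samples,
#'   wrapped to (-pi, pi]), `envelope` (>= 0), `valid` (logical per sample),
#'   `f_tag`, `sfreq`, `t0`, `labels`.
#' @export
narrowband_phase <- function(evoked, f_tag, half_bw = 2, edge_ms = 500,
                             test_window = c(0, 4000)) {
  stopifnot(inherits(evoked, "evoked"))
  nyq <- evoked$sfreq / 2
  lo <- f_tag - half_bw
  hi <- f_tag + half_bw
  if (lo <= 0 || hi >= nyq)
    stop("band edges [", lo, ", ", hi, "] Hz outside (0, Nyquist)")
  bt <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  x <- t(evoked$data)                  # samples x channels
  n <- nrow(x)
  z <- exp(-2i * pi * (0:(n - 1)) / n) # two-sided digital frequency grid
  Hnum <- Reduce(`+`, lapply(seq_along(bt$b),
                             function(k) bt$b[k] * z^(k - 1)))
  Hden <- Reduce(`+`, lapply(seq_along(bt$a),
                             function(k) bt$a[k] * z^(k - 1)))
  mag2 <- Mod(Hnum / Hden)^2           # forward-backward (zero-phase) gain
  hmask <- numeric(n)
  if (n %% 2 == 0) {
    hmask[c(1, n / 2 + 1)] <- 1
    hmask[2:(n / 2)] <- 2
  } else {
    hmask[1] <- 1
    hmask[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  an <- stats::mvfft(X * (mag2 * hmask), inverse = TRUE) / n
  phase <- t(Arg(an))
  env <- t(Mod(an))
  tt <- epoch_times(evoked)
  valid <- tt >= test_window[1] + edge_ms - 1e-9 &
    tt < test_window[2] - edge_ms - 1e-9
  dimnames(phase) <- dimnames(env) <- list(evoked$labels, NULL)
  structure(list(phase = phase, envelope = env, valid = valid,
                 f_tag = f_tag, sfreq = evoked$sfreq, t0 = evoked$t0,
                 labels = evoked$labels),
            class = "analytic_signal")
}

#' Inter-site phase clustering of two phase series
#'
#' `ISPC = |mean over valid samples of exp(i (phi_a - phi_b))|`: 1 when the
#' phase difference is constant, ~`0.886/sqrt(T)` for `T` independent uniform
#' phase differences. Invariant to constant phase offsets and to swapping the
#' two series.
#'
#' @param phase_a,phase_b equal-length phase series (radians).
#' @param valid logical mask of valid samples (default: all).
#' @param min_valid minimum number of valid samples.
#' @return Scalar in `[0, 1]`.
#' @export
ispc <- function(phase_a, phase_b, valid = NULL, min_valid = 100) {
  if (length(phase_a) != length(phase_b))
    stop("phase series lengths differ")
  if (is.null(valid)) valid <- rep(TRUE, length(phase_a))
  if (!any(valid)) stop("empty valid mask")
  if (sum(valid) < min_valid)
    stop("fewer than ", min_valid, " valid samples")
  Mod(mean(exp(1i * (phase_a[valid] - phase_b[valid]))))
}

#' Condition ISPC matrix over all channel pairs
#'
#' Pipeline per numerosity: surface Laplacian -> selective trial average
#' within (condition x numerosity) -> narrowband Hilbert phase at that
#' numerosity's tagging frequency -> ISPC for all channel pairs over the
#' valid samples; the five per-numerosity matrices are then averaged
#' (never across conditions). The Laplacian commutes with trial averaging
#' (both are linear), so it is applied to the averaged response.
#'
#' @param epochs one participant's [epoch_array()] containing all
#'   numerosities of the condition.
#' @param condition adaptation condition ("High"/"Low").
#' @param mont the matching [montage()].
#' @param test_duration test window duration (ms).
#' @param half_bw,edge_ms see [narrowband_phase()].
#' @param numerosities the numerosity cells required and averaged over.
#' @return An object of class `ispc_matrix`: symmetric channels x channels
#'   `values` in `[0, 1]` with unit diagonal, plus `condition`,
#'   `numerosities`, `labels`.
#' @export
ispc_matrix <- function(epochs, condition, mont, test_duration = 4000,
                        half_bw = 2, edge_ms = 500,
                        numerosities = c(14, 16, 18, 20, 22)) {
  stopifnot(inherits(epochs, "epoch_array"))
  nums <- sort(numerosities)
  have <- sort(unique(epochs$events$numerosity[
    epochs$events$adaptation == condition]))
  if (!all(nums %in% have) || length(nums) == 0)
    stop("missing (condition x numerosity) cell for condition ", condition,
         ": ", paste(setdiff(nums, have), collapse = ", "))
  L <- laplacian_matrix(mont)
  acc <- NULL
  for (nn in nums) {
    ev <- compute_evoked(epochs, condition, nn)
    ev$data <- L %*% ev$data
    an <- narrowband_phase(ev, tagging_frequency(nn, test_duration),
                           half_bw = half_bw, edge_ms = edge_ms,
                           test_window = c(0, test_duration))
    E <- exp(1i * an$phase[, an$valid, drop = FALSE])
    M <- Mod(E %*% Conj(t(E))) / sum(an$valid)
    acc <- if (is.null(acc)) M else acc + M
  }
  vals <- acc / length(nums)
  diag(vals) <- 1
  dimnames(vals) <- list(epochs$labels, epochs$labels)
  structure(list(values = vals, condition = condition, numerosities = nums,
                 labels = epochs$labels),
            class = "ispc_matrix")
}

#' Per-participant ISPC matrices for both conditions
#' @inheritParams ispc_matrix
#' @return list with elements `High` and `Low`, each an `ispc_matrix`.
#' @export
participant_ispc <- function(epochs, mont, test_duration = 4000,
                             half_bw = 2, edge_ms = 500) {
  list(High = ispc_matrix(epochs, "High", mont, test_duration, half_bw,
                          edge_ms),
       Low = ispc_matrix(epochs, "Low", mont, test_duration, half_bw,
                         edge_ms))
}

# upper-triangle pair names "A-B" for a label set
.pair_names <- function(labels) {
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  paste0(labels[idx[, 1]], "-", labels[idx[, 2]])
}

# stack a list of ispc_matrix into participants x pairs matrix
.pair_stack <- function(mats) {
  labels <- mats[[1]]$labels
  ut <- upper.tri(diag(length(labels)))
  out <- t(vapply(mats, function(m) m$values[ut],
                  numeric(sum(ut))))
  colnames(out) <- .pair_names(labels)
  out
}

#' Pairwise comparison of ISPC matrices between conditions
#'
#' Paired sign-flip permutation test for every unique off-diagonal channel
#' pair (435 pairs for 30 channels), with Benjamini-Hochberg FDR correction
#' across pairs.
#'
#' @param mats_high,mats_low lists of `ispc_matrix` (one per participant,
#'   paired by position).
#' @param n_permutations,q,seed permutation test parameters.
#' @return A [result_set()] keyed by channel pair ("A-B").
#' @export
compare_ispc <- function(mats_high, mats_low, n_permutations = 15000,
                         q = 0.05, seed = NULL) {
  if (length(mats_high) != length(mats_low))
    stop("high/low participant counts differ")
  if (length(mats_high) < 2) stop("need >= 2 participants")
  a <- .pair_stack(mats_high)
  b <- .pair_stack(mats_low)
  pt <- paired_permutation_test(a, b, n_permutations = n_permutations,
                                seed = seed)
  bh <- fdr_bh(pt$p, q = q)
  result_set(names = colnames(a), statistic = pt$statistic, p = pt$p,
             p_adjusted = bh$p_adjusted, significant = bh$significant,
             n_permutations = n_permutations, q = q,
             seed = seed %||% NA_integer_)
}
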