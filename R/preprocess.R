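#' Design the linear-phase FIR band-pass filter
#'
#' Hamming-windowed sinc band-pass with a 1-40 Hz passband and -6 dB points
#' at 0.5 and 40.5 Hz. Because the lower transition band sits next to DC,
#' the realized -6 dB frequency of a windowed design drifts from the
#' requested cutoff (spectral folding at 0 Hz); the requested cutoffs are
#' therefore calibrated by root-finding so the realized -6 dB points land on
#' `f_6db` exactly. The default order (even, ~3.3 / transition-width cycles)
#' gives < 0.2% passband ripple and ~40 dB DC attenuation.
#'
#' @param sfreq sampling rate (samples/s).
#' @param f_pass passband edges (Hz).
#' @param f_6db required -6 dB frequencies (Hz).
#' @param order filter order (even); default from the low-edge transition
#'   width `2 * (f_pass[1] - f_6db[1])`.
#' @return An object of class `fir_spec`: coefficients, order, sfreq, and the
#'   realized band edges.
#' @export
fir_bandpass_design <- function(sfreq = 500, f_pass = c(1, 40),
                                f_6db = c(0.5, 40.5), order = NULL) {
  if (sfreq <= 2 * f_6db[2])
    stop("sampling rate too low for the upper cutoff")
  if (!(f_6db[1] < f_pass[1] && f_pass[1] < f_pass[2] && f_pass[2] < f_6db[2]))
    stop("cutoffs must bracket the passband")
  if (is.null(order)) {
    tw <- 2 * (f_pass[1] - f_6db[1])
    order <- ceiling(3.3 * sfreq / tw)
  }
  if (order %% 2 == 1) order <- order + 1
  gain_at <- function(lo, hi, f) {
    b <- signal::fir1(order, c(lo, hi) / (sfreq / 2), type = "pass")
    abs(sum(b * exp(-2i * pi * f / sfreq * (0:order))))
  }
  lo <- stats::uniroot(function(z) gain_at(z, f_6db[2], f_6db[1]) - 0.5,
                       c(f_6db[1] * 0.5, f_pass[1] * 1.5), tol = 1e-4)$root
  hi <- stats::uniroot(function(z) gain_at(lo, z, f_6db[2]) - 0.5,
                       c(f_6db[2] * 0.95, f_6db[2] * 1.05), tol = 1e-4)$root
  coef <- signal::fir1(order, c(lo, hi) / (sfreq / 2), type = "pass")
  structure(list(coef = as.numeric(coef), order = order, sfreq = sfreq,
                 f_pass = f_pass, f_6db = f_6db,
                 design_cutoffs = c(lo, hi)),
            class = "fir_spec")
}

#' Frequency response magnitude of an FIR design
#' @param spec a `fir_spec`.
#' @param f frequencies (Hz).
#' @return Gain magnitudes at `f`.
#' @export
fir_gain <- function(spec, f) {
  vapply(f, function(ff)
    abs(sum(spec$coef * exp(-2i * pi * ff / spec$sfreq * (0:spec$order)))),
    numeric(1))
}

# zero-phase application of a linear-phase FIR to the columns of a matrix
# (samples x channels): reflection padding + FFT convolution + group-delay
# compensation
.fir_apply <- function(x, coef) {
  n <- nrow(x)
  ord <- length(coef) - 1L
  half <- ord %/% 2L
  xp <- rbind(x[(half + 1):2, , drop = FALSE],
              x,
              x[(n - 1):(n - half), , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np + ord, c(2, 3, 5))
  B <- stats::fft(c(coef, rep(0, nfft - length(coef))))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(x))))
  Y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  Y[(2L * half + 1):(2L * half + n), , drop = FALSE]
}

#' Band-pass filter epochs with a linear-phase FIR
#'
#' Applied forward with explicit group-delay compensation (the filter is
#' linear-phase, so the net phase response is zero) and reflection padding at
#' the epoch edges.
#'
#' @param epochs an [epoch_array()].
#' @param spec a `fir_spec` from [fir_bandpass_design()]; designed at the
#'   epochs' sampling rate when `NULL`.
#' @return The filtered [epoch_array()].
#' @export
bandpass_fir <- function(epochs, spec = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (is.null(spec)) spec <- fir_bandpass_design(sfreq = epochs$sfreq)
  stopifnot(inherits(spec, "fir_spec"))
  if (abs(spec$sfreq - epochs$sfreq) > 1e-9)
    stop("filter designed for ", spec$sfreq, " Hz, epochs at ", epochs$sfreq)
  nsamp <- dim(epochs$data)[3]
  if (nsamp < length(spec$coef))
    stop("epoch too short for the filter: ", nsamp, " samples < ",
         length(spec$coef), " coefficients")
  out <- epochs
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    xi <- array(epochs$data[i, , ], dim = d[2:3])   # channels x samples
    out$data[i, , ] <- t(.fir_apply(t(xi), spec$coef))
  }
  out
}

#' Re-reference epochs to the average of all channels
#'
#' After re-referencing, the mean across channels is zero at every sample;
#' the operation is a projection (idempotent).
#'
#' @param epochs an [epoch_array()].
#' @return The re-referenced [epoch_array()].
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (dim(epochs$data)[2] < 2) stop("average reference needs >= 2 channels")
  mu <- colMeans(aperm(epochs$data, c(2, 1, 3)), dims = 1)  # trials x samples
  out <- epochs
  out$data <- epochs$data - aperm(array(mu, dim = dim(epochs$data)[c(1, 3, 2)]),
                                  c(1, 3, 2))
  out
}

#' Replace a bad channel by spherical-spline interpolation
#'
#' The bad channel is reconstructed from all remaining channels with the same
#' spherical-spline basis used by the surface Laplacian (order m = 4,
#' regularization 1e-5, 50 Legendre terms). Other channels are untouched;
#' re-interpolating the same channel is a fixed point.
#'
#' @param epochs an [epoch_array()].
#' @param bad_label channel to replace.
#' @param mont the [montage()] matching the epochs' channel axis.
#' @return The corrected [epoch_array()].
#' @export
interpolate_channel <- function(epochs, bad_label, mont) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(mont, "montage"))
  if (!identical(epochs$labels, mont$labels))
    stop("epoch channels do not match the montage")
  if (!bad_label %in% mont$labels)
    stop("unknown channel: ", bad_label)
  good <- setdiff(mont$labels, bad_label)
  if (length(good) < 4) stop("too few good channels for interpolation")
  w <- .interp_weights(mont, bad_label, good)
  bad_i <- match(bad_label, epochs$labels)
  good_i <- match(good, epochs$labels)
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    out$data[i, bad_i, ] <- as.numeric(w %*% epochs$data[i, good_i, ])
  }
  out
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Deterministic stand-in for manual artifact inspection: an epoch is removed
#' iff any channel's peak-to-peak amplitude exceeds the threshold. Event rows
#' are removed in lockstep.
#'
#' @param epochs an [epoch_array()].
#' @param threshold peak-to-peak threshold (uV).
#' @return list with `epochs` (the retained trials) and `rejected_fraction`.
#' @export
reject_epochs <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (threshold <= 0) stop("threshold must be positive")
  ptp <- apply(epochs$data, 1, function(tr) max(apply(tr, 1, function(ch)
    diff(range(ch)))))
  keep <- ptp <= threshold
  if (!any(keep)) stop("all epochs rejected; downstream averages undefined")
  list(epochs = subset_epochs(epochs, keep),
       rejected_fraction = mean(!keep))
}
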