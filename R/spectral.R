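#' Single-sided FFT amplitude spectrum of an evoked response
#'
#' Computes the amplitude spectrum of the `[0, 4000)` ms test window
#' (2000 samples at 500 Hz, bin width 0.25 Hz, which makes every tagging
#' frequency bin-exact). Normalization: `|X(0)|/N` at DC and `2|X(k)|/N`
#' for k >= 1, so a sinusoid of amplitude A on an exact bin reads A.
#'
#' @param evoked an `evoked` covering the analysis window.
#' @param window half-open analysis window in ms.
#' @return An object of class `spectrum_set`: `amplitude` (channels x bins,
#'   uV), `freqs` (Hz), `df` (bin width, Hz).
#' @export
fft_amplitude <- function(evoked, window = c(0, 4000)) {
  stopifnot(inherits(evoked, "evoked"))
  idx <- .window_idx(evoked, window[1], window[2])
  n_expect <- round((window[2] - window[1]) / 1000 * evoked$sfreq)
  if (length(idx) != n_expect)
    stop("analysis window [", window[1], ", ", window[2],
         ") ms not fully inside the epoch")
  x <- t(evoked$data[, idx, drop = FALSE])   # samples x channels
  n <- nrow(x)
  X <- stats::mvfft(x)
  nb <- n %/% 2 + 1
  amp <- Mod(X[seq_len(nb), , drop = FALSE]) / n
  amp[-1, ] <- 2 * amp[-1, ]
  amp <- t(amp)
  rownames(amp) <- evoked$labels
  df <- evoked$sfreq / n
  structure(list(amplitude = amp, freqs = (seq_len(nb) - 1) * df, df = df,
                 labels = evoked$labels, window = window),
            class = "spectrum_set")
}

# bin index (1-based) of frequency f; errors when f is off-bin
.bin_index <- function(spectra, f) {
  k <- f / spectra$df
  if (abs(k - round(k)) > 1e-6)
    stop("frequency ", f, " Hz is not an exact multiple of the bin width ",
         spectra$df, " Hz (window/duration mismatch)")
  round(k) + 1L
}

#' Tagging-bin amplitudes and their numerosity average
#'
#' Extracts, for each numerosity, the per-channel amplitude at that
#' numerosity's tagging frequency (`numerosity / 4` Hz for a 4 s test) and
#' averages across numerosities (but never across adaptation conditions).
#'
#' @param spectra named list of `spectrum_set`, one per numerosity (names =
#'   numerosities).
#' @param numerosities numerosities to use; default = the list names.
#' @param test_duration test window duration (ms).
#' @return list with `per_numerosity` (channels x numerosities matrix) and
#'   `average` (per-channel numerosity-averaged amplitude).
#' @export
tagging_power <- function(spectra, numerosities = NULL,
                          test_duration = 4000) {
  if (is.null(numerosities)) numerosities <- as.numeric(names(spectra))
  stopifnot(length(spectra) == length(numerosities))
  cols <- lapply(seq_along(numerosities), function(j) {
    sp <- spectra[[j]]
    sp$amplitude[, .bin_index(sp, tagging_frequency(numerosities[j],
                                                    test_duration))]
  })
  per_num <- do.call(cbind, cols)
  colnames(per_num) <- as.character(numerosities)
  list(per_numerosity = per_num, average = rowMeans(per_num))
}

#' Per-participant numerosity-averaged tagging amplitude, both conditions
#'
#' Selective averaging per (condition x numerosity), FFT of the test window,
#' tagging-bin extraction, numerosity average.
#'
#' @param epochs one participant's [epoch_array()].
#' @param test_duration test window duration (ms).
#' @return 2 x channels matrix with rows "High" and "Low".
#' @export
participant_tagging_power <- function(epochs, test_duration = 4000) {
  stopifnot(inherits(epochs, "epoch_array"))
  nums <- sort(unique(epochs$events$numerosity))
  out <- matrix(NA_real_, 2, length(epochs$labels),
                dimnames = list(c("High", "Low"), epochs$labels))
  for (cond in c("High", "Low")) {
    spectra <- lapply(nums, function(nn)
      fft_amplitude(compute_evoked(epochs, cond, nn),
                    window = c(0, test_duration)))
    names(spectra) <- nums
    out[cond, ] <- tagging_power(spectra, nums, test_duration)$average
  }
  out
}

#' Channel-wise comparison of ssVEP tagging amplitude between conditions
#'
#' Paired sign-flip permutation test per channel with Benjamini-Hochberg FDR
#' correction across channels.
#'
#' @param power_high,power_low participants x channels matrices of
#'   numerosity-averaged tagging amplitudes, participant-paired.
#' @param n_permutations,q,seed permutation test parameters.
#' @return A [result_set()] keyed by channel.
#' @export
compare_ssvep <- function(power_high, power_low, n_permutations = 15000,
                          q = 0.05, seed = NULL) {
  power_high <- as.matrix(power_high); power_low <- as.matrix(power_low)
  if (!all(dim(power_high) == dim(power_low)))
    stop("high/low dimensions differ")
  if (nrow(power_high) < 2) stop("need >= 2 participants")
  pt <- paired_permutation_test(power_high, power_low,
                                n_permutations = n_permutations, seed = seed)
  bh <- fdr_bh(pt$p, q = q)
  result_set(names = colnames(power_high) %||%
               paste0("ch", seq_len(ncol(power_high))),
             statistic = pt$statistic, p = pt$p,
             p_adjusted = bh$p_adjusted, significant = bh$significant,
             n_permutations = n_permutations, q = q,
             seed = seed %||% NA_integer_)
}
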