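#' Behavioral generator parameters
#'
#' The generator is multiplicative: the estimate of a test of true numerosity
#' `N` after adaptor condition `c` is
#' `round(max(0, N * gain_c * s_p + eps))`, with a participant gain
#' `s_p ~ Normal(1, participant_gain_sd)` fixed per participant, trial noise
#' `eps ~ Normal(0, response_noise_sd)`, and rounding half away from zero
#' (verbal integer reports). Default gains 1.075 (Low) / 0.925 (High) are
#' calibrated so the expected overall adaptation percentage,
#' `100 * (gain_low - gain_high)`, is 15%.
#'
#' @param gain_high,gain_low multiplicative gains per adaptor condition.
#' @param participant_gain_sd SD of the per-participant gain.
#' @param response_noise_sd SD of the per-trial response noise (flashes).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(gain_high = 0.925, gain_low = 1.075,
                            participant_gain_sd = 0.05,
                            response_noise_sd = 1.2) {
  if (gain_high <= 0 || gain_low <= 0) stop("gains must be positive")
  if (participant_gain_sd < 0 || response_noise_sd < 0)
    stop("noise SDs must be non-negative")
  structure(list(gain_high = gain_high, gain_low = gain_low,
                 participant_gain_sd = participant_gain_sd,
                 response_noise_sd = response_noise_sd),
            class = "behavior_params")
}

# round half away from zero (symmetric verbal-report rounding)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate verbal numerosity estimates for a design
#'
#' @param design trial list from [generate_design()] (one or more
#'   participants row-bound).
#' @param params a [behavior_params()].
#' @param gain_scale scalar (or per-participant named vector) scaling the
#'   adaptation effect: condition gains become `1 + (gain - 1) * gain_scale`.
#'   Used to couple behavioral and EEG effect sizes across participants.
#' @return Behavioral table: `participant`, `block`, `trial`, `adaptation`,
#'   `true_numerosity`, `estimate`.
#' @export
simulate_behavior <- function(design, params = behavior_params(),
                              gain_scale = 1) {
  stopifnot(all(c("participant", "block", "trial", "adaptation",
                  "numerosity") %in% names(design)))
  ids <- unique(design$participant)
  s_p <- stats::setNames(1 + stats::rnorm(length(ids), 0,
                                          params$participant_gain_sd),
                         as.character(ids))
  if (length(gain_scale) == 1L)
    gain_scale <- stats::setNames(rep(gain_scale, length(ids)),
                                  as.character(ids))
  pid <- as.character(design$participant)
  lam <- gain_scale[pid]
  gain <- ifelse(design$adaptation == "High",
                 1 + (params$gain_high - 1) * lam,
                 1 + (params$gain_low - 1) * lam)
  mu <- design$numerosity * gain * s_p[pid]
  eps <- stats::rnorm(nrow(design), 0, params$response_noise_sd)
  est <- .round_half_away(pmax(0, mu + eps))
  data.frame(participant = design$participant, block = design$block,
             trial = design$trial, adaptation = design$adaptation,
             true_numerosity = design$numerosity, estimate = as.integer(est),
             stringsAsFactors = FALSE)
}

#' EEG effect specification for the synthetic generator
#'
#' Each simulated trial is the sum of (i) spatially correlated 1/f background
#' noise, (ii) intrinsic narrowband activity at the trial's tagging frequency
#' through which inter-site phase coupling is induced, and (iii) a
#' stimulus-locked ssVEP sinusoid at the tagging frequency, active during the
#' test window `[0, 4000)` ms, with condition-dependent amplitude at the
#' effect sensors and a Gaussian spatial falloff elsewhere.
#'
#' The narrowband activity is built on the DFT grid of the test window with
#' its exact tagging-bin coefficient zeroed, so it surrounds the tagging
#' frequency spectrally (and therefore drives the Hilbert-band phase) while
#' contributing nothing to the tagging-bin amplitude readout: the ssVEP and
#' connectivity manipulations stay independent by construction.
#'
#' The narrowband sources are modeled as focal cortical current sources
#' under the electrodes: each source is defined in current-source-density
#' space (a delta at its electrode) and mapped to the scalp through the
#' spherical-spline system's smooth forward field, so the surface-Laplacian
#' step of the connectivity analysis recovers it focally instead of
#' differencing it away between neighboring electrodes. They are
#' stimulus-entrained: one realization per numerosity, reproducible across
#' trials and across the two adaptation conditions (the test sequence is
#' identical), so selective trial averaging preserves them and
#' participant-level condition contrasts isolate what the adaptor
#' manipulates.
#'
#' Coupling: the channel-wise narrowband sources are drawn with target
#' covariance `I + w * A`, where `A` is the adjacency matrix of the coupling
#' pairs and `w = coupling_strength[condition]` the target band correlation
#' between pair members (capped at `0.95 / lambda_max(A)`, ~0.51 for the
#' default 4-pair graph, the joint feasibility limit of its hub topology).
#' Every channel keeps unit band variance and non-coupled pairs keep exactly
#' zero correlation, so the adaptor manipulates only the band-phase coupling
#' of the injected pairs.
#'
#' @param ssvep_amp_low ssVEP amplitude at effect sensors, Low condition (uV).
#' @param ssvep_amp_ratio_high High/Low amplitude ratio at effect sensors.
#' @param effect_sensors channels carrying the full ssVEP amplitude.
#' @param coupling_pairs list of length-2 character vectors of channel pairs.
#' @param coupling_strength named numeric `c(High = , Low = )` mixing weights
#'   in `[0, 1]`.
#' @param noise_exponent 1/f spectral exponent of the background noise.
#' @param noise_rms broadband background noise RMS per channel (uV).
#' @param nb_noise_rms RMS of each narrowband source in current-source-
#'   density units (the scalp footprint is this divided by the Laplacian
#'   scale, a few uV at the defaults).
#' @param nb_bw_sd spectral SD of the narrowband activity (Hz); kept inside
#'   the connectivity analysis band.
#' @param spatial_decay_deg Gaussian falloff scale (degrees of scalp angle) of
#'   the ssVEP topography away from the nearest effect sensor.
#' @param spatial_noise_share fraction of background-noise variance carried by
#'   shared low-rank spatial sources (volume-conduction stand-in).
#' @param n_spatial_sources number of shared spatial noise sources.
#' @param participant_amp_sd SD of the per-participant log-normal ssVEP
#'   amplitude gain.
#' @param nb_common_frac fraction of entrained narrowband source variance
#'   that is stimulus-determined, i.e. shared by all observers of the same
#'   experiment's test sequences; the rest is individual.
#' @param nb_common_seed integer keying the stimulus-determined stream; all
#'   participants simulated with the same key (one experiment) share that
#'   component, and a fresh key models a fresh experiment.
#' @return An object of class `eeg_effect_spec`.
#' @export
eeg_effect_spec <- function(ssvep_amp_low = 1.0, ssvep_amp_ratio_high = 1.3,
                            effect_sensors = c("POz", "O2", "C3", "Cz"),
                            coupling_pairs = list(c("C3", "CP5"),
                                                  c("CP5", "CP6"),
                                                  c("CP5", "POz"),
                                                  c("C3", "PO7")),
                            coupling_strength = c(High = 0.6, Low = 0.2),
                            noise_exponent = 1.0, noise_rms = 10,
                            nb_noise_rms = 28, nb_bw_sd = 1.2,
                            spatial_decay_deg = 6,
                            spatial_noise_share = 0.9,
                            n_spatial_sources = 6,
                            participant_amp_sd = 0.15,
                            nb_common_frac = 0.45,
                            nb_common_seed = 190000L) {
  if (ssvep_amp_low < 0 || ssvep_amp_ratio_high < 0)
    stop("amplitudes must be non-negative")
  if (any(coupling_strength < 0) || any(coupling_strength > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (!all(c("High", "Low") %in% names(coupling_strength)))
    stop("coupling_strength needs High and Low entries")
  structure(list(ssvep_amp_low = ssvep_amp_low,
                 ssvep_amp_ratio_high = ssvep_amp_ratio_high,
                 effect_sensors = effect_sensors,
                 coupling_pairs = coupling_pairs,
                 coupling_strength = coupling_strength,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 nb_noise_rms = nb_noise_rms, nb_bw_sd = nb_bw_sd,
                 spatial_decay_deg = spatial_decay_deg,
                 spatial_noise_share = spatial_noise_share,
                 n_spatial_sources = n_spatial_sources,
                 participant_amp_sd = participant_amp_sd,
                 nb_common_frac = nb_common_frac,
                 nb_common_seed = as.integer(nb_common_seed)),
            class = "eeg_effect_spec")
}

# unit-RMS 1/f noise, one column per series, via FFT magnitude shaping
.pink_noise <- function(nsamp, nseries, sfreq, exponent) {
  if (nseries == 0L) return(matrix(0, nsamp, 0))
  freqs <- seq(0, sfreq, length.out = nsamp + 1)[seq_len(nsamp)]
  f <- pmin(freqs, sfreq - freqs)          # two-sided frequency axis
  mag <- c(0, f[-1]^(-exponent / 2))       # no DC
  spec <- matrix(stats::rnorm(nsamp * nseries) +
                   1i * stats::rnorm(nsamp * nseries), nsamp, nseries) * mag
  x <- Re(stats::mvfft(spec, inverse = TRUE))
  sc <- sqrt(colMeans(x^2))
  sweep(x, 2, ifelse(sc > 0, sc, 1), "/")
}

# Unit-RMS narrowband noise centered at f0, built on the DFT grid of the
# test window (nwin samples) with the exact f0 bin zeroed, so the series is
# spectrally adjacent to, but exactly orthogonal to, the tagging bin of the
# analysis window. Zero outside the window. With `whiten = TRUE` the series
# block is orthonormalized over the window, so its sample covariance is
# exactly the identity: covariance structure later imposed on such a block
# is realized exactly rather than up to finite-sample error.
.narrowband_noise <- function(nsamp, win_idx, nseries, sfreq, f0, bw_sd,
                              whiten = FALSE) {
  if (nseries == 0L) return(matrix(0, nsamp, 0))
  nwin <- length(win_idx)
  freqs <- seq(0, sfreq, length.out = nwin + 1)[seq_len(nwin)]
  f <- pmin(freqs, sfreq - freqs)
  mag <- exp(-(f - f0)^2 / (2 * bw_sd^2))
  mag[abs(f - f0) < sfreq / nwin / 2] <- 0   # zero the tagging bin itself
  spec <- matrix(stats::rnorm(nwin * nseries) +
                   1i * stats::rnorm(nwin * nseries), nwin, nseries) * mag
  w <- Re(stats::mvfft(spec, inverse = TRUE))
  if (whiten && nseries > 1) {
    w <- w %*% solve(chol(crossprod(w) / nwin))
  } else {
    sc <- sqrt(colMeans(w^2))
    w <- sweep(w, 2, ifelse(sc > 0, sc, 1), "/")
  }
  x <- matrix(0, nsamp, nseries)
  x[win_idx, ] <- w
  x
}

# ssVEP spatial topography: exactly 1 at the effect sensors; elsewhere the
# minimum-leakage field around a Gaussian falloff reference. With the
# montage Laplacian `L` supplied, the free channels solve a small quadratic
# program that jointly penalizes scalp amplitude (which the tagging-bin
# readout sees) and current source density (which the Laplacian-filtered
# connectivity readout sees) away from the effect sensors, so the evoked
# response stays focal in BOTH analysis domains; `csd_weight` sets the
# trade-off. Without `L`, the plain Gaussian falloff is returned.
.ssvep_topography <- function(mont, effect_sensors, decay_deg, L = NULL,
                              csd_weight = 0.002) {
  miss <- setdiff(effect_sensors, mont$labels)
  if (length(miss)) stop("effect sensor not in montage: ",
                         paste(miss, collapse = ", "))
  ang <- .angdist(mont)[, effect_sensors, drop = FALSE] * 180 / pi
  dmin <- apply(ang, 1, min)
  g <- exp(-dmin^2 / (2 * decay_deg^2))
  if (is.null(L)) return(g)
  n <- length(g)
  E <- match(effect_sensors, mont$labels)
  Fr <- setdiff(seq_len(n), E)
  Ps <- diag(as.numeric(!(seq_len(n) %in% E)))
  Q <- Ps + csd_weight * t(L) %*% Ps %*% L
  x <- numeric(n)
  x[E] <- 1
  # minimize (x-g)' Ps (x-g) + csd_weight * (Lx)' Ps (Lx) over the free
  # channels, with the effect sensors pinned at 1
  rhs <- Ps %*% g - Q[, E, drop = FALSE] %*% rep(1, length(E))
  x[Fr] <- solve(Q[Fr, Fr], rhs[Fr])
  x
}

# fixed low-rank spatial mixing for shared background sources: very smooth
# Gaussian topographies (volume-conducted far fields, which the surface
# Laplacian is designed to suppress) centered on a spread subset of sensors
.spatial_mixing <- function(mont, k) {
  n <- length(mont$labels)
  centers <- round(seq(1, n, length.out = k))
  ang <- .angdist(mont)[, centers, drop = FALSE]
  M <- exp(-ang^2 / (2 * 1.5^2))
  M / sqrt(rowSums(M^2))
}

# Mixing matrix imposing the coupling correlation structure on the
# channel-wise narrowband sources: target covariance is the identity plus
# `w` on every coupled pair. The coupling weight is the target band
# correlation between pair members; joint feasibility over the whole pair
# graph caps it at 0.95 / lambda_max(adjacency) (~0.51 for the default
# 4-pair graph, whose hub structure admits at most ~0.54 uniform
# correlation). Unit variance at every channel, exact zero correlation at
# non-coupled pairs.
.coupling_mixing <- function(labels, pairs, w) {
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  for (pr in pairs) {
    miss <- setdiff(pr, labels)
    if (length(miss)) stop("coupling pair member not in montage: ",
                           paste(miss, collapse = ", "))
    A[pr[1], pr[2]] <- A[pr[2], pr[1]] <- 1
  }
  if (w > 0 && length(pairs)) {
    lam <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    w <- min(w, 0.95 / lam)
  }
  chol(diag(n) + w * A)
}

#' Simulate multichannel EEG epochs for one participant's trial list
#'
#' One epoch per design row, spanning `[-500, 4500)` ms around test onset at
#' `sfreq` (2500 samples at 500 Hz). See [eeg_effect_spec()] for the signal
#' model.
#'
#' @param design one participant's trial list from [generate_design()].
#' @param mont a [montage()] containing all effect and coupling sensors.
#' @param spec an [eeg_effect_spec()].
#' @param sfreq sampling rate (samples/s).
#' @param t0,t1 epoch limits (ms).
#' @param test_duration test window duration (ms); with the numerosities this
#'   sets the tagging frequencies.
#' @param amp_gain per-participant ssVEP amplitude gain (drawn log-normally
#'   when `NULL`).
#' @return An [epoch_array()].
#' @export
simulate_eeg <- function(design, mont = default_montage(),
                         spec = eeg_effect_spec(), sfreq = 500,
                         t0 = -500, t1 = 4500, test_duration = 4000,
                         amp_gain = NULL) {
  stopifnot(inherits(mont, "montage"), inherits(spec, "eeg_effect_spec"))
  n_ch <- length(mont$labels)
  nsamp <- round((t1 - t0) / 1000 * sfreq)
  tt <- t0 + (seq_len(nsamp) - 1) / sfreq * 1000
  test_mask <- tt >= 0 & tt < test_duration
  f_tags <- tagging_frequency(unique(design$numerosity), test_duration)
  if (any(f_tags >= sfreq / 2))
    stop("tagging frequency at or above Nyquist (", sfreq / 2, " Hz)")
  topo <- .ssvep_topography(mont, spec$effect_sensors, spec$spatial_decay_deg,
                            L = laplacian_matrix(mont))
  Mmix <- .spatial_mixing(mont, spec$n_spatial_sources)
  if (is.null(amp_gain))
    amp_gain <- exp(stats::rnorm(1, 0, spec$participant_amp_sd))
  n_tr <- nrow(design)
  win_idx <- which(test_mask)
  n_src <- spec$n_spatial_sources
  n_pair <- length(spec$coupling_pairs)
  a <- spec$spatial_noise_share
  data <- array(0, dim = c(n_tr, n_ch, nsamp))
  # Forward field of a focal unit current source under each electrode
  # (pseudo-inverse dropping only the Laplacian's exact null mode, so the
  # analysis recovers the injected covariance with the least possible
  # distortion). Source strength follows the montage's local CSD scale
  # (the Laplacian row norm, large where electrodes are crowded), keeping
  # the source-to-background ratio uniform across the scalp; this diagonal
  # scaling leaves all source correlations untouched.
  Pfwd <- NULL
  csd_scale <- NULL
  if (spec$nb_noise_rms > 0) {
    L <- laplacian_matrix(mont)
    Pfwd <- .laplacian_pinv(L)
    csd_scale <- sqrt(rowSums(L^2))
    csd_scale <- csd_scale / exp(mean(log(csd_scale)))
  }
  # Entrained narrowband sources: one realization per numerosity, reused
  # across trials and conditions (identical test stimulus); only the mixing
  # weights depend on the adaptor condition.
  nums <- sort(unique(design$numerosity))
  nb_by_num <- lapply(nums, function(nn) {
    indiv <- .narrowband_noise(nsamp, win_idx, n_ch, sfreq,
                               tagging_frequency(nn, test_duration),
                               spec$nb_bw_sd)
    kap <- spec$nb_common_frac
    if (kap > 0) {
      # stimulus-determined component: identical for every observer of the
      # same test sequence, drawn from a numerosity-keyed stream without
      # disturbing the caller's RNG state
      rs <- get0(".Random.seed", envir = globalenv())
      set.seed(spec$nb_common_seed + nn)
      common <- .narrowband_noise(nsamp, win_idx, n_ch, sfreq,
                                  tagging_frequency(nn, test_duration),
                                  spec$nb_bw_sd, whiten = TRUE)
      if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
      indiv <- sqrt(kap) * common + sqrt(1 - kap) * indiv
    }
    spec$nb_noise_rms * indiv
  })
  names(nb_by_num) <- nums
  # simulate cell by cell: trials of one (condition x numerosity) cell share
  # the tagging frequency and the entrained narrowband sources
  cells <- split(seq_len(n_tr),
                 list(design$adaptation, design$numerosity), drop = TRUE)
  for (cell in cells) {
    cond <- design$adaptation[cell[1]]
    f_tag <- tagging_frequency(design$numerosity[cell[1]], test_duration)
    k <- length(cell)
    amp <- spec$ssvep_amp_low *
      (if (cond == "High") spec$ssvep_amp_ratio_high else 1) * amp_gain
    carrier <- cos(2 * pi * f_tag * tt / 1000) * test_mask
    locked <- outer(carrier, amp * topo)
    if (spec$nb_noise_rms > 0) {
      src <- nb_by_num[[as.character(design$numerosity[cell[1]])]]
      R <- .coupling_mixing(mont$labels, spec$coupling_pairs,
                            spec$coupling_strength[[cond]])
      # correlated CSD-space sources, mapped to scalp by the forward field
      locked <- locked + sweep(src %*% R, 2, csd_scale, "*") %*% t(Pfwd)
    }
    if (spec$noise_rms > 0) {
      ind <- .pink_noise(nsamp, n_ch * k, sfreq, spec$noise_exponent)
      lat <- .pink_noise(nsamp, n_src * k, sfreq, spec$noise_exponent)
    }
    for (j in seq_len(k)) {
      x <- locked
      if (spec$noise_rms > 0) {
        cols_i <- (j - 1) * n_ch + seq_len(n_ch)
        cols_l <- (j - 1) * n_src + seq_len(n_src)
        x <- x + spec$noise_rms *
          (sqrt(1 - a) * ind[, cols_i, drop = FALSE] +
             sqrt(a) * lat[, cols_l, drop = FALSE] %*% t(Mmix))
      }
      data[cell[j], , ] <- t(x)
    }
  }
  epoch_array(data, sfreq = sfreq, t0 = t0, labels = mont$labels,
              events = data.frame(participant = design$participant,
                                  block = design$block, trial = design$trial,
                                  adaptation = design$adaptation,
                                  numerosity = design$numerosity,
                                  stringsAsFactors = FALSE))
}

#' Simulate a full multi-participant experiment
#'
#' Convenience wrapper: per participant, generates the design, the behavioral
#' table, and (optionally) the EEG epochs. A per-participant adaptation
#' strength `lambda_p ~ Normal(1, participant_link_sd)` scales both the
#' behavioral gain separation and the EEG ssVEP High/Low ratio, so individual
#' differences in the two measures are positively coupled.
#'
#' @param config a [design_config()].
#' @param bparams a [behavior_params()].
#' @param espec an [eeg_effect_spec()]; `NULL` skips EEG simulation.
#' @param mont a [montage()].
#' @param seed RNG seed for the whole experiment.
#' @param participant_link_sd SD of the shared adaptation strength.
#' @param eeg logical; simulate EEG epochs?
#' @return list with `behavior` (all participants), `epochs` (list of
#'   [epoch_array()] per participant, or NULL), `lambda` (per-participant
#'   adaptation strengths), `amp_gain` (per-participant ssVEP gains).
#' @export
simulate_experiment <- function(config = design_config(),
                                bparams = behavior_params(),
                                espec = eeg_effect_spec(),
                                mont = default_montage(), seed = NULL,
                                participant_link_sd = 0.15, eeg = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ids <- seq_len(config$n_participants)
  lambda <- stats::setNames(pmax(0, 1 + stats::rnorm(length(ids), 0,
                                                     participant_link_sd)),
                            as.character(ids))
  behavior <- NULL
  epochs <- if (eeg) vector("list", length(ids)) else NULL
  amp_gain <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  for (p in ids) {
    des <- generate_design(config, participant = p)
    behavior <- rbind(behavior,
                      simulate_behavior(des, bparams,
                                        gain_scale = lambda[[as.character(p)]]))
    if (eeg) {
      esp <- espec
      esp$ssvep_amp_ratio_high <-
        1 + (espec$ssvep_amp_ratio_high - 1) * lambda[[as.character(p)]]
      amp_gain[[as.character(p)]] <- exp(stats::rnorm(1, 0,
                                                      espec$participant_amp_sd))
      epochs[[p]] <- simulate_eeg(des, mont, esp,
                                  test_duration = config$test_duration,
                                  amp_gain = amp_gain[[as.character(p)]])
    }
  }
  list(behavior = behavior, epochs = epochs, lambda = lambda,
       amp_gain = amp_gain)
}
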