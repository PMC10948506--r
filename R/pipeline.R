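#' Per-participant analysis pipeline
#'
#' Average-references the epochs, rejects artifactual epochs by peak-to-peak
#' threshold, and computes (i) the numerosity-averaged tagging-bin amplitude
#' per condition and channel, and (ii) the ISPC matrices per condition.
#' An optional linear-phase FIR band-pass can be applied first; the ssVEP
#' and ISPC readouts live at 3.5-5.5 Hz where the 1-40 Hz filter's gain is
#' unity, so it is off by default in the simulation pipeline.
#'
#' @param epochs one participant's [epoch_array()].
#' @param mont the matching [montage()].
#' @param fir a `fir_spec` to apply first, or `NULL`.
#' @param reref apply the average reference first? The recorded-EEG chain
#'   needs it to remove the recording reference; the synthetic generator
#'   emits reference-free potentials, for which re-referencing only mixes
#'   the focal topography's spatial mean into every channel, so the
#'   simulation pipeline disables it. The Laplacian/ISPC arm is
#'   reference-invariant either way.
#' @param reject_threshold peak-to-peak rejection threshold (uV); `Inf`
#'   disables rejection.
#' @param test_duration test window duration (ms).
#' @param ispc logical; compute the ISPC matrices?
#' @return list with `tagging` (2 x channels matrix, rows High/Low),
#'   `ispc` (list High/Low of `ispc_matrix`, or NULL),
#'   `rejected_fraction`.
#' @export
analyze_participant <- function(epochs, mont, fir = NULL, reref = TRUE,
                                reject_threshold = 150,
                                test_duration = 4000, ispc = TRUE) {
  if (!is.null(fir)) epochs <- bandpass_fir(epochs, fir)
  if (reref) epochs <- rereference_average(epochs)
  rej_frac <- 0
  if (is.finite(reject_threshold)) {
    rej <- reject_epochs(epochs, reject_threshold)
    # selective averaging needs every (condition x numerosity) cell; if the
    # threshold would empty one, keep the participant's epochs unrejected
    full <- with(epochs$events, table(adaptation, numerosity))
    kept <- with(rej$epochs$events, table(factor(adaptation,
                                                 rownames(full)),
                                          factor(numerosity,
                                                 colnames(full))))
    if (all(kept > 0)) {
      epochs <- rej$epochs
      rej_frac <- rej$rejected_fraction
    } else {
      warning("rejection would empty a design cell; keeping all epochs")
    }
  }
  list(tagging = participant_tagging_power(epochs, test_duration),
       ispc = if (ispc) participant_ispc(epochs, mont, test_duration) else NULL,
       rejected_fraction = rej_frac)
}

#' Simulate and analyze a full group-level EEG experiment
#'
#' Streams the experiment participant by participant (simulate, analyze,
#' discard the raw epochs), then runs the group-level channel-wise ssVEP
#' comparison and pair-wise ISPC comparison.
#'
#' @param config a [design_config()].
#' @param espec an [eeg_effect_spec()].
#' @param bparams a [behavior_params()].
#' @param mont a [montage()].
#' @param seed RNG seed for the run.
#' @param n_permutations,q group-test parameters.
#' @param participant_link_sd SD of the shared behavioral/EEG adaptation
#'   strength across participants.
#' @param ispc logical; run the connectivity arm?
#' @param reject_threshold passed to [analyze_participant()].
#' @return list with `ssvep` ([result_set()] by channel), `ispc`
#'   ([result_set()] by pair, or NULL), `behavior` (behavioral table),
#'   `tagging_high`/`tagging_low` (participants x channels),
#'   `rejected_fraction` (mean over participants).
#' @export
run_group_experiment <- function(config = design_config(n_blocks = 2,
                                                        trials_per_block = 40),
                                 espec = eeg_effect_spec(),
                                 bparams = behavior_params(),
                                 mont = default_montage(), seed = NULL,
                                 n_permutations = 15000, q = 0.05,
                                 participant_link_sd = 0.15, ispc = TRUE,
                                 reject_threshold = 150) {
  if (!is.null(seed)) set.seed(seed)
  # one experiment = one realization of the stimulus-determined entrained
  # component, shared by its participants
  espec$nb_common_seed <- sample.int(2^30, 1)
  np <- config$n_participants
  n_ch <- length(mont$labels)
  tag_hi <- tag_lo <- matrix(NA_real_, np, n_ch,
                             dimnames = list(NULL, mont$labels))
  mats_hi <- mats_lo <- vector("list", np)
  behavior <- NULL
  rej <- numeric(np)
  for (p in seq_len(np)) {
    lambda <- max(0, 1 + stats::rnorm(1, 0, participant_link_sd))
    esp <- espec
    esp$ssvep_amp_ratio_high <- 1 + (espec$ssvep_amp_ratio_high - 1) * lambda
    des <- generate_design(config, participant = p)
    behavior <- rbind(behavior,
                      simulate_behavior(des, bparams, gain_scale = lambda))
    ep <- simulate_eeg(des, mont, esp, test_duration = config$test_duration)
    res <- analyze_participant(ep, mont, reref = FALSE,
                               reject_threshold = reject_threshold,
                               test_duration = config$test_duration,
                               ispc = ispc)
    tag_hi[p, ] <- res$tagging["High", ]
    tag_lo[p, ] <- res$tagging["Low", ]
    if (ispc) {
      mats_hi[[p]] <- res$ispc$High
      mats_lo[[p]] <- res$ispc$Low
    }
    rej[p] <- res$rejected_fraction
  }
  list(ssvep = compare_ssvep(tag_hi, tag_lo, n_permutations = n_permutations,
                             q = q),
       ispc = if (ispc) compare_ispc(mats_hi, mats_lo,
                                     n_permutations = n_permutations, q = q),
       behavior = behavior, tagging_high = tag_hi, tagging_low = tag_lo,
       rejected_fraction = mean(rej))
}
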