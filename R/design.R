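#' Experiment design configuration
#'
#' Defaults reproduce the blocked adaptation design: 350 trials per
#' participant in 10 blocks of 35, High (64 flashes / 8 s, ~8 Hz) or Low
#' (16 flashes / 8 s, ~2 Hz) adaptor constant within a block, test sequences
#' of 14/16/18/20/22 flashes over 4 s (~3.5-5.5 Hz), 1000 ms ISI, 40 ms
#' flashes, and +/-15% jitter of the inter-flash interval. Half the
#' participants start with five High blocks, half with five Low blocks.
#'
#' A reduced profile for desk-scale EEG simulation uses `n_blocks = 2`,
#' `trials_per_block = 40` (8 trials per condition x numerosity cell).
#'
#' @param n_participants number of participants.
#' @param n_blocks blocks per participant (condition constant within block).
#' @param trials_per_block trials per block; must be divisible by the number
#'   of test numerosities.
#' @param test_numerosities test flash counts.
#' @param test_duration test sequence duration (ms).
#' @param adaptor_high_n,adaptor_low_n adaptor flash counts.
#' @param adaptor_duration adaptor sequence duration (ms).
#' @param isi adaptor-test interval (ms).
#' @param flash_duration single flash duration (ms).
#' @param jitter_fraction jitter of each inter-flash interval as a fraction of
#'   the nominal interval; in `[0, 0.5)`.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_participants = 16, n_blocks = 10,
                          trials_per_block = 35,
                          test_numerosities = c(14, 16, 18, 20, 22),
                          test_duration = 4000,
                          adaptor_high_n = 64, adaptor_low_n = 16,
                          adaptor_duration = 8000, isi = 1000,
                          flash_duration = 40, jitter_fraction = 0.15) {
  cfg <- list(n_participants = n_participants, n_blocks = n_blocks,
              trials_per_block = trials_per_block,
              test_numerosities = sort(test_numerosities),
              test_duration = test_duration,
              adaptor_high_n = adaptor_high_n, adaptor_low_n = adaptor_low_n,
              adaptor_duration = adaptor_duration, isi = isi,
              flash_duration = flash_duration,
              jitter_fraction = jitter_fraction)
  if (n_participants < 1 || n_blocks < 2 || n_blocks %% 2 != 0)
    stop("need >= 1 participant and an even number of blocks")
  if (trials_per_block %% length(test_numerosities) != 0)
    stop("trials_per_block (", trials_per_block,
         ") not divisible by the number of numerosities (",
         length(test_numerosities), ")")
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop("jitter_fraction must be in [0, 0.5)")
  structure(cfg, class = "design_config")
}

#' Jittered flash-onset times of one stimulus sequence
#'
#' `n` flashes are evenly distributed over `duration` ms and each onset is
#' jittered so every inter-onset interval stays within
#' `nominal * (1 +/- jitter_fraction)`, where `nominal = duration / n`.
#' The first onset is at (or jittered slightly after) 0 and the last flash
#' ends before `duration`.
#'
#' @param n number of flashes (>= 1).
#' @param duration sequence duration (ms).
#' @param jitter_fraction jitter bound, in `[0, 0.5)`.
#' @param flash_duration flash duration (ms), used for the overlap check.
#' @return Strictly increasing onset times (ms) in `[0, duration)`.
#' @export
generate_flash_onsets <- function(n, duration, jitter_fraction = 0.15,
                                  flash_duration = 40) {
  if (n < 1 || duration <= 0) stop("need n >= 1 and duration > 0")
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop("jitter_fraction must be in [0, 0.5)")
  nominal <- duration / n
  if (n * flash_duration > duration)
    stop("flashes would overlap: n * flash_duration (", n * flash_duration,
         " ms) exceeds duration (", duration, " ms)")
  if (nominal * (1 - jitter_fraction / 2) < flash_duration)
    stop("jittered flashes could overlap the sequence end")
  half <- jitter_fraction * nominal / 2
  # first onset shifted only forward so it stays >= 0; every inter-onset
  # interval is then within nominal * (1 +/- jitter_fraction)
  delta <- c(stats::runif(1, 0, half),
             if (n > 1) stats::runif(n - 1, -half, half))
  (seq_len(n) - 1) * nominal + delta
}

#' Generate one participant's ordered trial list
#'
#' 10 blocks of 35 trials with defaults; adaptation condition constant within
#' block and counterbalanced over participants (even participant index starts
#' with High blocks, odd with Low); numerosity order randomized within block
#' with equal counts per (condition x numerosity) cell.
#'
#' @param config a [design_config()].
#' @param participant integer participant id.
#' @param seed optional seed for the within-block shuffles.
#' @return data.frame with columns `participant`, `block`, `trial` (within
#'   block), `adaptation`, `numerosity`.
#' @export
generate_design <- function(config = design_config(), participant = 0,
                            seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  nums <- config$test_numerosities
  per_block <- config$trials_per_block / length(nums)
  first <- if (participant %% 2 == 0) "High" else "Low"
  second <- setdiff(c("High", "Low"), first)
  block_cond <- rep(c(first, second), each = config$n_blocks / 2)
  rows <- lapply(seq_len(config$n_blocks), function(b) {
    data.frame(participant = participant, block = b,
               trial = seq_len(config$trials_per_block),
               adaptation = block_cond[b],
               numerosity = sample(rep(nums, each = per_block)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tagging frequency of a test sequence
#'
#' `n` flashes over `duration` ms tag the EEG at `n / (duration/1000)` Hz
#' (3.5-5.5 Hz for 14-22 flashes over 4 s).
#'
#' @param numerosity flash count.
#' @param duration sequence duration (ms).
#' @return Frequency in Hz.
#' @export
tagging_frequency <- function(numerosity, duration = 4000) {
  numerosity / (duration / 1000)
}
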