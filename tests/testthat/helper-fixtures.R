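# shared fixture builders (everything generated in code)

# minimal epoch array: deterministic values, arbitrary window
make_epochs <- function(n_trials = 2, n_ch = 3, n_samp = 100, sfreq = 500,
                        t0 = -100, data = NULL,
                        adaptation = rep(c("High", "Low"),
                                         length.out = n_trials),
                        numerosity = rep(16, n_trials)) {
  if (is.null(data))
    data <- array(seq_len(n_trials * n_ch * n_samp) / 1000,
                  dim = c(n_trials, n_ch, n_samp))
  epoch_array(data, sfreq = sfreq, t0 = t0,
              labels = paste0("ch", seq_len(n_ch)),
              events = data.frame(participant = 1,
                                  block = 1,
                                  trial = seq_len(n_trials),
                                  adaptation = adaptation,
                                  numerosity = numerosity))
}

# one-participant epoch array holding a pure sinusoid on every channel
make_tone_epochs <- function(freq, amp = 1, n_ch = 2, sfreq = 500,
                             t0 = -500, t1 = 4500, window = c(0, 4000),
                             n_trials = 1, numerosity = 16,
                             adaptation = rep("Low", n_trials)) {
  n_samp <- round((t1 - t0) / 1000 * sfreq)
  tt <- t0 + (seq_len(n_samp) - 1) / sfreq * 1000
  x <- amp * cos(2 * pi * freq * tt / 1000) *
    (tt >= window[1] & tt < window[2])
  data <- array(rep(x, each = n_trials * n_ch),
                dim = c(n_trials, n_ch, n_samp))
  make_epochs(n_trials, n_ch, n_samp, sfreq, t0, data,
              adaptation = adaptation,
              numerosity = rep(numerosity, n_trials))
}

# evoked wrapper around a channels x samples matrix
make_evoked <- function(data, sfreq = 500, t0 = -500,
                        labels = paste0("ch", seq_len(nrow(data)))) {
  structure(list(data = data, sfreq = sfreq, t0 = t0, labels = labels,
                 condition = "Low", numerosities = 16, n_trials = 1),
            class = "evoked")
}

# reduced design profile used for EEG simulation tests
reduced_design <- function(n_participants = 16) {
  design_config(n_participants = n_participants, n_blocks = 2,
                trials_per_block = 40)
}

default_pairs <- c("C3-CP5", "CP5-CP6", "CP5-POz", "C3-PO7")
default_sensors <- c("POz", "O2", "C3", "Cz")
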