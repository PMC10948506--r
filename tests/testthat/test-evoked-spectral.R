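test_that("ERP averaging, numerosity-22 exclusion and baseline removal", {
  n_samp <- 2500
  tt <- -500 + (seq_len(n_samp) - 1) * 2
  template <- 5 * exp(-((tt - 100) / 50)^2)
  n_tr <- 5
  data <- array(rep(template, each = n_tr * 2), c(n_tr, 2, n_samp))
  data[5, , ] <- 999   # numerosity-22 trial must not contaminate the ERP
  ep <- make_epochs(n_tr, 2, n_samp, t0 = -500, data = data,
                    adaptation = rep("High", n_tr),
                    numerosity = c(14, 16, 18, 20, 22))
  erp <- compute_erp(ep, "High")
  expect_equal(ncol(erp$data), 150)
  base_idx <- which(epoch_times(erp) < 0)
  expect_lt(max(abs(rowMeans(erp$data[, base_idx]))), 1e-9)
  # equals baseline-corrected template on [-100, 200)
  sel <- tt >= -100 & tt < 200
  expected <- template[sel] - mean(template[tt >= -100 & tt < 0])
  expect_equal(erp$data[1, ], expected, ignore_attr = TRUE)
  expect_error(compute_erp(ep, "Low"), "no trials")
})

test_that("cluster timecourse is the unweighted channel mean", {
  ev <- make_evoked(matrix(rep(c(2, -2, 0, 0, 0, 0, 0), 10), 7, 10),
                    labels = paste0("e", 1:7))
  expect_equal(cluster_timecourse(ev, paste0("e", 1:7)), rep(0, 10))
  ev2 <- make_evoked(matrix(3.3, 7, 4), labels = paste0("e", 1:7))
  expect_equal(cluster_timecourse(ev2, paste0("e", 1:7)), rep(3.3, 4))
  expect_error(cluster_timecourse(ev, c("e1", "zz")), "zz")
})

test_that("fft_amplitude satisfies the Fourier identities", {
  ev <- make_evoked(rbind(cos(2 * pi * 4 * (0:2499) / 500),
                          rep(3, 2500)), t0 = -500)
  # window [0, 4000) = samples 251..2250
  sp <- fft_amplitude(ev)
  expect_equal(sp$df, 0.25)
  b4 <- which(abs(sp$freqs - 4) < 1e-9)
  expect_equal(b4, 17L)   # bin index 16 counting from 0 at DC
  expect_lt(abs(sp$amplitude[1, b4] - 1), 1e-9)
  expect_lt(max(sp$amplitude[1, -b4]), 1e-9)
  # constant input: all in the DC bin
  expect_equal(unname(sp$amplitude[2, 1]), 3, tolerance = 1e-12)
  expect_lt(max(sp$amplitude[2, -1]), 1e-9)
})

test_that("tagging-bin amplitude is invariant to orthogonal-bin tones", {
  tt <- (-500 + (0:2499) * 2) / 1000
  x <- cos(2 * pi * 4 * tt)
  y <- x + 2.5 * cos(2 * pi * 7.25 * tt + 1) + 0.7 * sin(2 * pi * 11 * tt)
  sp <- fft_amplitude(make_evoked(rbind(x, y), t0 = -500))
  b4 <- which(abs(sp$freqs - 4) < 1e-9)
  expect_equal(unname(sp$amplitude[1, b4]), unname(sp$amplitude[2, b4]),
               tolerance = 1e-9)
})

test_that("Parseval holds under the single-sided normalization", {
  set.seed(5)
  x <- rnorm(2500)
  ev <- make_evoked(matrix(x, 1), t0 = -500)
  sp <- fft_amplitude(ev)
  idx <- .window_idx(ev, 0, 4000)
  n <- length(idx)
  # amplitude a_k = 2|X_k|/n (k>0), a_0 = |X_0|/n; Nyquist bin also halved
  a <- sp$amplitude[1, ]
  nyq <- length(a)
  power <- a[1]^2 + sum(a[2:(nyq - 1)]^2) / 2 + a[nyq]^2 / 4
  expect_equal(power, mean(x[idx]^2), tolerance = 1e-6)
})

test_that("fft window must lie inside the epoch and tagging bins must be exact", {
  ev <- make_evoked(matrix(0, 1, 500), t0 = 0)   # only [0, 1000) ms
  expect_error(fft_amplitude(ev), "not fully inside")
  sp <- fft_amplitude(make_evoked(matrix(1, 1, 2500), t0 = -500))
  # a 3-s test window would put 14 flashes at 14/3 Hz, off the 0.25 Hz grid
  expect_error(tagging_power(list(`14` = sp), 14, test_duration = 3000),
               "not an exact multiple")
})

test_that("tagging_power extracts the per-numerosity bins and averages", {
  tt <- (-500 + (0:2499) * 2) / 1000
  spectra <- lapply(c(14, 16, 18, 20, 22), function(nn) {
    f <- nn / 4
    fft_amplitude(make_evoked(matrix(cos(2 * pi * f * tt), 1), t0 = -500))
  })
  names(spectra) <- c(14, 16, 18, 20, 22)
  tp <- tagging_power(spectra)
  expect_equal(as.numeric(tp$per_numerosity), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(tp$average), 1, tolerance = 1e-9)
  # numerosity-18 tagging bin sits at 4.5 Hz = bin index 18 (0-based)
  sp18 <- spectra[["18"]]
  expect_equal(which(abs(sp18$freqs - 4.5) < 1e-9) - 1L, 18L)
})

test_that("noise-free condition-amplitude ratio is recovered exactly", {
  des <- generate_design(design_config(n_blocks = 2, trials_per_block = 10),
                         participant = 1, seed = 7)
  esp <- eeg_effect_spec(noise_rms = 0, nb_noise_rms = 0,
                         participant_amp_sd = 0)
  ep <- simulate_eeg(des, default_montage(), esp, amp_gain = 1)
  tp <- participant_tagging_power(ep)
  for (s in default_sensors)
    expect_equal(tp["High", s] / tp["Low", s], 1.3, tolerance = 1e-6)
})

test_that("compare_ssvep returns an empty mask under the exact null and flags a saturated effect", {
  set.seed(8)
  base <- matrix(rexp(12 * 30), 12, 30,
                 dimnames = list(NULL, paste0("c", 1:30)))
  res <- compare_ssvep(base, base, n_permutations = 500, seed = 1)
  expect_false(any(res$significant))
  expect_true(all(res$p == 1))
  shifted <- base
  shifted[, 1:4] <- shifted[, 1:4] + 5
  res2 <- compare_ssvep(shifted, base, n_permutations = 2000, seed = 1)
  expect_identical(sort(res2$names[res2$significant]),
                   sort(paste0("c", 1:4)))
  expect_error(compare_ssvep(base[1, , drop = FALSE], base[1, , drop = FALSE]),
               ">= 2 participants")
})

test_that("channel-wise false-positive rate under a null generator stays near alpha", {
  set.seed(9)
  # summary-level null: per-participant tagging amplitudes with no condition
  # effect, 500 replicate experiments x 30 channels in one vectorized call
  n <- 12
  reps <- 500
  a <- matrix(rnorm(n * reps, mean = 2), n, reps)
  b <- matrix(rnorm(n * reps, mean = 2), n, reps)
  pt <- paired_permutation_test(a, b, n_permutations = 2000, seed = 10)
  expect_gt(mean(pt$p <= 0.05), 0.030)
  expect_lt(mean(pt$p <= 0.05), 0.070)
})

test_that("compare_erp flags nothing under the null and everything under a constant shift", {
  set.seed(10)
  base <- matrix(rnorm(8 * 150), 8, 150)
  res <- compare_erp(base, base, n_permutations = 300, seed = 2)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
  res2 <- compare_erp(base + 5, base, n_permutations = 2000, seed = 2)
  expect_true(all(res2$significant))
})
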