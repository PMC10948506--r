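mont30 <- default_montage()

test_that("the surface Laplacian kills constants and is linear", {
  L <- laplacian_matrix(mont30)
  expect_lt(max(abs(L %*% rep(7.7, 30))), 1e-6)
  set.seed(1)
  v <- rnorm(30)
  expect_equal(L %*% (7 * v), 7 * (L %*% v), tolerance = 1e-9)
  # via the epoch interface
  data <- array(rep(1, 30 * 10), c(1, 30, 10))
  ep <- epoch_array(data, 500, 0, mont30$labels,
                    data.frame(participant = 1, block = 1, trial = 1,
                               adaptation = "Low", numerosity = 16))
  out <- surface_laplacian(ep, mont30)
  expect_lt(max(abs(out$data)), 1e-6)
})

test_that("the Laplacian decorrelates a volume-conducted low-rank field", {
  set.seed(2)
  K <- 4
  src <- matrix(rnorm(500 * K), 500, K)
  centers <- c(5, 13, 21, 26)
  topo <- exp(-(.angdist(mont30)[, centers]^2) / (2 * 0.9^2))
  X <- src %*% t(topo) + 0.1 * matrix(rnorm(500 * 30), 500, 30)
  L <- laplacian_matrix(mont30)
  XL <- X %*% t(L)
  cor_pre <- mean(abs(stats::cor(X)[upper.tri(diag(30))]))
  cor_post <- mean(abs(stats::cor(XL)[upper.tri(diag(30))]))
  expect_lt(cor_post, cor_pre)
})

test_that("duplicate sensor positions are rejected", {
  m <- montage(c("a", "b", "c", "d", "e", "f", "g", "h"),
               rbind(diag(3), -diag(3), c(1, 1, 1) / sqrt(3),
                     c(1, 0, 0)))
  expect_error(laplacian_matrix(m), "duplicate")
})

test_that("narrowband phase extraction satisfies the analytic-signal identities", {
  sfreq <- 500
  tt <- -500 + (0:2499) * 2
  x <- cos(2 * pi * 4 * tt / 1000)
  ev <- make_evoked(rbind(x, x))
  an <- narrowband_phase(ev, 4)
  expect_true(all(an$phase > -pi - 1e-12 & an$phase <= pi + 1e-12))
  v <- which(an$valid)
  # valid mask excludes >= 500 ms at each end of the test window
  expect_true(min(epoch_times(ev)[v]) >= 500)
  expect_true(max(epoch_times(ev)[v]) < 3500)
  unwrapped <- cumsum(c(an$phase[1, v][1],
                        ((diff(an$phase[1, v]) + pi) %% (2 * pi)) - pi))
  inst_f <- diff(unwrapped) * sfreq / (2 * pi)
  expect_true(all(abs(inst_f - 4) < 0.05))
  env <- an$envelope[1, v]
  expect_lt(diff(range(env)) / mean(env), 0.01)
})

test_that("an out-of-band tone is strongly attenuated in the envelope", {
  tt <- -500 + (0:2499) * 2
  x4 <- cos(2 * pi * 4 * tt / 1000)
  x10 <- cos(2 * pi * 10 * tt / 1000)
  v <- NULL
  # at the default half-bandwidth (2 Hz) the forward-backward 2nd-order
  # response puts a 10 Hz tone ~14 dB down; at a 0.5 Hz half-bandwidth the
  # same tone is > 20 dB down
  for (cfg in list(list(hb = 2, db = 13), list(hb = 0.5, db = 20))) {
    an4 <- narrowband_phase(make_evoked(rbind(x4)), 4, half_bw = cfg$hb)
    anmix <- narrowband_phase(make_evoked(rbind(x4 + x10)), 4,
                              half_bw = cfg$hb)
    v <- which(an4$valid)
    resid <- anmix$envelope[1, v] - an4$envelope[1, v]
    expect_lt(sqrt(mean(resid^2)), 10^(-cfg$db / 20) * sqrt(0.5))
  }
})

test_that("band edges must stay inside (0, Nyquist)", {
  ev <- make_evoked(matrix(0, 1, 2500))
  expect_error(narrowband_phase(ev, 1, half_bw = 1.5), "outside")
  expect_error(narrowband_phase(ev, 260), "outside")
})

test_that("ispc closed-form identities", {
  set.seed(3)
  phi <- runif(2000, -pi, pi)
  expect_equal(ispc(phi, phi), 1)
  expect_equal(ispc(phi, phi - 0.7), 1, tolerance = 1e-12)
  expect_equal(ispc(phi, phi + 2), ispc(phi + 2, phi))   # symmetry
  expect_error(ispc(phi, phi, valid = rep(FALSE, 2000)), "empty")
  expect_error(ispc(phi[1:50], phi[1:50]), "fewer than")
  expect_error(ispc(phi, phi[1:100]), "lengths differ")
})

test_that("mean ISPC of independent uniform phases matches the Rayleigh resultant", {
  set.seed(4)
  T <- 2000
  reps <- 1000
  vals <- replicate(reps, ispc(runif(T, -pi, pi), runif(T, -pi, pi)))
  # E R = sqrt(pi)/2 / sqrt(T) ~ 0.886/sqrt(T); SE of the mean ~ 0.0002
  expect_equal(mean(vals), 0.886 / sqrt(T), tolerance = 0.02)
})

test_that("ispc_matrix is symmetric with unit diagonal, in [0,1], and equals the numerosity mean", {
  set.seed(5)
  cfg <- design_config(n_blocks = 2, trials_per_block = 10)
  des <- generate_design(cfg, participant = 1)
  ep <- simulate_eeg(des, mont30, eeg_effect_spec(), amp_gain = 1)
  m <- ispc_matrix(ep, "High", mont30)
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), rep(1, 30), ignore_attr = TRUE)
  expect_true(all(m$values >= 0 & m$values <= 1))
  # numerosity-average = arithmetic mean of the per-numerosity matrices
  per_num <- lapply(c(14, 16, 18, 20, 22), function(nn)
    ispc_matrix(subset_epochs(ep, ep$events$numerosity == nn),
                "High", mont30, numerosities = nn)$values)
  avg <- Reduce(`+`, per_num) / 5
  diag(avg) <- 1
  expect_equal(m$values, avg, tolerance = 1e-12)
  expect_error(ispc_matrix(subset_epochs(ep, ep$events$numerosity != 14),
                           "High", mont30), "missing")
})

test_that("the Laplacian+ISPC pipeline is invariant to global amplitude rescaling", {
  set.seed(6)
  cfg <- design_config(n_blocks = 2, trials_per_block = 10)
  des <- generate_design(cfg, participant = 2)
  ep <- simulate_eeg(des, mont30, eeg_effect_spec(), amp_gain = 1)
  m1 <- ispc_matrix(ep, "Low", mont30)
  ep$data <- ep$data * 13.7
  m2 <- ispc_matrix(ep, "Low", mont30)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("injected coupling raises High over Low ISPC at every injected pair", {
  # single-participant ISPC estimates carry ~0.1 sampling noise, so the
  # generator ground truth is checked on a small participant average
  set.seed(7)
  pairs <- list(c("C3", "CP5"), c("CP5", "CP6"), c("CP5", "POz"),
                c("C3", "PO7"))
  esp <- eeg_effect_spec()
  esp$nb_common_seed <- 91L
  D <- sapply(1:5, function(p) {
    des <- generate_design(reduced_design(), participant = p)
    ep <- simulate_eeg(des, mont30, esp, amp_gain = 1)
    im <- participant_ispc(ep, mont30)
    sapply(pairs, function(pr) im$High$values[pr[1], pr[2]] -
             im$Low$values[pr[1], pr[2]])
  })
  expect_true(all(rowMeans(D) > 0))        # each injected pair separates
  expect_gt(mean(D), 0.05)                 # and clearly so on average
})

test_that("compare_ispc finds nothing when High and Low matrices are identical", {
  set.seed(8)
  mk <- function() {
    v <- matrix(runif(900), 30, 30)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    structure(list(values = v, condition = "High", numerosities = 14:18,
                   labels = mont30$labels), class = "ispc_matrix")
  }
  mats <- replicate(6, mk(), simplify = FALSE)
  res <- compare_ispc(mats, mats, n_permutations = 300, seed = 3)
  expect_false(any(res$significant))
  expect_length(res$p, 435)
  expect_error(compare_ispc(mats[1], mats[1]), ">= 2 participants")
})

test_that("equal coupling strengths leave paired ISPC differences centered on zero", {
  set.seed(9)
  esp <- eeg_effect_spec(coupling_strength = c(High = 0.4, Low = 0.4))
  cfg <- design_config(n_blocks = 2, trials_per_block = 10)
  diffs <- replicate(6, {
    des <- generate_design(cfg, participant = sample.int(100, 1))
    ep <- simulate_eeg(des, mont30, esp, amp_gain = 1)
    im <- participant_ispc(ep, mont30)
    mean(sapply(list(c("C3", "CP5"), c("CP5", "CP6"), c("CP5", "POz"),
                     c("C3", "PO7")),
                function(pr) im$High$values[pr[1], pr[2]] -
                  im$Low$values[pr[1], pr[2]]))
  })
  expect_lt(abs(mean(diffs)), 0.1)
})
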