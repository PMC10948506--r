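test_that("paired permutation p is 1 for identical conditions", {
  a <- matrix(1:12, 4, 3)
  pt <- paired_permutation_test(a, a, n_permutations = 100, seed = 1)
  expect_equal(pt$p, rep(1, 3))
  expect_equal(pt$statistic, rep(0, 3))
})

test_that("Monte-Carlo p matches the exhaustive 2^5 enumeration at n = 5", {
  set.seed(2)
  a <- matrix(rnorm(5 * 4, mean = 0.8), 5, 4)
  b <- matrix(rnorm(5 * 4), 5, 4)
  # exhaustive path (2^5 = 32 <= n_permutations)
  ex <- paired_permutation_test(a, b, n_permutations = 1000, seed = 3)
  expect_true(ex$exhaustive)
  # independent brute-force enumeration of all sign flips
  D <- a - b
  brute <- sapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    t_obs <- mean(d) / (sd(d) / sqrt(5))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
    tperm <- apply(signs, 1, function(s) {
      ds <- s * d
      mean(ds) / (sd(ds) / sqrt(5))
    })
    mean(abs(tperm) >= abs(t_obs) - 1e-10)
  })
  expect_equal(ex$p, brute, tolerance = 1e-12)
  # Monte-Carlo (force by lowering n_permutations below 32): within 2 SE
  mc <- paired_permutation_test(a, b, n_permutations = 20, seed = 4)
  expect_false(mc$exhaustive)
  se <- sqrt(brute * (1 - brute) / 20)
  expect_true(all(abs(mc$p - brute) <= 2 * se + 2 / 21))
})

test_that("permutation p values are invariant to a common additive constant", {
  set.seed(5)
  a <- matrix(rnorm(8 * 3), 8, 3)
  b <- matrix(rnorm(8 * 3), 8, 3)
  p1 <- paired_permutation_test(a, b, n_permutations = 500, seed = 6)$p
  p2 <- paired_permutation_test(a + 3.2, b + 3.2, n_permutations = 500,
                                seed = 6)$p
  expect_equal(p1, p2)
})

test_that("type-I error of the permutation test is near nominal", {
  set.seed(7)
  n <- 10
  reps <- 1000
  a <- matrix(rnorm(n * reps), n, reps)
  b <- matrix(rnorm(n * reps), n, reps)
  pt <- paired_permutation_test(a, b, n_permutations = 2000, seed = 8)
  rate <- mean(pt$p <= 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("BH adjustment matches hand computation and brute force", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(res$p_adjusted, rep(0.04, 4))
  expect_true(all(res$significant))
  # brute-force definition min_{j >= i} m p_(j) / j capped at 1
  set.seed(9)
  for (r in 1:200) {
    p <- runif(30)^2
    got <- fdr_bh(p)$p_adjusted
    o <- order(p)
    m <- length(p)
    brute <- sapply(seq_len(m), function(i)
      min(1, min(m * p[o][i:m] / (i:m))))
    expect_equal(got[o], brute, tolerance = 1e-12)
  }
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("BH significant set is monotone when p values decrease", {
  set.seed(10)
  p <- runif(20)
  s1 <- fdr_bh(p, q = 0.1)$significant
  p2 <- p
  p2[7] <- p2[7] / 10
  s2 <- fdr_bh(p2, q = 0.1)$significant
  expect_true(all(s2[s1]))
})

test_that("two-level factors have epsilon 1 and F equal to the squared paired t", {
  set.seed(11)
  s <- 10
  Y <- matrix(rnorm(s * 10), s, 10)
  tab <- expand.grid(participant = 1:s, adaptation = c("High", "Low"),
                     numerosity = c(14, 16, 18, 20, 22))
  tab$value <- as.vector(Y)
  res <- rm_anova_gg(tab)
  expect_equal(res["Adaptation", "epsilon"], 1)
  # marginal means per condition
  agg <- aggregate(value ~ participant + adaptation, tab, mean)
  wide <- reshape(agg, idvar = "participant", timevar = "adaptation",
                  direction = "wide")
  tt <- t.test(wide$value.High, wide$value.Low, paired = TRUE)
  expect_equal(res["Adaptation", "F"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(res["Adaptation", "p_uncorrected"], tt$p.value,
               tolerance = 1e-9)
})

test_that("compound-symmetric data give epsilon near 1", {
  set.seed(12)
  s <- 200
  subj <- rnorm(s, sd = 2)
  Y <- outer(subj, rep(1, 10)) + matrix(rnorm(s * 10), s, 10)
  tab <- expand.grid(participant = 1:s, adaptation = c("High", "Low"),
                     numerosity = c(14, 16, 18, 20, 22))
  tab$value <- as.vector(Y)
  res <- rm_anova_gg(tab)
  expect_gt(res["Numerosity", "epsilon"], 0.9)
})

test_that("rm_anova_gg matches car's multivariate repeated-measures machinery", {
  skip_if_not_installed("car")
  set.seed(13)
  for (r in 1:5) {
    s <- 8 + r
    Y <- matrix(rnorm(s * 10), s, 10)
    tab <- expand.grid(participant = 1:s, adaptation = c("A1", "A2"),
                       numerosity = c(14, 16, 18, 20, 22))
    tab$value <- as.vector(Y)
    res <- rm_anova_gg(tab)
    idata <- expand.grid(adaptation = factor(c("A1", "A2")),
                         numerosity = factor(c(14, 16, 18, 20, 22)))
    aa <- car::Anova(lm(Y ~ 1), idata = idata,
                     idesign = ~ adaptation * numerosity, type = 3)
    sm <- suppressWarnings(summary(aa, multivariate = FALSE))
    uv <- sm$univariate.tests
    expect_equal(res["Adaptation", "F"], uv["adaptation", "F value"],
                 tolerance = 1e-6)
    expect_equal(res["Numerosity", "F"], uv["numerosity", "F value"],
                 tolerance = 1e-6)
    expect_equal(res["Adaptation:Numerosity", "F"],
                 uv["adaptation:numerosity", "F value"], tolerance = 1e-6)
    pv <- sm$pval.adjustments
    expect_equal(res["Numerosity", "epsilon"],
                 unname(pv["numerosity", "GG eps"]), tolerance = 1e-6)
    expect_equal(res["Numerosity", "p"],
                 unname(pv["numerosity", "Pr(>F[GG])"]), tolerance = 1e-6)
    expect_equal(res["Adaptation:Numerosity", "epsilon"],
                 unname(pv["adaptation:numerosity", "GG eps"]),
                 tolerance = 1e-6)
  }
})

test_that("rm_anova_gg rejects incomplete tables", {
  tab <- expand.grid(participant = 1:4, adaptation = c("High", "Low"),
                     numerosity = c(14, 16))
  tab$value <- rnorm(nrow(tab))
  expect_error(rm_anova_gg(tab[-1, ]), "missing cell")
})

test_that("Bonferroni post-hocs multiply by the number of comparisons and cap at 1", {
  set.seed(14)
  tab <- expand.grid(participant = 1:10, adaptation = c("High", "Low"),
                     numerosity = c(14, 16, 18, 20, 22))
  tab$value <- rnorm(nrow(tab)) +
    ifelse(tab$adaptation == "High", -1, 1) * 0
  ph <- bonferroni_posthoc(tab)
  expect_equal(nrow(ph), 5)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 5))
  # one comparison: adjusted = raw
  one <- bonferroni_posthoc(tab[tab$numerosity == 14, ])
  expect_equal(one$p_adjusted, one$p_raw)
})

test_that("default behavioral generator yields adjusted post-hoc ps < 0.001 at every numerosity", {
  set.seed(42)
  beh <- NULL
  for (p in 1:16) {
    des <- generate_design(design_config(), participant = p)
    beh <- rbind(beh, simulate_behavior(des))
  }
  cells <- aggregate(estimate ~ participant + adaptation + true_numerosity,
                     beh, mean)
  names(cells)[3:4] <- c("numerosity", "value")
  ph <- bonferroni_posthoc(cells)
  expect_true(all(ph$p_adjusted < 0.001))
})

test_that("Spearman correlation identities and oracle agreement", {
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  res <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman_correlation(x, y)$rho,
               -spearman_correlation(x, -y)$rho)
  or <- cor.test(x, y, method = "spearman", exact = FALSE)
  got <- spearman_correlation(x, y)
  expect_equal(got$rho, unname(or$estimate))
  expect_equal(got$p, or$p.value, tolerance = 1e-9)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_correlation(1:3, 1:3), ">= 4")
})
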