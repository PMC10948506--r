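#' Paired sign-flip permutation test
#'
#' Two-sided permutation test for paired two-condition data. The statistic is
#' the paired t on the within-participant differences; the null distribution
#' is built by randomly sign-flipping each participant's difference vector
#' (equivalent to exchanging the condition labels within participant). When
#' `2^n <= n_permutations` all sign patterns are enumerated exhaustively and
#' the p value is the exact proportion `#{|t_perm| >= |t_obs|} / 2^n`;
#' otherwise Monte-Carlo sampling with the convention
#' `p = (1 + #{|t_perm| >= |t_obs|}) / (n_permutations + 1)`, so p is never 0.
#'
#' Multiple features (channels, pairs, time samples) are tested in one
#' vectorized call sharing the same sign flips, as in channel-wise EEG
#' permutation testing.
#'
#' @param a,b participants x features matrices (or vectors),
#'   participant-paired by row.
#' @param n_permutations number of permutations for Monte-Carlo sampling.
#' @param seed optional RNG seed.
#' @return list with `statistic` (paired t per feature), `p` (raw two-sided
#'   p per feature), and `exhaustive` (logical).
#' @export
paired_permutation_test <- function(a, b, n_permutations = 15000,
                                    seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("paired inputs must have equal dimensions")
  if (anyNA(a) || anyNA(b))
    stop("missing condition value for some participant")
  n <- nrow(a)
  if (n < 2) stop("need >= 2 participants")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  D <- a - b
  tstat_of <- function(S) {
    # S: perms x participants sign matrix -> perms x features t matrix
    m <- (S %*% D) / n
    ss <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
    v <- (ss - n * m^2) / (n - 1)
    out <- m / sqrt(v / n)
    out[v <= 0] <- ifelse(abs(m[v <= 0]) > 0, Inf, 0)
    out
  }
  t_obs <- as.numeric(tstat_of(matrix(1, 1, n)))
  exhaustive <- n <= 30 && 2^n <= n_permutations
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    storage.mode(S) <- "double"
    Tp <- abs(tstat_of(S))
    thr <- abs(t_obs) * (1 - 1e-12) - 1e-12
    p <- colMeans(sweep(Tp, 2, thr, ">="))
  } else {
    S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                n_permutations, n)
    Tp <- abs(tstat_of(S))
    thr <- abs(t_obs) * (1 - 1e-12) - 1e-12
    p <- (1 + colSums(sweep(Tp, 2, thr, ">="))) / (n_permutations + 1)
  }
  list(statistic = t_obs, p = pmin(p, 1), exhaustive = exhaustive)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values `p_adj(i) = min_{j >= i} min(1, m p_(j) / j)`
#' (sorted scale) with enforced monotonicity; the significance mask is
#' `p_adj <= q`.
#'
#' @param p raw p values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `p_adjusted` and logical `significant`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  padj_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  p_adjusted <- numeric(m)
  p_adjusted[o] <- padj_sorted
  list(p_adjusted = p_adjusted, significant = p_adjusted <= q)
}

# orthonormal contrast basis with k-1 columns
.ortho_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

# Greenhouse-Geisser epsilon from the covariance of contrast scores
.gg_epsilon <- function(Z) {
  S <- stats::cov(Z)
  k1 <- ncol(Z)
  sum(diag(S))^2 / (k1 * sum(S^2))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subjects 2 (Adaptation) x 5 (Numerosity) decomposition on
#' per-participant cell means. For each multi-level effect the
#' Greenhouse-Geisser epsilon is estimated from the covariance of the
#' orthonormal contrast scores, `eps = tr(S)^2 / ((k-1) tr(S^2))`, and the
#' corrected p value uses `(eps df1, eps df2)`; reported degrees of freedom
#' stay uncorrected. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error stratum.
#'
#' @param table long data.frame with columns `participant`, `adaptation`,
#'   `numerosity`, `value` (one value per cell per participant).
#' @return data.frame with one row per effect (`Adaptation`, `Numerosity`,
#'   `Adaptation:Numerosity`): `F`, `df1`, `df2`, `epsilon`, `p` (GG
#'   corrected), `p_uncorrected`, `eta_p2`.
#' @export
rm_anova_gg <- function(table) {
  req <- c("participant", "adaptation", "numerosity", "value")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("table missing column(s): ", paste(miss, collapse = ", "))
  subj <- sort(unique(table$participant))
  alev <- sort(unique(table$adaptation))
  blev <- sort(unique(table$numerosity))
  s <- length(subj); a <- length(alev); b <- length(blev)
  Y <- array(NA_real_, dim = c(s, a, b))
  for (r in seq_len(nrow(table))) {
    Y[match(table$participant[r], subj), match(table$adaptation[r], alev),
      match(table$numerosity[r], blev)] <- table$value[r]
  }
  if (anyNA(Y)) stop("missing cell: the design must be complete and balanced")
  m <- mean(Y)
  mA <- apply(Y, 2, mean); mB <- apply(Y, 3, mean); mS <- apply(Y, 1, mean)
  mAB <- apply(Y, c(2, 3), mean)
  mAS <- apply(Y, c(1, 2), mean)
  mBS <- apply(Y, c(1, 3), mean)
  ssA <- s * b * sum((mA - m)^2)
  ssB <- s * a * sum((mB - m)^2)
  ssAB <- s * sum((sweep(sweep(mAB, 1, mA), 2, mB) + m)^2)
  ssAS <- b * sum((sweep(sweep(mAS, 2, mA), 1, mS) + m)^2)
  ssBS <- a * sum((sweep(sweep(mBS, 2, mB), 1, mS) + m)^2)
  resid <- Y
  for (i in seq_len(s)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- Y[i, j, k] - mAB[j, k] - mAS[i, j] - mBS[i, k] +
      mA[j] + mB[k] + mS[i] - m
  }
  ssABS <- sum(resid^2)
  eff <- function(name, ss_eff, ss_err, df1, df2, eps) {
    Fv <- (ss_eff / df1) / (ss_err / df2)
    data.frame(effect = name, F = Fv, df1 = df1, df2 = df2, epsilon = eps,
               p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               eta_p2 = ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  }
  CA <- .ortho_contrasts(a); CB <- .ortho_contrasts(b)
  YA <- apply(Y, c(1, 2), mean)    # collapse over B
  YB <- apply(Y, c(1, 3), mean)
  Yflat <- matrix(Y, s, a * b)     # column order: a fastest within b
  CAB <- kronecker(CB, CA)         # matches column order (a varies fastest)
  epsA <- if (a > 2) .gg_epsilon(YA %*% CA) else 1
  epsB <- if (b > 2) .gg_epsilon(YB %*% CB) else 1
  epsAB <- if ((a - 1) * (b - 1) > 1) .gg_epsilon(Yflat %*% CAB) else 1
  out <- rbind(eff("Adaptation", ssA, ssAS, a - 1, (a - 1) * (s - 1), epsA),
               eff("Numerosity", ssB, ssBS, b - 1, (b - 1) * (s - 1), epsB),
               eff("Adaptation:Numerosity", ssAB, ssABS,
                   (a - 1) * (b - 1), (a - 1) * (b - 1) * (s - 1), epsAB))
  rownames(out) <- out$effect
  out
}

#' Bonferroni-corrected post-hoc High vs Low comparisons
#'
#' Paired t test of High vs Low cell means at each numerosity, p values
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param table long data.frame as in [rm_anova_gg()].
#' @return data.frame with `numerosity`, `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_posthoc <- function(table) {
  req <- c("participant", "adaptation", "numerosity", "value")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("table missing column(s): ", paste(miss, collapse = ", "))
  nums <- sort(unique(table$numerosity))
  if (length(nums) < 1) stop("need >= 1 numerosity cell")
  rows <- lapply(nums, function(nn) {
    sub <- table[table$numerosity == nn, ]
    wide <- merge(sub[sub$adaptation == "High", c("participant", "value")],
                  sub[sub$adaptation == "Low", c("participant", "value")],
                  by = "participant", suffixes = c("_high", "_low"))
    tt <- stats::t.test(wide$value_high, wide$value_low, paired = TRUE)
    data.frame(numerosity = nn, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Adaptation percentage
#'
#' Per participant and numerosity `N`:
#' `100 * (mean estimate | Low - mean estimate | High) / N`; each
#' participant's overall value is the unweighted mean over numerosities, and
#' the group value the mean over participants.
#'
#' @param behavior a behavioral table (see [write_behavior()]).
#' @return list with `per_participant` (data.frame participant x numerosity
#'   percentages plus `overall`), `per_numerosity` (group mean per
#'   numerosity), and `overall` (group mean).
#' @export
adaptation_percentage <- function(behavior) {
  validate_behavior(behavior)
  ids <- sort(unique(behavior$participant))
  nums <- sort(unique(behavior$true_numerosity))
  pct <- matrix(NA_real_, length(ids), length(nums),
                dimnames = list(ids, nums))
  for (i in seq_along(ids)) for (j in seq_along(nums)) {
    sel <- behavior$participant == ids[i] &
      behavior$true_numerosity == nums[j]
    hi <- behavior$estimate[sel & behavior$adaptation == "High"]
    lo <- behavior$estimate[sel & behavior$adaptation == "Low"]
    if (!length(hi) || !length(lo))
      stop("empty (participant ", ids[i], ", numerosity ", nums[j],
           ", condition) cell")
    pct[i, j] <- 100 * (mean(lo) - mean(hi)) / nums[j]
  }
  overall_pp <- rowMeans(pct)
  list(per_participant = data.frame(participant = ids, pct,
                                    overall = overall_pp,
                                    check.names = FALSE),
       per_numerosity = colMeans(pct),
       overall = mean(overall_pp))
}

#' Spearman rank correlation with t-approximation p value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-sided p
#' from the t approximation `t = rho sqrt((n-2) / (1-rho^2))`.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 4) stop("need >= 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}
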