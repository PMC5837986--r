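# Shared fixtures and independent oracles used across the test files.

# Multichannel sinusoid recording (every channel identical up to phase).
make_sine_recording <- function(freq, fs, dur_s = 10, n_channels = 2,
                                amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- t(sapply(seq_len(n_channels), function(ch)
    amp * sin(2 * pi * freq * t + (ch - 1) * 0.1)))
  recording(data, fs = fs)
}

make_white_recording <- function(n_channels, fs, dur_s, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_channels * fs * dur_s), n_channels), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

# Dominant FFT frequency (Hz) of a vector sampled at fs.
peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(floor(n / 2))]
  (which.max(sp) - 1) * fs / n
}

# Exhaustive Mann-Whitney oracle: enumerate all rank assignments of the
# combined tie-free sample; p from the exact null distribution of U.
u_test_oracle <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  positions <- utils::combn(n + m, n)
  u_null <- apply(positions, 2L, function(idx) sum(idx) - n * (n + 1) / 2)
  p_ge <- mean(u_null >= u_obs)
  p_le <- mean(u_null <= u_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Brute-force AUC oracle: explicit concordant-pair counting.
auc_oracle <- function(scores, labels) {
  g <- scores[labels]; p <- scores[!labels]
  tot <- 0
  for (a in g) for (b in p) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(g) * length(p))
}

# Holm step-down oracle, straight from the definition.
holm_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) rej[ord[k]] <- TRUE else break
  }
  rej
}

# Random background-plus-core weighted network in the style of the FC
# matrices the pipeline produces.
make_core_network <- function(n = 12, core = 1:3, w_core = 0.7, w_bg = 0.2,
                              density = 0.3, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  idx <- which(upper.tri(a))
  a[idx[runif(length(idx)) < density]] <- w_bg
  a[core, core] <- w_core
  a <- a + t(a)
  a[a > 1] <- 1
  diag(a) <- 0
  a
}

# Hand-built association_samples structure for corrected_fc arithmetic.
make_samples <- function(rho0_by_pair, rhosurr_by_pair, n_channels,
                         measure = "pearson") {
  pairs <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  list(pairs = unname(pairs),
       rho0 = matrix(rep(rho0_by_pair, 10), ncol = 10),
       rhosurr = matrix(rep(rhosurr_by_pair, 100), ncol = 100),
       n_channels = n_channels, measure = measure)
}

# Reduced-scale synthetic cohort profile used by the pipeline and
# acceptance tests (sizes chosen for desk-scale runtimes; same effect
# sizes as the default spec).
small_cohort_spec <- function(seed, n_subjects = 16) {
  synthetic_spec(n_subjects = n_subjects, n_channels = 8, fs = 128,
                 core_size = 3, preictal_s = 36, ictal_range_s = c(36, 54),
                 postictal_s = 36, edge_density = 0.35, seed = seed)
}

small_run_config <- function(seed) {
  run_config(profile = "custom", n_steps = 2e4, n_k = 11, seed = seed,
             target_fs = 128, band = c(0.5, 40), notch = NULL)
}
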