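test_that("IAAFT surrogates preserve amplitudes exactly, match spectra, and are seed-deterministic", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.8), 1024))
  s <- iaaft_surrogates(x, n_surrogates = 10, seed = 7)
  expect_length(s, 10)
  for (y in s) expect_identical(sort(y), sort(x))
  # power spectrum within 5% relative L2 error
  px <- Mod(fft(x))^2
  for (y in s)
    expect_lt(sqrt(sum((Mod(fft(y))^2 - px)^2) / sum(px^2)), 0.05)
  # white-noise autocorrelation at lag 1 reproduced within +/- 0.1
  set.seed(5)
  w <- rnorm(1024)
  ac0 <- cor(w[-1], w[-1024])
  for (y in iaaft_surrogates(w, 10, seed = 8))
    expect_lt(abs(cor(y[-1], y[-1024]) - ac0), 0.1)
  # determinism and independence across seeds
  expect_identical(iaaft_surrogates(x, 3, seed = 9), iaaft_surrogates(x, 3, seed = 9))
  expect_false(identical(iaaft_surrogates(x, 1, seed = 1)[[1]],
                         iaaft_surrogates(x, 1, seed = 2)[[1]]))
  expect_error(iaaft_surrogates(rep(1, 128), 2), "constant")
})

test_that("zero-lag Pearson association uses the absolute-value convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_zero_lag(x, x), 1)
  expect_equal(pearson_zero_lag(x, -x), 1)
  # hand computation of the Pearson formula
  y <- c(1, 2, 3, 5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_zero_lag(x, y), abs(num / den))
  expect_equal(pearson_zero_lag(x, y), 0.98271, tolerance = 1e-5)
  expect_error(pearson_zero_lag(rep(1, 4), y), "constant")
})

test_that("h2 index captures linear and quadratic dependence and stays near 0 under independence", {
  set.seed(11)
  x <- runif(1000, -1, 1)
  expect_gte(h2_association(x, x), 0.999)
  expect_gte(h2_association(x, x^2, n_bins = 10), 0.9)
  expect_lt(abs(cor(x, x^2)), 0.1) # Pearson misses the parabola
  null_h2 <- replicate(100, {
    a <- rnorm(1024); b <- rnorm(1024)
    h2_association(a, b)
  })
  expect_lte(max(null_h2), 0.1)
  expect_equal(h2_association(x, rep(0, 1000)), 0)
  expect_error(h2_association(x, x, n_bins = 1), "n_bins")
})

test_that("U-test p-values agree with exhaustive rank enumeration for small samples", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- round(rnorm(n), 6); y <- round(rnorm(m) + runif(1, -1, 1), 6)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(u_test(x, y, alt)$p.value, u_test_oracle(x, y, alt),
                   tolerance = 1e-12,
                   label = sprintf("n=%d m=%d alt=%s", n, m, alt))
    }
  }
})

test_that("surrogate significance rejects clear separation and controls the null", {
  # clear separation: originals far above surrogates
  set.seed(31)
  samples <- list(
    pairs = matrix(c(1L, 2L), 1),
    rho0 = matrix(0.9 + runif(10) * 1e-3, 1),
    rhosurr = matrix(0.1 + runif(100) * 1e-3, 1),
    n_channels = 2L, measure = "pearson")
  s <- surrogate_significance(samples, alpha = 0.05)
  expect_equal(s[1, 2], 1)
  expect_lt(attr(s, "p_values")[1], 1e-6)
  # null calibration: both groups from the same distribution
  set.seed(32)
  rejections <- replicate(200, {
    sm <- list(pairs = matrix(c(1L, 2L), 1),
               rho0 = matrix(runif(10), 1),
               rhosurr = matrix(runif(100), 1),
               n_channels = 2L, measure = "pearson")
    surrogate_significance(sm, alpha = 0.05)[1, 2]
  })
  expect_lte(mean(rejections), 0.05 + 0.03)
})

test_that("Holm step-down decisions match the definition", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "holm") <= 0.05, holm_reject_oracle(p, 0.05))
  expect_true(all(holm_reject_oracle(p, 0.05)))
  set.seed(41)
  for (rep in 1:20) {
    pv <- runif(sample(3:12, 1))^2
    expect_equal(p.adjust(pv, "holm") <= 0.05, holm_reject_oracle(pv, 0.05))
  }
})

test_that("corrected FC follows the surrogate-correction formula and its edge cases", {
  sm <- make_samples(rho0_by_pair = c(0.6, 1, 0.5),
                     rhosurr_by_pair = c(0.2, 0.3, 0.5), n_channels = 3)
  s_all <- matrix(1, 3, 3) - diag(3)
  net <- corrected_fc(sm, s_all)
  expect_equal(net$weights[1, 2], (0.6 - 0.2) / (1 - 0.2)) # 0.5
  expect_equal(net$weights[1, 3], 1)                       # rho0 = 1
  expect_equal(net$weights[2, 3], 0)                       # rho0 = rhosurr
  # s = 0 zeroes the entry regardless of the association values
  net0 <- corrected_fc(sm, matrix(0, 3, 3))
  expect_true(all(net0$weights == 0))
  # degenerate denominator -> weight 0 with a warning
  smd <- make_samples(c(1, 0.1, 0.1), c(1, 0.05, 0.05), 3)
  expect_warning(netd <- corrected_fc(smd, s_all), "rhosurr = 1")
  expect_equal(netd$weights[1, 2], 0)
})

test_that("inferred FC matrices are symmetric, zero-diagonal and bounded", {
  set.seed(51)
  g <- rnorm(1024)
  m <- rbind(sqrt(0.7) * g + sqrt(0.3) * rnorm(1024),
             sqrt(0.7) * g + sqrt(0.3) * rnorm(1024),
             rnorm(1024))
  net <- segment_fc(m, fs = 128, seed = 3)
  w <- net$weights
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all((w > 0) == (net$significance > 0)))
})

test_that("the surrogate test detects shared signal and spares independent channels", {
  # sensitivity: 70% shared variance pair
  set.seed(61)
  hits <- replicate(12, {
    g <- rnorm(1024)
    m <- rbind(sqrt(0.7) * g + sqrt(0.3) * rnorm(1024),
               sqrt(0.7) * g + sqrt(0.3) * rnorm(1024))
    segment_fc(m, fs = 128, seed = sample.int(1e6, 1))$weights[1, 2] > 0
  })
  expect_gte(sum(hits), 11)
  # null: independent channels yield almost no edges after Holm
  set.seed(62)
  edge_frac <- replicate(10, {
    m <- matrix(rnorm(4 * 1024), 4)
    w <- segment_fc(m, fs = 128, seed = sample.int(1e6, 1))$weights
    sum(w[upper.tri(w)] > 0) / sum(upper.tri(w))
  })
  expect_lte(mean(edge_frac), 0.05)
})

test_that("FC networks round-trip through the TSV + JSON serialization", {
  a <- make_core_network(n = 6, core = 1:2, seed = 3)
  net <- fc_network(a, measure = "pearson")
  path <- tempfile(fileext = ".tsv")
  write_fc(net, path, meta = list(alpha = 0.05))
  back <- read_fc(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
  expect_equal(back$measure, "pearson")
})
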