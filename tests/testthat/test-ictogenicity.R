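test_that("the uncoupled node has the closed-form fixed point and SNIC boundary", {
  expect_equal(theta_steady_state(-1.2), -acos(-1 / 11), tolerance = 1e-9)
  expect_equal(theta_steady_state(-1), -pi / 2, tolerance = 1e-9)
  expect_lt(abs(theta_steady_state(-1e-9)), 1e-4) # theta_s -> 0 at the bifurcation
  expect_error(theta_steady_state(0), "no fixed point")
  expect_error(theta_steady_state(0.3), "no fixed point")
  # spiking iff I0 > 0 (noise-free, uncoupled)
  a1 <- matrix(0, 1, 1)
  below <- simulate_theta_network(a1, theta_params(i0 = -0.1, noise_sd = 0,
                                                   n_steps = 5e4, seed = 1), 0)
  above <- simulate_theta_network(a1, theta_params(i0 = 0.1, noise_sd = 0,
                                                   n_steps = 5e4, seed = 1), 0)
  expect_length(below[[1]], 0)
  expect_gt(length(above[[1]]), 10)
})

test_that("noise-free spiking period matches pi/sqrt(I0) within 2 dt", {
  a1 <- matrix(0, 1, 1)
  dt <- 0.01
  for (i0 in c(0.1, 0.5, 1.0)) {
    sp <- simulate_theta_network(
      a1, theta_params(i0 = i0, noise_sd = 0, dt = dt, n_steps = 2e4), 0)
    isi <- diff(sp[[1]])
    expect_lt(abs(mean(isi) - pi / sqrt(i0)), 2 * dt)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- make_core_network(n = 5, core = 1:2, seed = 2)
  p <- theta_params(n_steps = 1e4, seed = 77)
  expect_identical(simulate_theta_network(a, p, 10),
                   simulate_theta_network(a, p, 10))
  expect_error(simulate_theta_network(matrix(NA_real_, 2, 2), p, 1),
               "non-finite|diagonal")
})

test_that("seizure fraction evaluates the trailing-window definition directly", {
  expect_equal(seizure_fraction(list(numeric(0), numeric(0)), 100), 0)
  w <- default_seizure_window()
  # node 1 spikes continuously (ISI < w), node 2 silent -> 0.5 up to edges
  sp <- list(seq(1, 100, by = w / 3), numeric(0))
  expect_equal(seizure_fraction(sp, 100, w), 0.5, tolerance = w / 100)
  # a single spike contributes exactly w / horizon
  expect_equal(seizure_fraction(list(c(10)), 100, w), w / 100)
  # dense spiking on every node -> 1
  sp2 <- list(seq(0.5, 200, by = 1), seq(0.5, 200, by = 1))
  expect_equal(seizure_fraction(sp2, 200, w), 1, tolerance = w / 200)
})

test_that("BNI* respects coupling: zero at K = 0 baseline, increasing for excitatory networks", {
  p <- theta_params(n_steps = 2e4, seed = 5)
  empty <- matrix(0, 6, 6)
  full <- matrix(0.5, 6, 6); diag(full) <- 0
  # K = 0 removes the network: identical to the empty network
  expect_equal(bni_star(full, p, 0), bni_star(empty, p, 0))
  # empty network: baseline regardless of K
  base <- bni_star(empty, p, 0)
  expect_lt(abs(bni_star(empty, p, 100) - base), 0.05)
  # monotone growth with K on an all-to-all network
  cv <- bni_curve(full, p, seq(0, 60, length.out = 20))
  expect_true(all(cv$bni_star >= 0 & cv$bni_star <= 1))
  expect_gte(cor(cv$k_grid, cv$bni_star, method = "spearman"), 0.8)
})

test_that("adding edges cannot decrease seizure propensity (paired replicates)", {
  p <- theta_params(n_steps = 2e4)
  set.seed(8)
  wins <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    a <- make_core_network(n = 8, core = 1:3, w_core = 0.4, w_bg = 0.3,
                           density = 0.25, seed = 100 + r)
    # add extra edges on empty slots
    b <- a
    empty_idx <- which(upper.tri(b) & b == 0)
    add <- sample(empty_idx, max(1, length(empty_idx) %/% 3))
    b[add] <- 0.4
    b <- pmax(b, t(b))
    p$seed <- 200 + r
    # probe at a coupling inside the transition of the sparser network
    cal <- calibrate_reference_coupling(a, p, n_realizations = 1)
    k <- cal$k_ref
    wins <- wins + (bni_star(b, p, k, n_realizations = 2) >=
                      bni_star(a, p, k, n_realizations = 2) - 0.02)
  }
  expect_gte(wins, ceiling(0.8 * n_rep))
})

test_that("coupling-interval selection applies the saturation rule with a 20% margin", {
  curve_at <- function(k_sat, cap = 1) {
    g <- seq(0, 6, by = 0.5)
    structure(list(k_grid = g,
                   bni_star = pmin(cap, ifelse(g >= k_sat, 1, g / k_sat))),
              class = "bni_curve")
  }
  expect_equal(select_k_interval(list(curve_at(3))), c(0, 3.6))
  expect_equal(select_k_interval(list(curve_at(2), curve_at(5))), c(0, 6))
  expect_error(select_k_interval(list(curve_at(3, cap = 0.7))), "grid exhausted")
  expect_warning(
    ki <- select_k_interval(list(curve_at(2), curve_at(3, cap = 0.7))),
    "dropped")
  expect_equal(ki, c(0, 2.4))
})

test_that("BNI integrates the curve by the trapezoid rule", {
  mk <- function(g, v) structure(list(k_grid = g, bni_star = v),
                                 class = "bni_curve")
  expect_equal(bni_integral(mk(seq(0, 2, 0.5), rep(1, 5))), 2)
  expect_equal(bni_integral(mk(seq(1, 3, 0.5), rep(0.5, 5))), 1)
  expect_equal(bni_integral(mk(seq(0, 1, 0.1), seq(0, 1, 0.1))), 0.5)
  # interior bounds via interpolation
  expect_equal(bni_integral(mk(seq(0, 2, 0.5), rep(1, 5)), 0.25, 1.75), 1.5)
  expect_error(bni_integral(mk(seq(0, 1, 0.5), rep(1, 3)), 1, 0.5), "exceed")
  expect_error(bni_integral(mk(seq(0, 1, 0.5), rep(1, 3)), 0, 2), "range")
})

test_that("time-course normalization scales by the epoch maximum and resamples seizures to 10 points", {
  tc <- bni_timecourse(time_s = c(1, 5, 9),
                       epoch = c("preictal", "ictal", "postictal"),
                       bni = c(2, 4, 1))
  out <- normalize_timecourse(tc)
  expect_equal(out$bni[out$epoch == "preictal"], 0.5)
  expect_equal(unique(out$bni[out$epoch == "ictal"]), 1)
  expect_equal(out$bni[out$epoch == "postictal"], 0.25)
  expect_equal(sum(out$epoch == "ictal"), 10)
  # 11 ictal values -> exactly 10
  tc11 <- bni_timecourse(time_s = c(0, seq(10, 20, 1), 30),
                         epoch = c("preictal", rep("ictal", 11), "postictal"),
                         bni = c(1, seq(1, 2, 0.1), 1))
  out11 <- normalize_timecourse(tc11)
  expect_equal(sum(out11$epoch == "ictal"), 10)
  # already 10 equally spaced values: unchanged (up to the normalization)
  tc10 <- bni_timecourse(time_s = c(0, seq(10, 19, 1), 30),
                         epoch = c("preictal", rep("ictal", 10), "postictal"),
                         bni = c(1, seq(1, 2, length.out = 10), 2.5))
  out10 <- normalize_timecourse(tc10)
  expect_equal(out10$bni[out10$epoch == "ictal"],
               seq(1, 2, length.out = 10) / 2.5)
  expect_error(normalize_timecourse(
    bni_timecourse(1, "preictal", 1)), "ictal")
})

test_that("bisection calibration homes in on the crossing of a monotone response", {
  # known monotone function crossing the target at K = 1.7
  f <- function(k) plogis((k - 1.7) / 0.2)
  res <- ictonet:::bisect_to_target(f, target = 0.5, tol = 0.01)
  expect_lt(abs(res$k - 1.7), 0.1)
  expect_lt(abs(res$value - 0.5), 0.01)
  # all-silent response cannot be bracketed
  expect_error(ictonet:::bisect_to_target(function(k) 0, 0.5, 0.05,
                                          max_doublings = 6),
               "not bracketed")
  # baseline already above the target
  expect_error(ictonet:::bisect_to_target(function(k) 0.9, 0.5, 0.05),
               "exceeds")
})

test_that("calibration on a network reaches the 0.5 reference within tolerance", {
  a <- make_core_network(n = 8, core = 1:3, w_core = 0.6, w_bg = 0.25,
                         density = 0.3, seed = 4)
  p <- theta_params(n_steps = 2e4, seed = 10)
  cal <- calibrate_reference_coupling(a, p, n_realizations = 2)
  expect_lte(abs(cal$bni_achieved - 0.5), 0.05)
  expect_gt(cal$k_ref, 0)
})

test_that("resection scoring follows the relative-drop definition", {
  a <- make_core_network(n = 8, core = 1:3, w_core = 0.7, w_bg = 0.15,
                         density = 0.25, seed = 6)
  p <- theta_params(n_steps = 2e4, seed = 11)
  cal <- calibrate_reference_coupling(a, p, n_realizations = 2)
  res <- delta_bni(a, 1:3, p, cal$k_ref, n_realizations = 2,
                   bni_pre = cal$bni_achieved)
  expect_equal(res$delta_bni,
               (res$bni_pre - res$bni_post) / res$bni_pre)
  expect_gt(res$delta_bni, 0) # removing the strongly coupled core helps
  expect_error(delta_bni(a, 1:8, p, cal$k_ref), "every node")
  expect_error(delta_bni(a, c(0, 9), p, cal$k_ref), "range")
})
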