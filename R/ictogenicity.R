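# Theta-neuron network simulation, BNI scoring and in-silico resection.

#' Theta-model parameters
#'
#' Parameters of the noisy theta-neuron network. Each node obeys
#' `dtheta/dt = (1 - cos theta) + (1 + cos theta) * I(t)` with input
#' `I = I0 + xi(t) + (K/N) * sum_i a_ij * (1 - cos(theta_i - theta_i_s))`.
#' With `I0 < 0` the uncoupled noise-free node rests at a stable fixed point;
#' noise and coupling drive transitions through the SNIC bifurcation into
#' spiking ("seizure") activity.
#'
#' @param i0 Per-node excitability, scalar (recycled) or one value per node.
#'   Negative values (the default regime) give an excitable node with a
#'   stable fixed point; nonnegative values put the node beyond the SNIC
#'   bifurcation, where it spikes autonomously with period `pi / sqrt(i0)`.
#' @param noise_sd Standard deviation of the Gaussian input noise.
#' @param dt Euler-Maruyama integration step (model time units).
#' @param n_steps Number of integration steps.
#' @param seed Optional integer seed for the noise stream.
#' @return An object of class `"theta_params"`.
#' @export
theta_params <- function(i0 = -1.2, noise_sd = 0.6, dt = 0.01,
                         n_steps = 2e5, seed = NULL) {
  if (!is.numeric(i0) || any(!is.finite(i0)))
    stop("`i0` must be finite numeric")
  stop_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  stop_scalar(dt, "dt", positive = TRUE)
  stop_scalar(n_steps, "n_steps", positive = TRUE)
  structure(list(i0 = i0, noise_sd = noise_sd, dt = dt,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "theta_params")
}

#' Steady state of the uncoupled theta node
#'
#' The stable fixed point of `dtheta/dt = (1 - cos theta) + (1 + cos theta) I0`
#' for constant negative input: `theta_s = -acos((1 + I0) / (1 - I0))`.
#'
#' @param i0 Excitability; must be negative. Vectorized.
#' @return The stable fixed-point phase(s) in `(-pi, 0]`.
#' @export
theta_steady_state <- function(i0) {
  if (any(i0 >= 0))
    stop("no fixed point: `i0` must be negative (node is beyond the SNIC ",
         "bifurcation)")
  -acos((1 + i0) / (1 - i0))
}

#' Simulate the theta-neuron network
#'
#' Euler-Maruyama integration of the coupled stochastic theta model on a
#' weighted network, started from the per-node stable fixed point. Phases are
#' wrapped to `(-pi, pi]`; a spike is recorded at each upward crossing of
#' `theta = pi`. Deterministic for a fixed seed.
#'
#' @param a Square nonnegative weight matrix with zero diagonal (e.g.
#'   `fc_network$weights`).
#' @param params A [theta_params()].
#' @param k Global coupling scaling K.
#' @return List of per-node spike-time vectors (model time units), with
#'   attributes `horizon` (total simulated time) and `dt`.
#' @export
simulate_theta_network <- function(a, params, k) {
  if (inherits(a, "fc_network")) a <- a$weights
  check_weight_matrix(a)
  stopifnot(inherits(params, "theta_params"))
  stop_scalar(k, "k")
  n <- nrow(a)
  i0 <- rep_len(params$i0, n)
  spikes <- with_seed(params$seed,
    theta_sim_cpp(a, i0, params$noise_sd, k, params$dt, params$n_steps))
  attr(spikes, "horizon") <- params$n_steps * params$dt
  attr(spikes, "dt") <- params$dt
  spikes
}

# Fraction of [0, horizon] covered by the union of windows [s, s + w]
# trailing the spike times s.
occupied_fraction <- function(spike_times, horizon, w) {
  s <- spike_times[spike_times <= horizon & spike_times >= 0]
  if (!length(s)) return(0)
  s <- sort(s)
  en <- pmin(s + w, horizon)
  tot <- 0; cs <- s[1L]; ce <- en[1L]
  if (length(s) > 1L) for (i in 2:length(s)) {
    if (s[i] <= ce) ce <- max(ce, en[i])
    else { tot <- tot + ce - cs; cs <- s[i]; ce <- en[i] }
  }
  (tot + ce - cs) / horizon
}

#' Default seizure-state window
#'
#' Three nominal inter-spike intervals of the spiking regime at input
#' `I = 0.5` (period `pi / sqrt(I)`), about 13.3 model time units: long
#' enough that sustained spiking maps to contiguous seizure-state time,
#' short enough that isolated escapes contribute little.
#'
#' @return The window length in model time units.
#' @export
default_seizure_window <- function() 3 * pi / sqrt(0.5)

#' Seizure-time fraction (raw BNI*)
#'
#' A node is in the seizure state at time `t` iff it spiked within the
#' trailing window `[t - window, t]`; BNI* is the average over nodes of the
#' fraction of the horizon spent in that state.
#'
#' @param spikes List of per-node spike-time vectors.
#' @param horizon Evaluation horizon (model time units).
#' @param window Trailing window `w` (default three nominal inter-spike
#'   intervals of the spiking regime).
#' @return BNI*, a value in `[0, 1]`.
#' @export
seizure_fraction <- function(spikes, horizon, window = default_seizure_window()) {
  stop_scalar(horizon, "horizon", positive = TRUE)
  stop_scalar(window, "window", positive = TRUE)
  if (!length(spikes)) return(0)
  mean(vapply(spikes, occupied_fraction, numeric(1),
              horizon = horizon, w = window))
}

#' BNI* at a single coupling value
#'
#' Simulates the network at coupling `k`, discards the initial transient
#' (`burn_frac` of the horizon) and evaluates the seizure-time fraction,
#' averaged over `n_realizations` independent noise realizations (seeds
#' derived from `params$seed`).
#'
#' @inheritParams simulate_theta_network
#' @param n_realizations Number of noise realizations to average.
#' @param burn_frac Fraction of the simulation discarded as burn-in.
#' @param window Seizure-state window passed to [seizure_fraction()].
#' @return BNI* in `[0, 1]`.
#' @export
bni_star <- function(a, params, k, n_realizations = 1L, burn_frac = 0.1,
                     window = default_seizure_window()) {
  vals <- vapply(seq_len(n_realizations), function(r) {
    p <- params
    p$seed <- derive_seed(params$seed, r)
    sp <- simulate_theta_network(a, p, k)
    horizon <- attr(sp, "horizon")
    burn <- burn_frac * horizon
    shifted <- lapply(sp, function(s) s[s > burn] - burn)
    seizure_fraction(shifted, horizon - burn, window)
  }, numeric(1))
  mean(vals)
}

#' BNI* as a function of coupling
#'
#' Evaluates BNI* on a grid of coupling values with a fresh noise stream per
#' grid point (derived from the same master seed).
#'
#' @inheritParams bni_star
#' @param k_grid Increasing vector of coupling values (at least 2).
#' @return A `"bni_curve"`: list with `k_grid` and `bni_star`.
#' @export
bni_curve <- function(a, params, k_grid, n_realizations = 1L,
                      burn_frac = 0.1, window = default_seizure_window()) {
  if (length(k_grid) < 2L || any(diff(k_grid) <= 0))
    stop("`k_grid` must be increasing with at least 2 points")
  vals <- vapply(seq_along(k_grid), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, 1000L + i)
    bni_star(a, p, k_grid[i], n_realizations, burn_frac, window)
  }, numeric(1))
  structure(list(k_grid = k_grid, bni_star = vals), class = "bni_curve")
}

#' Find a saturating coupling by geometric scan
#'
#' Doubles the coupling from `k_init` until BNI* reaches `threshold`;
#' used to size the coupling grid before computing full curves.
#'
#' @inheritParams bni_star
#' @param threshold Saturation level (default 0.95).
#' @param k_init First coupling probed.
#' @param max_doublings Scan cap.
#' @return The smallest probed coupling with BNI* at or above `threshold`,
#'   or `NA` if the scan is exhausted.
#' @export
scan_k_saturation <- function(a, params, threshold = 0.95, k_init = 1,
                              max_doublings = 14L, n_realizations = 1L) {
  k <- k_init
  for (i in seq_len(max_doublings + 1L)) {
    p <- params
    p$seed <- derive_seed(params$seed, 2000L + i)
    if (bni_star(a, p, k, n_realizations) >= threshold) return(k)
    k <- 2 * k
  }
  NA_real_
}

#' Fix the coupling-integration interval for a subject
#'
#' `K1 = 0`; `K2` is the smallest grid value at which every supplied curve
#' saturates (BNI* at or above `threshold`), extended by a 20% margin.
#' Curves that never saturate within their grid are dropped from the rule
#' with a warning; if no curve saturates the scan is declared exhausted.
#' The returned interval is then fixed for all segments of the subject, so
#' that BNI values are comparable.
#'
#' @param curves A list of `"bni_curve"` objects from the same subject.
#' @param threshold Saturation level (default 0.95).
#' @param margin Relative extension of K2 (default 0.2).
#' @return Numeric `c(k1, k2)`.
#' @export
select_k_interval <- function(curves, threshold = 0.95, margin = 0.2) {
  if (inherits(curves, "bni_curve")) curves <- list(curves)
  if (!length(curves)) stop("at least one curve is required")
  k_sat <- vapply(curves, function(cv) {
    i <- which(cv$bni_star >= threshold)
    if (length(i)) cv$k_grid[min(i)] else NA_real_
  }, numeric(1))
  if (all(is.na(k_sat)))
    stop("grid exhausted: no curve reaches BNI* >= ", threshold,
         " on its grid; rescan with a wider coupling range")
  if (anyNA(k_sat))
    warning(sum(is.na(k_sat)), " curve(s) never saturate on their grid and ",
            "were dropped from the K2 rule", call. = FALSE)
  c(0, (1 + margin) * max(k_sat, na.rm = TRUE))
}

#' Coupling-integrated BNI
#'
#' Trapezoidal integral of BNI*(K) over `[k1, k2]`, removing the dependence
#' on a single arbitrary coupling value. Endpoints inside the grid are
#' handled by linear interpolation.
#'
#' @param curve A `"bni_curve"`.
#' @param k1,k2 Integration bounds; must lie within the curve's grid range
#'   and satisfy `k1 < k2`.
#' @return The integral, a value in `[0, k2 - k1]`.
#' @export
bni_integral <- function(curve, k1 = min(curve$k_grid),
                         k2 = max(curve$k_grid)) {
  stopifnot(inherits(curve, "bni_curve"))
  if (k2 <= k1) stop("`k2` must exceed `k1`")
  g <- curve$k_grid
  if (k1 < min(g) - 1e-9 || k2 > max(g) + 1e-9)
    stop("integration bounds must lie within the curve's grid range")
  xs <- sort(unique(c(k1, g[g > k1 & g < k2], k2)))
  ys <- approx(g, curve$bni_star, xout = xs)$y
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' BNI time course container
#'
#' @param time_s Segment midpoint times in seconds.
#' @param epoch Epoch labels (`"preictal"`, `"ictal"`, `"postictal"`).
#' @param bni BNI values per segment.
#' @return A data frame of class `"bni_timecourse"` with attribute
#'   `normalized = FALSE`.
#' @export
bni_timecourse <- function(time_s, epoch, bni) {
  if (!all(epoch %in% c("preictal", "ictal", "postictal")))
    stop("epoch labels must be preictal/ictal/postictal")
  tc <- data.frame(time_s = time_s, epoch = epoch, bni = bni)
  tc <- tc[order(tc$time_s), ]
  rownames(tc) <- NULL
  structure(tc, class = c("bni_timecourse", "data.frame"),
            normalized = FALSE)
}

#' Normalize a peri-ictal BNI time course
#'
#' Divides all values by the maximum over the whole peri-ictal epoch
#' (pre-ictal + ictal + post-ictal of one recording), so the maximum becomes
#' 1, and linearly resamples the ictal series onto exactly 10 equally spaced
#' points in normalized seizure time (making seizures of different duration
#' comparable). Pre- and post-ictal series keep their length.
#'
#' @param tc A `"bni_timecourse"`.
#' @param n_ictal Number of ictal points after resampling (default 10).
#' @return The normalized `"bni_timecourse"` (attribute `normalized = TRUE`).
#' @export
normalize_timecourse <- function(tc, n_ictal = 10L) {
  stopifnot(inherits(tc, "bni_timecourse"))
  if (!any(tc$epoch == "ictal")) stop("time course contains no ictal values")
  m <- max(tc$bni)
  if (m <= 0) stop("degenerate time course: maximum BNI is 0")
  tc$bni <- tc$bni / m
  ict <- tc[tc$epoch == "ictal", ]
  if (nrow(ict) != n_ictal) {
    if (nrow(ict) == 1L) {
      new_bni <- rep(ict$bni, n_ictal)
      new_t <- rep(ict$time_s, n_ictal)
    } else {
      pos <- seq(0, 1, length.out = nrow(ict))
      out <- seq(0, 1, length.out = n_ictal)
      new_bni <- approx(pos, ict$bni, xout = out)$y
      new_t <- approx(pos, ict$time_s, xout = out)$y
    }
    ict <- data.frame(time_s = new_t, epoch = "ictal", bni = new_bni)
  }
  out <- rbind(tc[tc$epoch == "preictal", ], ict,
               tc[tc$epoch == "postictal", ])
  rownames(out) <- NULL
  structure(out, class = c("bni_timecourse", "data.frame"), normalized = TRUE)
}

#' Calibrate the resection reference coupling
#'
#' Finds, by bracketing and bisection on the global coupling, the value
#' `K_ref` at which the pre-surgery network's BNI* (averaged over
#' `n_realizations` noise realizations) matches the reference level
#' (`target = 0.5`). This is the reference state against which node removals
#' are scored.
#'
#' @inheritParams bni_star
#' @param target Reference BNI* level (default 0.5).
#' @param tol Acceptable deviation from `target` (default 0.05).
#' @param k_init Initial bracketing coupling.
#' @param max_doublings,max_bisections Iteration caps.
#' @return A `"bni_calibration"`: list with `k_ref`, `bni_achieved` and the
#'   evaluation log `trace` (data frame of k and BNI*).
#' @export
calibrate_reference_coupling <- function(a, params, target = 0.5, tol = 0.05,
                                         n_realizations = 3L, k_init = 1,
                                         max_doublings = 16L,
                                         max_bisections = 14L) {
  if (inherits(a, "fc_network")) a <- a$weights
  check_weight_matrix(a)
  eval_no <- 0L
  f <- function(k) {
    eval_no <<- eval_no + 1L
    p <- params
    p$seed <- derive_seed(params$seed, 3000L + eval_no)
    bni_star(a, p, k, n_realizations)
  }
  res <- bisect_to_target(f, target = target, tol = tol, k_init = k_init,
                          max_doublings = max_doublings,
                          max_bisections = max_bisections)
  structure(list(k_ref = res$k, bni_achieved = res$value, target = target,
                 tol = tol, trace = res$trace),
            class = "bni_calibration")
}

# Bracket [0, k] by doubling until f crosses `target`, then bisect until the
# function value is within `tol`. f may be a noisy (Monte-Carlo) evaluator:
# with `confirm = TRUE` a candidate inside the tolerance is accepted only if
# a fresh re-evaluation, pooled with the first, stays inside it — guarding
# against acceptance on a single lucky draw. Internal; also the test seam
# for the bisection logic.
bisect_to_target <- function(f, target, tol, k_init = 1,
                             max_doublings = 16L, max_bisections = 14L,
                             confirm = TRUE) {
  trace_k <- numeric(0); trace_b <- numeric(0)
  g <- function(k) {
    b <- f(k)
    trace_k <<- c(trace_k, k); trace_b <<- c(trace_b, b)
    b
  }
  done <- function(k, value)
    list(k = k, value = value,
         trace = data.frame(k = trace_k, value = trace_b))
  # returns the pooled value when k is confirmed at the target, else NULL
  try_accept <- function(k, b) {
    if (abs(b - target) > tol) return(NULL)
    if (!confirm) return(b)
    pooled <- (b + g(k)) / 2
    if (abs(pooled - target) <= tol) pooled else NULL
  }
  b_lo <- g(0)
  if (b_lo > target + tol)
    stop("calibration failed: baseline value (", signif(b_lo, 3),
         ") already exceeds the target")
  k_lo <- 0
  k_hi <- k_init
  b_hi <- g(k_hi)
  n_doub <- 0L
  while (b_hi < target && n_doub < max_doublings) {
    acc <- try_accept(k_hi, b_hi)
    if (!is.null(acc)) return(done(k_hi, acc))
    k_lo <- k_hi; b_lo <- b_hi
    k_hi <- 2 * k_hi
    b_hi <- g(k_hi)
    n_doub <- n_doub + 1L
  }
  if (b_hi < target)
    stop("calibration failed: target not bracketed up to K = ", k_hi)
  acc <- try_accept(k_hi, b_hi)
  if (!is.null(acc)) return(done(k_hi, acc))
  best_k <- k_hi; best_b <- b_hi
  if (abs(b_lo - target) < abs(best_b - target)) { best_k <- k_lo; best_b <- b_lo }
  for (i in seq_len(max_bisections)) {
    k_mid <- (k_lo + k_hi) / 2
    b_mid <- g(k_mid)
    acc <- try_accept(k_mid, b_mid)
    if (!is.null(acc)) return(done(k_mid, acc))
    if (abs(b_mid - target) < abs(best_b - target)) {
      best_k <- k_mid; best_b <- b_mid
    }
    if (b_mid < target) { k_lo <- k_mid } else { k_hi <- k_mid }
  }
  warning("calibration stopped at value ", signif(best_b, 3),
          " (target ", target, " +/- ", tol, ")", call. = FALSE)
  done(best_k, best_b)
}

#' In-silico resection
#'
#' Removes the node set from the network (rows and columns deleted; the
#' `K/N` prefactor uses the reduced node count), re-simulates at the
#' calibrated reference coupling, and scores the resection as
#' `delta_bni = (bni_pre - bni_post) / bni_pre`. Values near 1 mean the
#' removal suppresses seizure activity in the model; values near 0 mean no
#' effect.
#'
#' @inheritParams bni_star
#' @param nodes Integer indices of the removed nodes; must be a strict
#'   subset of the node set (an empty set scores the unmodified network).
#' @param k_ref Calibrated reference coupling (see
#'   [calibrate_reference_coupling()]).
#' @param bni_pre Reference BNI*; if `NULL`, re-evaluated at `k_ref` on the
#'   intact network.
#' @return A `"resection_result"`: list with `removed_nodes`, `bni_pre`,
#'   `bni_post`, `delta_bni`.
#' @export
delta_bni <- function(a, nodes, params, k_ref, n_realizations = 3L,
                      bni_pre = NULL) {
  if (inherits(a, "fc_network")) a <- a$weights
  check_weight_matrix(a)
  n <- nrow(a)
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) && (min(nodes) < 1L || max(nodes) > n))
    stop("`nodes` out of range")
  if (length(nodes) >= n)
    stop("invalid resection: cannot remove every node")
  if (is.null(bni_pre)) {
    p <- params; p$seed <- derive_seed(params$seed, 4001L)
    bni_pre <- bni_star(a, p, k_ref, n_realizations)
  }
  if (bni_pre <= 0) stop("reference BNI* is 0; resection score undefined")
  a_post <- if (length(nodes)) a[-nodes, -nodes, drop = FALSE] else a
  p <- params; p$seed <- derive_seed(params$seed, 4002L)
  bni_post <- bni_star(a_post, p, k_ref, n_realizations)
  structure(list(removed_nodes = nodes, bni_pre = bni_pre,
                 bni_post = bni_post,
                 delta_bni = (bni_pre - bni_post) / bni_pre),
            class = "resection_result")
}

#' @export
print.resection_result <- function(x, ...) {
  cat(sprintf("<resection> %d node(s) removed: BNI %0.3f -> %0.3f, delta = %0.3f\n",
              length(x$removed_nodes), x$bni_pre, x$bni_post, x$delta_bni))
  invisible(x)
}
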