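# Functional connectivity: IAAFT surrogates, association measures,
# surrogate significance testing and the corrected FC matrix.

#' IAAFT surrogates of a univariate series
#'
#' Iterated amplitude adjusted Fourier transform surrogates: each surrogate
#' preserves the amplitude distribution of `x` exactly (same multiset of
#' sample values) and matches its power spectrum at convergence. Iteration
#' stops when the rank ordering is unchanged between iterations or after
#' `max_iter` iterations. Surrogates destroy cross-channel coupling and serve
#' as the null ensemble for association testing.
#'
#' @param x Numeric vector, length at least 64, not constant.
#' @param n_surrogates Number of surrogates to generate.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   surrogates and distinct seeds give independent surrogates.
#' @param max_iter Iteration cap (default 100).
#' @return A list of `n_surrogates` numeric vectors.
#' @export
iaaft_surrogates <- function(x, n_surrogates = 10L, seed = NULL,
                             max_iter = 100L) {
  if (!is.numeric(x) || length(x) < 64L)
    stop("`x` must be a numeric vector of length >= 64")
  if (sd(x) == 0) stop("degenerate signal: `x` is constant")
  if (n_surrogates < 1L) stop("`n_surrogates` must be >= 1")
  with_seed(seed,
    lapply(seq_len(n_surrogates), function(i)
      as.numeric(iaaft_cpp(x, as.integer(max_iter)))))
}

#' Zero-lag Pearson association
#'
#' Absolute value of the sample Pearson correlation at lag zero. The absolute
#' value makes the association a nonnegative coupling strength, as required
#' by the downstream network model.
#'
#' @param x,y Numeric vectors of equal length (at least 2), neither constant.
#' @return The association, a value in `[0, 1]`.
#' @export
pearson_zero_lag <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input")
  abs(cor(x, y))
}

h2_directional <- function(x, y, n_bins) {
  sse0 <- sum((y - mean(y))^2)
  if (sse0 == 0) return(0)
  # equal-count bins of x
  bin <- ceiling(rank(x, ties.method = "first") * n_bins / length(x))
  mx <- as.numeric(tapply(x, bin, mean))
  my <- as.numeric(tapply(y, bin, mean))
  f <- approx(mx, my, xout = x, ties = mean)$y
  # extend the end segments linearly beyond the outer bin centres
  nb <- length(mx)
  lo <- x < mx[1]; hi <- x > mx[nb]
  if (any(lo))
    f[lo] <- my[1] + (my[2] - my[1]) / (mx[2] - mx[1]) * (x[lo] - mx[1])
  if (any(hi))
    f[hi] <- my[nb] + (my[nb] - my[nb - 1]) / (mx[nb] - mx[nb - 1]) *
      (x[hi] - mx[nb])
  h2 <- 1 - sum((y - f)^2) / sse0
  min(max(h2, 0), 1)
}

#' Nonlinear h2 association index
#'
#' Fraction of the variance of one signal explained by a piecewise-linear
#' regression curve on the other: the curve interpolates the per-bin means of
#' `y` over `n_bins` equal-count bins of `x` (end segments extended linearly
#' beyond the outer bin centres, so exact linear dependence scores 1). The index is symmetrized as the maximum over both
#' directions and clipped to `[0, 1]`. Unlike the Pearson coefficient it
#' captures nonlinear (e.g. quadratic) dependence.
#'
#' @param x,y Numeric vectors of equal length, at least `10 * n_bins`;
#'   `x` must not be constant.
#' @param n_bins Number of equal-count bins (default 10, minimum 2).
#' @return The association, a value in `[0, 1]`.
#' @export
h2_association <- function(x, y, n_bins = 10L) {
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 10L * n_bins)
    stop("need at least 10 * n_bins = ", 10L * n_bins, " samples")
  if (sd(x) == 0) stop("degenerate input: `x` is constant")
  if (sd(y) == 0) return(0)
  max(h2_directional(x, y, n_bins), h2_directional(y, x, n_bins))
}

# Association value (|rho| or h2) for one subsegment matrix, all channel
# pairs at once; returns the P-vector of upper-triangle values.
pair_associations <- function(m, measure, n_bins) {
  if (measure == "pearson") {
    r <- abs(suppressWarnings(cor(t(m))))
    r[upper.tri(r)]
  } else {
    n <- nrow(m)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    apply(idx, 1L, function(p) h2_association(m[p[1], ], m[p[2], ], n_bins))
  }
}

#' Per-pair association samples from a subsegment ensemble
#'
#' Evaluates the association measure on every channel pair for each of the 10
#' original subsegments and each of the 100 surrogate subsegments, producing
#' the original-vs-surrogate samples that feed the significance test.
#'
#' @param ensemble Output of [make_subsegments()].
#' @param measure `"pearson"` or `"h2"`.
#' @param n_bins Bin count for the h2 index.
#' @return A list with `pairs` (P x 2 index matrix), `rho0` (P x 10 matrix),
#'   `rhosurr` (P x 100 matrix), `n_channels` and `measure`.
#' @export
association_samples <- function(ensemble, measure = c("pearson", "h2"),
                                n_bins = 10L) {
  measure <- match.arg(measure)
  n <- nrow(ensemble$original[[1L]])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rho0 <- vapply(ensemble$original, pair_associations,
                 numeric(nrow(pairs)), measure = measure, n_bins = n_bins)
  rhosurr <- vapply(ensemble$surrogate, pair_associations,
                    numeric(nrow(pairs)), measure = measure, n_bins = n_bins)
  if (nrow(pairs) == 1L) { # vapply drops to vectors for a single pair
    rho0 <- matrix(rho0, nrow = 1L)
    rhosurr <- matrix(rhosurr, nrow = 1L)
  }
  list(pairs = unname(pairs), rho0 = rho0, rhosurr = rhosurr,
       n_channels = n, measure = measure)
}

#' Mann-Whitney U test wrapper
#'
#' Rank-sum comparison of two samples, exact when both samples are small and
#' tie-free, otherwise the normal approximation with tie correction (the
#' behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (of `x` relative
#'   to `y`).
#' @return List with `statistic` (the U of `x`) and `p.value`.
#' @export
u_test <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(unique(c(x, y))) == 1L) # complete ties carry no evidence
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  w <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
  list(statistic = unname(w$statistic), p.value = w$p.value)
}

#' Surrogate significance mask
#'
#' One-sided Mann-Whitney U test per channel pair (alternative: original
#' associations stochastically larger than surrogate associations), followed
#' by Bonferroni-Holm step-down over all pairs. Pairs whose associations are
#' undefined (all `NA`) are excluded from the family and never flagged.
#'
#' @param samples Output of [association_samples()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Symmetric binary N x N matrix `s` with `s[i, j] = 1` iff the pair
#'   is significant; attribute `"p_values"` carries the per-pair raw
#'   p-values.
#' @export
surrogate_significance <- function(samples, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  P <- nrow(samples$pairs)
  if (is.null(P) || P < 1L || nrow(samples$rho0) != P ||
      nrow(samples$rhosurr) != P)
    stop("`samples` must contain one association sample per channel pair")
  pvals <- rep(NA_real_, P)
  for (p in seq_len(P)) {
    x <- samples$rho0[p, ]
    y <- samples$rhosurr[p, ]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 1L || length(y) < 1L) next
    pvals[p] <- u_test(x, y, alternative = "greater")$p.value
  }
  rej <- rep(FALSE, P)
  ok <- which(is.finite(pvals))
  if (length(ok)) rej[ok] <- p.adjust(pvals[ok], method = "holm") <= alpha
  s <- matrix(0, samples$n_channels, samples$n_channels)
  s[samples$pairs] <- as.numeric(rej)
  s <- s + t(s)
  attr(s, "p_values") <- pvals
  s
}

#' Surrogate-corrected functional connectivity
#'
#' Builds the corrected FC matrix from the per-pair association samples and
#' the significance mask. For the Pearson measure the corrected weight is
#' `C = max(0, (rho0 - rhosurr) / (1 - rhosurr)) * s`, with `rho0` and
#' `rhosurr` summarized as the medians of the 10 original and 100 surrogate
#' associations; for the h2 measure the weight is `H = h2 * s` with `h2` the
#' median original index. Pairs with a degenerate denominator
#' (`rhosurr = 1`) get weight 0.
#'
#' @param samples Output of [association_samples()].
#' @param s Significance mask from [surrogate_significance()].
#' @return An `"fc_network"`: list with `weights` (symmetric, zero diagonal,
#'   entries in `[0, 1]`), `significance`, `measure`.
#' @export
corrected_fc <- function(samples, s) {
  n <- samples$n_channels
  if (!is.matrix(s) || any(dim(s) != n))
    stop("`s` must be an N x N mask matching the samples")
  w <- matrix(0, n, n)
  rho0 <- apply(samples$rho0, 1L, median)
  rhosurr <- apply(samples$rhosurr, 1L, median)
  for (p in seq_len(nrow(samples$pairs))) {
    i <- samples$pairs[p, 1L]; j <- samples$pairs[p, 2L]
    if (s[i, j] == 0) next
    if (samples$measure == "pearson") {
      if (1 - rhosurr[p] <= .Machine$double.eps) {
        warning("rhosurr = 1 for pair (", i, ",", j, "); weight set to 0",
                call. = FALSE)
        next
      }
      w[i, j] <- max(0, (rho0[p] - rhosurr[p]) / (1 - rhosurr[p]))
    } else {
      w[i, j] <- rho0[p]
    }
  }
  w <- w + t(w)
  fc_network(w, measure = samples$measure, significance = s)
}

#' FC network container
#'
#' @param weights Symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @param measure `"pearson"` (matrix C) or `"h2"` (matrix H).
#' @param significance Optional binary significance mask.
#' @return An object of class `"fc_network"`.
#' @export
fc_network <- function(weights, measure = "pearson", significance = NULL) {
  check_weight_matrix(weights)
  if (any(weights > 1 + 1e-12))
    stop("FC weights must lie in [0, 1]")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("FC weights must be symmetric")
  structure(list(weights = weights, measure = measure,
                 significance = significance),
            class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<fc_network> %d nodes, %d significant edges, measure = %s\n",
              nrow(x$weights), nz, x$measure))
  invisible(x)
}

#' Full FC inference for one segment
#'
#' Runs the complete surrogate-correction protocol on an 8 s segment:
#' IAAFT surrogates per channel, subsegment ensembles, per-pair association
#' samples, one-sided U tests with Holm correction, and the corrected FC
#' matrix.
#'
#' @param seg A `"segment"` (from [segment_peri_ictal()]) or a
#'   channels-x-samples matrix (then `fs` is required).
#' @param fs Sampling rate in Hz (taken from the segment when available).
#' @param measure `"pearson"` or `"h2"`.
#' @param n_surrogates Surrogates per channel (default 10).
#' @param alpha Family-wise significance level.
#' @param seed Optional integer seed for the surrogate generation.
#' @param n_bins Bin count for the h2 index.
#' @return An `"fc_network"`.
#' @export
segment_fc <- function(seg, fs = NULL, measure = c("pearson", "h2"),
                       n_surrogates = 10L, alpha = 0.05, seed = NULL,
                       n_bins = 10L) {
  measure <- match.arg(measure)
  if (inherits(seg, "segment")) {
    data <- seg$data; fs <- seg$fs
  } else {
    data <- seg
    if (is.null(fs)) stop("`fs` is required when `seg` is a bare matrix")
  }
  n <- nrow(data)
  # one surrogate version of the whole multichannel segment per draw:
  # every channel surrogated independently
  sur_per_channel <- lapply(seq_len(n), function(ch)
    iaaft_surrogates(data[ch, ], n_surrogates, seed = derive_seed(seed, ch)))
  surrogates <- lapply(seq_len(n_surrogates), function(k)
    do.call(rbind, lapply(sur_per_channel, `[[`, k)))
  seg_obj <- if (inherits(seg, "segment")) seg else
    structure(list(data = data, start_s = 0, end_s = ncol(data) / fs,
                   epoch_label = NA_character_, fs = fs), class = "segment")
  ens <- make_subsegments(seg_obj, surrogates)
  samples <- association_samples(ens, measure = measure, n_bins = n_bins)
  s <- surrogate_significance(samples, alpha = alpha)
  corrected_fc(samples, s)
}

#' Read and write FC networks
#'
#' The matrix is stored as a tab-separated N x N table; a JSON sidecar
#' carries the measure and any metadata passed through `meta`.
#'
#' @param net An `"fc_network"`.
#' @param path Matrix file path; the sidecar is `paste0(path, ".json")`.
#' @param meta Optional named list written into the sidecar.
#' @return `write_fc()` returns `path` invisibly; `read_fc()` an
#'   `"fc_network"`.
#' @export
write_fc <- function(net, path, meta = list()) {
  stopifnot(inherits(net, "fc_network"))
  utils::write.table(net$weights, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- c(list(measure = net$measure), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(w) <- NULL
  side <- paste0(path, ".json")
  measure <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)$measure else "pearson"
  fc_network(w, measure = measure)
}
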