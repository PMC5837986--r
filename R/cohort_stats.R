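# Cohort-level statistics: epoch comparison, per-subject elevated-ictal
# classification, permutation chi-square against outcome, ROC/AUC.

#' Kruskal-Wallis comparison of peri-ictal epochs
#'
#' Rank-based comparison of BNI values pooled by epoch (pre-ictal, ictal,
#' post-ictal), with tie correction; the p-value uses the chi-square
#' approximation with 2 degrees of freedom.
#'
#' @param pre,ictal,post Numeric vectors of BNI values, each nonempty.
#' @return List with `statistic` (H), `p.value` and `df`.
#' @export
kruskal_wallis_epochs <- function(pre, ictal, post) {
  groups <- list(pre = pre, ictal = ictal, post = post)
  if (any(!vapply(groups, length, integer(1))))
    stop("every epoch group must be nonempty")
  vals <- unlist(groups)
  if (length(unique(vals)) < 2L)
    stop("degenerate input: all values identical")
  kw <- kruskal.test(groups)
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       df = unname(kw$parameter))
}

#' Per-subject elevated-ictal classification
#'
#' For each peri-ictal epoch, a one-tailed Mann-Whitney U test of whether the
#' ictal BNI values are stochastically larger than the pre-ictal values. A
#' subject is flagged `elevated_ictal` only if the test is significant in
#' every epoch independently.
#'
#' @param epochs List of epochs; each element a list with numeric vectors
#'   `pre` and `ictal` (each with at least 3 values).
#' @param alpha Per-epoch significance level (default 0.05; a test with
#'   p exactly equal to `alpha` is flagged).
#' @return List with `epoch_flags`, `p_values` and `elevated_ictal`.
#' @export
elevated_ictal_test <- function(epochs, alpha = 0.05) {
  if (!length(epochs)) stop("at least one epoch is required")
  p_values <- vapply(epochs, function(e) {
    if (length(e$pre) < 3L || length(e$ictal) < 3L)
      stop("insufficient data: each epoch needs >= 3 pre-ictal and >= 3 ",
           "ictal BNI values")
    u_test(e$ictal, e$pre, alternative = "greater")$p.value
  }, numeric(1))
  flags <- p_values <= alpha
  list(epoch_flags = flags, p_values = p_values,
       elevated_ictal = all(flags))
}

# Pearson chi-square statistic of a 2x2 table, no continuity correction.
chisq_stat_2x2 <- function(a, ke, ng, n) {
  # a = elevated & good; margins: ke elevated, ng good, n total
  o <- c(a, ke - a, ng - a, n - ke - ng + a)
  e <- c(ke * ng, ke * (n - ng), (n - ke) * ng, (n - ke) * (n - ng)) / n
  sum((o - e)^2 / e)
}

#' Permutation chi-square for elevated-ictal vs outcome
#'
#' Observed statistic: Pearson chi-square of the 2 x 2 table crossing the
#' elevated-ictal flag with the dichotomized outcome. The null is built from
#' random reassignments of the elevated labels across subjects (preserving
#' their total count); the p-value uses the add-one convention
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param elevated Logical vector, one flag per subject.
#' @param outcome Logical vector (`TRUE` = good outcome) or factor/character
#'   with values `"good"`/`"poor"`.
#' @param n_perm Number of random reassignments (default 10000).
#' @param seed Optional integer seed.
#' @return List with `p.value`, `statistic` (observed chi-square) and
#'   `table` (the observed 2 x 2 table).
#' @export
permutation_chi_square <- function(elevated, outcome, n_perm = 10000L,
                                   seed = NULL) {
  elevated <- as.logical(elevated)
  if (!is.logical(outcome)) outcome <- as.character(outcome) == "good"
  if (length(elevated) != length(outcome) || anyNA(elevated) || anyNA(outcome))
    stop("`elevated` and `outcome` must be complete and of equal length")
  n <- length(elevated)
  ke <- sum(elevated); ng <- sum(outcome)
  if (ke == 0L || ke == n || ng == 0L || ng == n)
    stop("degenerate table: a margin of the 2 x 2 table is zero")
  if (min(ng, n - ng) < 2L)
    stop("need at least 2 subjects per outcome category")
  obs_a <- sum(elevated & outcome)
  obs <- chisq_stat_2x2(obs_a, ke, ng, n)
  null_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, ke)
    chisq_stat_2x2(sum(outcome[idx]), ke, ng, n)
  }, numeric(1)))
  p <- (1 + sum(null_stats >= obs - 1e-12)) / (n_perm + 1)
  tab <- matrix(c(obs_a, ke - obs_a, ng - obs_a, n - ke - ng + obs_a),
                2L, 2L,
                dimnames = list(elevated = c("yes", "no"),
                                outcome = c("good", "poor")))
  list(p.value = p, statistic = obs, table = tab)
}

#' ROC area under the curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' good-outcome score exceeds a randomly chosen poor-outcome score, counting
#' ties as one half.
#'
#' @param scores Numeric classifier scores (higher = predicts good outcome).
#' @param labels Logical (`TRUE` = good) or `"good"`/`"poor"` vector; both
#'   classes must be present.
#' @return The AUC, a value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "good"
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

half_split_aucs <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "good"
  n <- length(scores)
  if (n < 4L) stop("insufficient data: a group needs at least 4 subjects")
  splits <- combn(n, floor(n / 2))
  aucs <- apply(splits, 2L, function(idx) {
    l <- labels[idx]
    if (!any(l) || all(l)) return(NA_real_)
    roc_auc(scores[idx], l)
  })
  aucs <- aucs[!is.na(aucs)]
  if (!length(aucs))
    stop("insufficient data: no half-split contains both outcome classes")
  aucs
}

#' Half-group-splitting AUC comparison
#'
#' For each group, enumerates all subsets of size `floor(n/2)` containing
#' both outcome classes and computes the AUC on each, giving a distribution
#' of AUC values per group; the two distributions are then compared with a
#' two-sided Mann-Whitney U test.
#'
#' @param scores_a,labels_a Scores and labels of the first group.
#' @param scores_b,labels_b Scores and labels of the second group.
#' @return List with `auc_a`, `auc_b` (full-group AUCs), `dist_a`, `dist_b`
#'   (half-split AUC distributions) and `p.value`.
#' @export
half_split_auc_compare <- function(scores_a, labels_a, scores_b, labels_b) {
  dist_a <- half_split_aucs(scores_a, labels_a)
  dist_b <- half_split_aucs(scores_b, labels_b)
  p <- u_test(dist_a, dist_b, alternative = "two.sided")$p.value
  list(auc_a = roc_auc(scores_a, labels_a),
       auc_b = roc_auc(scores_b, labels_b),
       dist_a = dist_a, dist_b = dist_b, p.value = p)
}
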