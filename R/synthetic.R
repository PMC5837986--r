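# Ground-truthed synthetic peri-ictal cohorts: switched VAR(1) recordings
# with an ictogenic core, resection masks and outcome labels.

#' Synthetic cohort specification
#'
#' Describes a cohort of synthetic subjects. Each subject has a random
#' background coupling graph, a designated ictogenic core, and two peri-ictal
#' recordings. Signals follow a first-order vector autoregression whose
#' coupling matrix switches between epochs: during the ictal epoch of
#' "responder" subjects, core-core couplings are multiplied by
#' `ictal_boost`, so their ictal functional connectivity is genuinely
#' elevated. Resection masks either cover the core (intended good outcome)
#' or largely miss it (intended poor outcome).
#'
#' @param n_subjects Number of subjects (default 16).
#' @param n_channels Channels per subject (default 20).
#' @param fs Sampling rate in Hz (default 512).
#' @param core_size Number of ictogenic-core channels (default 5).
#' @param preictal_s,postictal_s Pre-/post-ictal durations in seconds
#'   (default 180, the 3-minute protocol).
#' @param ictal_range_s Range (uniform) of seizure durations in seconds
#'   (default 60-120).
#' @param coupling_base Off-diagonal VAR coupling on background edges
#'   (default 0.15).
#' @param ictal_boost Multiplier on core-core couplings during the ictal
#'   epoch of responders (default 2.5; 1 disables the effect).
#' @param responder_fraction Fraction of subjects whose ictal coupling is
#'   boosted (default 0.5).
#' @param edge_density Background graph edge density (default 0.2).
#' @param ar_diag Diagonal of the VAR matrix (default 0.5).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param max_spectral_radius Stability bound; every epoch's VAR matrix is
#'   rescaled to this spectral radius when it exceeds it (default 0.95).
#' @param seed Master seed for the cohort.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 16L, n_channels = 20L, fs = 512,
                           core_size = 5L, preictal_s = 180,
                           ictal_range_s = c(60, 120), postictal_s = 180,
                           coupling_base = 0.15, ictal_boost = 2.5,
                           responder_fraction = 0.5, edge_density = 0.2,
                           ar_diag = 0.5, noise_sd = 1,
                           max_spectral_radius = 0.95, seed = 1L) {
  if (core_size >= n_channels)
    stop("invalid spec: core must be a strict subset of the channels")
  if (ictal_boost < 1) stop("`ictal_boost` must be >= 1")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must be in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    fs = fs, core_size = as.integer(core_size), preictal_s = preictal_s,
    ictal_range_s = ictal_range_s, postictal_s = postictal_s,
    coupling_base = coupling_base, ictal_boost = ictal_boost,
    responder_fraction = responder_fraction, edge_density = edge_density,
    ar_diag = ar_diag, noise_sd = noise_sd,
    max_spectral_radius = max_spectral_radius, seed = seed),
    class = "synthetic_spec")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# VAR coupling matrix for one epoch of one subject.
epoch_var_matrix <- function(spec, background, core_nodes, ictal, responder) {
  A <- background * spec$coupling_base
  if (ictal && responder && length(core_nodes) > 1L)
    A[core_nodes, core_nodes] <- A[core_nodes, core_nodes] * spec$ictal_boost
  diag(A) <- spec$ar_diag
  r <- spectral_radius(A)
  if (r >= spec$max_spectral_radius)
    A <- A * (spec$max_spectral_radius / r)
  if (spectral_radius(A) >= 1) stop("generation error: unstable VAR matrix")
  A
}

# Per-subject structural draw: background graph, core, resection mask and
# intended outcome. Consumes the current RNG stream.
draw_subject <- function(spec, responder, good_outcome) {
  n <- spec$n_channels
  bg <- matrix(0, n, n)
  idx <- which(upper.tri(bg))
  bg[idx[runif(length(idx)) < spec$edge_density]] <- 1
  bg <- bg + t(bg)
  core <- sort(sample.int(n, spec$core_size))
  # the ictogenic core is a fully coupled subnetwork
  bg[core, core] <- 1
  diag(bg) <- 0
  if (good_outcome) {
    mask <- core
  } else {
    # overlap strictly below 40% of the core size
    max_overlap <- ceiling(0.4 * spec$core_size) - 1L
    k_overlap <- if (max_overlap > 0L) sample.int(max_overlap + 1L, 1L) - 1L
                 else 0L
    mask <- sort(c(if (k_overlap > 0L) sample(core, k_overlap),
                   sample(setdiff(seq_len(n), core),
                          spec$core_size - k_overlap)))
  }
  engel <- if (good_outcome) sample(c("I", "II"), 1L)
           else sample(c("III", "IV"), 1L)
  list(core_nodes = core, background = bg, responder = responder,
       resection_mask = mask, good_outcome = good_outcome,
       engel_class = engel)
}

#' Generate one synthetic peri-ictal recording
#'
#' Simulates the three epochs (pre-ictal, ictal, post-ictal) of one subject
#' with the epoch-appropriate VAR coupling matrices, concatenates them, and
#' attaches the epoch annotations. The seizure duration is drawn uniformly
#' from `spec$ictal_range_s`. Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param subject A ground-truth structure (fields `background`,
#'   `core_nodes`, `responder`), as produced inside [generate_cohort()].
#' @param seed Integer seed for this recording.
#' @return A [recording()] with annotations.
#' @export
generate_recording <- function(spec, subject, seed) {
  with_seed(seed, {
    ictal_s <- round(runif(1, spec$ictal_range_s[1], spec$ictal_range_s[2]))
    durations <- c(spec$preictal_s, ictal_s, spec$postictal_s)
    is_ictal <- c(FALSE, TRUE, FALSE)
    x0 <- rep(0, spec$n_channels)
    chunks <- vector("list", 3L)
    for (e in 1:3) {
      A <- epoch_var_matrix(spec, subject$background, subject$core_nodes,
                            is_ictal[e], subject$responder)
      m <- var1_sim_cpp(A, x0, spec$noise_sd,
                        as.integer(durations[e] * spec$fs))
      x0 <- m[, ncol(m)]
      chunks[[e]] <- m
    }
    ann <- epoch_annotation(0, spec$preictal_s, spec$preictal_s + ictal_s,
                            sum(durations))
    recording(do.call(cbind, chunks), fs = spec$fs, annotations = ann)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws the per-subject structure (background graph, ictogenic core,
#' responder flag, resection mask, outcome label) and, unless
#' `recordings = FALSE`, the two peri-ictal recordings per subject.
#' Responders are assigned in the stated fraction; within responders and
#' non-responders alike, half the subjects get a core-covering mask
#' (intended good outcome, Engel I/II) and half a core-missing mask
#' (intended poor outcome, Engel III/IV).
#'
#' @param spec A [synthetic_spec()].
#' @param recordings If `FALSE`, only ground-truth structures are returned
#'   (recordings can then be generated lazily with
#'   [generate_subject_recordings()], keeping memory use flat).
#' @return List of subjects; each has `subject_id`, `ground_truth`,
#'   `recording_seeds`, and (optionally) `recordings` (list of 2).
#' @export
generate_cohort <- function(spec, recordings = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects
  n_resp <- round(n * spec$responder_fraction)
  subjects <- with_seed(spec$seed, {
    responder <- sample(rep(c(TRUE, FALSE), c(n_resp, n - n_resp)))
    good <- logical(n)
    for (grp in c(TRUE, FALSE)) {
      idx <- which(responder == grp)
      if (length(idx)) good[sample(idx, ceiling(length(idx) / 2))] <- TRUE
    }
    lapply(seq_len(n), function(i)
      list(subject_id = sprintf("S%02d", i),
           ground_truth = draw_subject(spec, responder[i], good[i]),
           recording_seeds = c(derive_seed(spec$seed, 100L * i + 1L),
                               derive_seed(spec$seed, 100L * i + 2L))))
  })
  if (recordings)
    subjects <- lapply(subjects, function(s) {
      s$recordings <- generate_subject_recordings(spec, s)
      s
    })
  subjects
}

#' @rdname generate_cohort
#' @param subject One element of the list returned by
#'   `generate_cohort(spec, recordings = FALSE)`.
#' @export
generate_subject_recordings <- function(spec, subject) {
  lapply(subject$recording_seeds, function(sd)
    generate_recording(spec, subject$ground_truth, seed = sd))
}

#' Ground-truth table of a cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return A data frame with one row per subject: `subject_id`, `responder`,
#'   `good_outcome`, `engel_class`, `core_nodes` and `resection_mask`
#'   (comma-separated).
#' @export
cohort_ground_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    gt <- s$ground_truth
    data.frame(subject_id = s$subject_id, responder = gt$responder,
               good_outcome = gt$good_outcome, engel_class = gt$engel_class,
               core_nodes = paste(gt$core_nodes, collapse = ","),
               resection_mask = paste(gt$resection_mask, collapse = ","))
  }))
}
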