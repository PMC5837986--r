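# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a master seed and a stream index; keeps
# every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483629L)
}

stop_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

is_square_weight_matrix <- function(a) {
  is.matrix(a) && nrow(a) == ncol(a) && is.numeric(a)
}

check_weight_matrix <- function(a) {
  if (!is_square_weight_matrix(a))
    stop("adjacency must be a square numeric matrix", call. = FALSE)
  if (nrow(a) < 1L) stop("adjacency must have at least one node", call. = FALSE)
  if (any(!is.finite(a))) stop("adjacency contains non-finite weights", call. = FALSE)
  if (any(a < 0)) stop("adjacency weights must be nonnegative", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal", call. = FALSE)
  invisible(a)
}
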