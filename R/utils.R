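# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-patient sub-seed: independent of cohort size, so adding
# patients never perturbs existing ones. Kept inside 32-bit integer range.
patient_seed <- function(master_seed, patient_index) {
  as.integer((as.numeric(master_seed) %% 1e6L) * 1009 +
               patient_index * 97L + 12345) %% 2147483647L
}

# Coerce points to an n x 3 numeric matrix (accepts length-3 vectors).
as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    p <- matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 3L)
    storage.mode(p) <- "double"
  }
  p
}

vnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
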