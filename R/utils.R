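# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and a stream index.
# Double arithmetic keeps the product exact (< 2^53) and avoids integer
# overflow when chaining derived seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(is.finite(x))) {
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  }
  x
}

check_labels <- function(labels, C) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers", call. = FALSE)
  if (any(labels < 1L) || any(labels > C)) {
    stop("labels must lie in 1..", C, call. = FALSE)
  }
  labels
}
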