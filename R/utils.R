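#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from a single root seed. Each consumer
#' (train/test split, bootstrap cell sample, per-iteration cell sampling,
#' baseline draws, the simulator) derives its own stream seed so that changing
#' one stage never perturbs another.
#'
#' @param seed integer root seed.
#' @param stream character stream name, e.g. `"split"`, `"cells"`.
#' @param iter optional non-negative integer (e.g. iteration number) folded
#'   into the derivation.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream, iter = 0L) {
  stopifnot(is.character(stream), length(stream) == 1L)
  ch <- utf8ToInt(stream)
  h <- sum(as.double(ch) * seq_along(ch))
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                h * 9973 + as.double(iter) * 7919) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Validate an integer class-label vector; returns sorted distinct classes.
label_classes <- function(labels) {
  if (anyNA(labels)) stop("labels must not contain NA")
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L)
    stop("labels must contain at least two distinct classes")
  cls
}
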