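# Internal helpers shared across modules.

# Classed errors so the CLI can map conditions to exit codes
# (config -> 2, data -> 3, numeric -> 4).
abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "triagerec_config_error", field = field)
}
abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "triagerec_data_error", ...)
}
abort_numeric <- function(msg, ...) {
  rlang::abort(msg, class = "triagerec_numeric_error", ...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Run an expression with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' All randomized stages of the pipeline draw their own seed from one master
#' seed through this fixed affine-mod rule, so that a single `--seed` makes
#' every stage reproducible while stages remain statistically decoupled.
#'
#' @param master Master seed (integer).
#' @param stage Stage name; one of the documented pipeline stages.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, "clustering")
split_seed <- function(master, stage) {
  stages <- c(
    "generate" = 1L, "split" = 2L, "clustering" = 3L, "als" = 4L,
    "evaluation" = 5L, "misc" = 6L
  )
  if (!stage %in% names(stages)) {
    abort_config(paste0("unknown pipeline stage '", stage, "'"), field = "stage")
  }
  if (!is_count(master, min = 0L)) {
    abort_config("`master` seed must be a single non-negative integer", field = "seed")
  }
  # 2147483629 is prime and below .Machine$integer.max
  as.integer((as.numeric(master) * 7919 + 104729 * stages[[stage]]) %% 2147483629)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
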