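# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  code
}

#' Derive a deterministic child seed from a master seed
#'
#' The package draws every random component (genome, plants, breaks, each
#' null-model iteration) from its own child stream so components can be
#' regenerated independently and in any order. The map is a fixed linear
#' congruential hash; results stay inside the 32-bit integer range R's
#' `set.seed()` accepts.
#'
#' @param master master seed (integer-valued).
#' @param index non-negative stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1)
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  as.integer(((abs(as.numeric(master)) %% m) * 48271 +
                (as.numeric(index) %% m) * 16807 + 1) %% m)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}
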