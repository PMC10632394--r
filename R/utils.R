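#' @importFrom stats rnorm rbinom rnbinom runif coef lm.fit median quantile
#'   prcomp sd var cor pt setNames
#' @importFrom utils head read.delim write.table
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Counter-based derived seed: reproducible per (master seed, stream id)
# independent of execution order; kept strictly inside 32-bit integer range.
derive_seed <- function(seed, id) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 69069 + 104729 * as.numeric(id) + 1) %% 2147483647)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

spectral_radius <- function(m) {
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

as_matrix <- function(x, what = "matrix") {
  x <- as.matrix(x)
  abort_if(!is.numeric(x), paste(what, "must be numeric"))
  x
}
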