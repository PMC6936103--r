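#' Derive a deterministic substream seed
#'
#' Every stochastic unit of the simulator (one transcript, one
#' sample/replicate track, one gene) draws its random numbers under its own
#' seed derived from the master seed and a small integer index path.  Adding
#' or removing transcripts therefore does not perturb the random draws of
#' the others.
#'
#' @param master integer master seed.
#' @param ... integer index components (stream ids, transcript index,
#'   replicate number, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, ...) {
  parts <- c(master, unlist(list(...)))
  h <- 0
  for (v in parts) {
    h <- (h * 69069 + as.numeric(v) + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}
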