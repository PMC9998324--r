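#' @keywords internal
"_PACKAGE"

#' @useDynLib arvcmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rnorm runif rbinom rmultinom sd cor qnorm
#'   pnorm binom.test mcnemar.test setNames
#' @importFrom utils head tail
NULL

# label codes of the segmentation maps
LV_LABEL <- 1L
RV_LABEL <- 2L

structure_label <- function(structure) {
  structure <- match.arg(toupper(structure), c("LV", "RV"))
  if (structure == "LV") LV_LABEL else RV_LABEL
}

#' Draw reproducible sub-seeds from a master seed
#'
#' Streams of per-subject random draws are decoupled by giving every
#' subject its own integer seed, all derived deterministically from one
#' master seed. Seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a local RNG seed
#'
#' The global RNG state is saved, the seed set, the expression evaluated,
#' and the previous state restored, so package internals never perturb the
#' caller's random stream.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise
sample_exact <- function(x, size) {
  if (length(x) == 1L) return(rep(x, length.out = size))
  sample(x, size)
}
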