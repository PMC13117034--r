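# Shared numerical helpers and seed-stream plumbing.

#' Numerically stable softmax
#'
#' @param x numeric vector of logits.
#' @return nonnegative vector summing to 1.
#' @export
softmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  e <- exp(x - max(x))
  e / sum(e)
}

#' Logistic sigmoid
#'
#' @param x numeric.
#' @return 1 / (1 + exp(-x)), elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

abort_domain <- function(...) stop(paste0(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort_domain(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

#' Derive a named sub-stream seed from a global seed
#'
#' One global integer seed drives every stochastic component; each component
#' draws from its own stream derived from the pair (seed, stream name), so
#' adding a component never perturbs the draws of another.
#'
#' @param seed integer global seed.
#' @param name character stream name.
#' @return integer in [0, 2^31 - 2], usable with [set.seed()].
#' @export
stream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(stream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# round-half-up for positive values (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)
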