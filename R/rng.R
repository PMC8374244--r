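# Named independent random-number substreams.
#
# One master seed spawns a fixed set of named substreams (synthesis,
# demography, yields, labour, livestock, scenario).  Each substream keeps its
# own .Random.seed state, so a change in one sub-model's consumption of
# random numbers does not perturb the draws of the others.

STREAM_NAMES <- c("synthesis", "demography", "yields", "labour",
                  "livestock", "scenario", "misc")

#' Create named RNG substreams from a master seed
#'
#' @param seed Master integer seed.
#' @param names Stream names.
#' @return An environment mapping names to saved RNG states.
#' @export
make_rng_streams <- function(seed, names = STREAM_NAMES) {
  streams <- new.env(parent = emptyenv())
  old <- get_random_seed()
  on.exit(restore_random_seed(old))
  for (k in seq_along(names)) {
    sub <- (abs(as.integer(seed)) + 100003L * k) %% .Machine$integer.max
    set.seed(sub)
    assign(names[k], get(".Random.seed", envir = globalenv()), envir = streams)
  }
  streams
}

get_random_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_random_seed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Evaluate an expression under a named substream
#'
#' Swaps the substream's saved state into the global RNG, evaluates, and
#' saves the advanced state back, restoring whatever state the caller had.
#'
#' @param streams Environment from [make_rng_streams()].
#' @param name Stream name.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
with_stream <- function(streams, name, expr) {
  if (!exists(name, envir = streams, inherits = FALSE))
    stop("unknown RNG stream: ", name)
  old <- get_random_seed()
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    restore_random_seed(old)
  })
  expr
}
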