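#' @keywords internal
"_PACKAGE"

## Deterministic sub-stream seeding -----------------------------------------
##
## Every stochastic operation draws from its own named sub-stream derived by
## hashing (name, seed[, year]).  Adding a generator or toggling one process
## therefore never perturbs the draws of another.

#' Derive a reproducible sub-stream seed
#'
#' Hashes a stream name together with a base seed (and an optional epoch such
#' as a simulation year) into an integer seed below 2^31.  Used internally so
#' that each stochastic operation owns an independent, stable random stream.
#'
#' @param name character scalar naming the stream (e.g. `"mortality"`).
#' @param seed integer base seed.
#' @param epoch optional integer (e.g. simulation year) mixed into the hash.
#' @return a single integer suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(name, seed, epoch = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647   # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% m
  if (!is.null(epoch)) h <- (h * 31 + as.numeric(epoch) %% m) %% m
  as.integer(h)
}

## evaluate `expr` under a named sub-stream, restoring the caller's RNG state
with_substream <- function(name, seed, epoch = NULL, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(name, seed, epoch))
  expr
}

## argument checking helpers -------------------------------------------------
stop_input <- function(...) {
  stop(structure(class = c("fc_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    stop_input(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_input(name, " must be >= ", lower)
  if (x > upper)
    stop_input(name, " must be <= ", upper)
  invisible(x)
}
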