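#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' run seed plus the stage name, so inserting or reordering a stage never
#' silently shifts the random stream of the stages downstream of it.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by the Lehmer generator
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## data.frame constructor without the checking overhead of data.frame();
## used in the per-trace hot path
quick_df <- function(lst) {
  n <- length(lst[[1]])
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

## runs a block under a local RNG state so simulators never disturb the
## caller's random stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
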