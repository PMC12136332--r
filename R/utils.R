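## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so library code never disturbs user-level randomness.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## One structured log line per pipeline stage; suppressed unless verbose.
stageLog <- function(verbose, stage, ...) {
  if (isTRUE(verbose))
    message(sprintf("[dwgnn] %s: %s", stage, sprintf(...)))
  invisible(NULL)
}

symmetrize <- function(m) (m + t(m)) / 2
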