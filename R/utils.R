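# Small internal helpers shared across modules.

# Round half away from zero for non-negative row positions (base round() is
# round-half-even, which would make boundary rasterisation data-dependent).
round_half_up <- function(x) floor(x + 0.5)

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_octseg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mirror (symmetric) reflection of 0-based indices into [0, n - 1].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n
  i <- i %% period
  i <- ifelse(i < 0L, i + period, i)
  ifelse(i >= n, period - 1L - i, i)
}
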