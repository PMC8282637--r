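#' Derive a reproducible substream seed
#'
#' All randomness in a benchmark run descends from a single master seed.
#' Named substreams (scatterer generation, per-algorithm photon noise,
#' algorithm-internal randomness) get their own 32-bit seeds derived
#' deterministically from the master seed, a text label and an index, so
#' that every algorithm compared within one trial sees the identical
#' scatterer but an independent shot-noise stream.
#'
#' @param seed master integer seed.
#' @param label character substream label, e.g. `"scatterer"` or an
#'   algorithm name.
#' @param index integer substream index (e.g. the trial number).
#' @return A single integer in `[0, 2^31 - 94]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "scatterer", 3)
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483563  # large prime below 2^31
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  h <- (h * 31 + as.numeric(index) + 1) %% m
  as.integer(h)
}

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls do not perturb user sessions.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
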