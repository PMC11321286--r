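# Seed handling: one master seed spawns named substreams so each pipeline
# stage (cohort generation, validation sampling, bootstrap) is independently
# reproducible. The substream seed is a deterministic 31-bit hash of the
# master seed and the stream name; the caller's RNG state is saved and
# restored so library code never perturbs user randomness.

substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

substream_rng <- function(seed, name) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# round half away from zero (R's round() is half-to-even); matches the
# whole-percent presentation used in clinical reporting
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
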