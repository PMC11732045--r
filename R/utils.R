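# Seed hygiene: generators are pure functions of (spec, seed) and must not
# disturb the caller's RNG stream.

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic sub-seed in [0, 2^31): distinct salts give independent-ish
# streams from one user-facing seed.
.mix_seed <- function(seed, salt) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + salt) %% 2147483647)
}
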