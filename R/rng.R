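# Per-entity keyed random streams.
#
# Every simulated entity (protein, guide, sample) draws from its own stream,
# keyed by (global seed, stream id, entity index). Adding entities to a
# configuration therefore never perturbs the draws of existing ones, which
# keeps incremental fixtures reproducible.

.RNG_MOD <- 2147483647  # 2^31 - 1; keyed seeds stay valid 32-bit integers

.streamSeed <- function(seed, stream, index) {
  s <- as.double(seed) %% .RNG_MOD
  as.integer((s * 48271 + as.double(stream) * 1000003 +
                as.double(index) * 7919) %% .RNG_MOD)
}

# Evaluate expr under the stream's seed; caller RNG state is untouched.
.withStream <- function(seed, stream, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.streamSeed(seed, stream, index))
  expr
}
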