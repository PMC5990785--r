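# Deterministic child seeds: every component draws from its own stream so
# that changing, say, the number of permutations never reshuffles the
# random selections. Plain 32-bit mixing, exact in double arithmetic.
child_seed <- function(seed, tag, i = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (((seed %% 2147483647) * 69069) %% 2147483647 +
     (h * 7919) %% 2147483647 +
     (i * 104729) %% 2147483647) %% 2147483647
}

# sample() without the scalar-x surprise: always samples from the set x
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
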