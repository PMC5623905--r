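## Deterministic random streams that do not disturb (and are not
## disturbed by) the caller's global RNG state. Each generator owns a
## private .Random.seed snapshot keyed by (seed, tag).

make_rng <- function(seed, tag = "") {
  sub <- (abs(as.numeric(seed)) * 7919 +
            sum(utf8ToInt(tag)) * 104729) %% 2147483629
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(sub))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

runif_rng <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))

sample_rng <- function(rng, x, size, replace = FALSE, prob = NULL)
  with_rng(rng, sample(x, size, replace = replace, prob = prob))

sample_int_rng <- function(rng, n, size, replace = FALSE, prob = NULL)
  with_rng(rng, sample.int(n, size, replace = replace, prob = prob))
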