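## Internal seeded RNG streams. Every stochastic operation takes an integer
## seed and draws from its own stream, so results are pure functions of
## (seed, parameters) and the caller's .Random.seed is never disturbed.

.seededRNG <- function(seed) {
    env <- new.env(parent = emptyenv())
    old <- .saveGlobalSeed()
    set.seed(as.integer(seed))
    env$state <- get(".Random.seed", envir = globalenv())
    .restoreGlobalSeed(old)
    env
}

.saveGlobalSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreGlobalSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
}

.withRNG <- function(rng, expr) {
    old <- .saveGlobalSeed()
    assign(".Random.seed", rng$state, envir = globalenv())
    on.exit({
        rng$state <- get(".Random.seed", envir = globalenv())
        .restoreGlobalSeed(old)
    })
    expr
}

.rngSampleInt <- function(rng, n, size, replace = FALSE) {
    .withRNG(rng, sample.int(n, size, replace = replace))
}

.rngRunif <- function(rng, n, lo = 0, hi = 1) {
    .withRNG(rng, stats::runif(n, lo, hi))
}

.rngRbinom <- function(rng, n, prob) {
    .withRNG(rng, stats::rbinom(n, 1L, prob))
}

## deterministic lineage id: founders joined by '_' in their sorted order
.joinIds <- function(id1, id2) {
    paste(sort(c(id1, id2)), collapse = "_")
}
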