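# Shared fixtures, built in code. Heavier context objects are cached per
# test run so multiple test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# uniform state density on [lo, hi]
uniform_q <- function(lo = 0, hi = 10, n = 1025L)
    stateDensityFromGrid(seq(lo, hi, length.out = n), rep(1, n))

circle_poly <- function(center, R, V = 64L)
    gibbsColoc:::.circle_polygon(center, R, V)

# small circle context (quick q estimation) with cached state density
small_context <- function(seed = 101L, M = 25L, R = 3, size = 100,
                          arrangement = "random", h = 0.5) {
    key <- paste("ctx", seed, M, R, size, arrangement, h, sep = "_")
    if (is.null(.fixtures[[key]])) {
        spec <- scenarioSpec(domainSize = c(size, size), M = M, R = R,
                             arrangement = arrangement, N = 1L, seed = seed)
        ctx <- generateCircles(spec)
        ctx$q <- estimateStateDensity(ctx$domain, ctx$Y, gridSpacing = h)
        ctx$spec <- spec
        .fixtures[[key]] <- ctx
    }
    .fixtures[[key]]
}

# the reference power-study context: 100 circles R = 3.57 in 200 x 200
reference_context <- function(seed = 11L, h = 0.25) {
    key <- paste("reference", seed, h, sep = "_")
    if (is.null(.fixtures[[key]])) {
        spec <- scenarioSpec(seed = seed)
        ctx <- generateCircles(spec)
        ctx$q <- estimateStateDensity(ctx$domain, ctx$Y, gridSpacing = h)
        ctx$spec <- spec
        .fixtures[[key]] <- ctx
    }
    .fixtures[[key]]
}
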