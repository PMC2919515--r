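test_that("the reference context has the printed covered-area fraction", {
    spec <- scenarioSpec()                  # M = 100, R = 3.57, 200 x 200
    expect_equal(nominalAreaFraction(spec), 100 * pi * 3.57^2 / 200^2)
    expect_equal(nominalAreaFraction(spec), 0.1, tolerance = 0.002)
})

test_that("arrangements produce their characteristic geometry", {
    # regular: every point of the domain is close to some circle
    reg <- small_context(seed = 301L, M = 16L, R = 3, size = 100,
                         arrangement = "regular")
    rnd <- small_context(seed = 301L, M = 16L, R = 3, size = 100)
    g <- domainGrid(rectangleDomain(100), 2)
    dreg <- gibbsColoc:::.nn_signed(g, reg$Y)
    drnd <- gibbsColoc:::.nn_signed(g, rnd$Y)
    s <- (100 - 2 * 3) / ceiling(sqrt(16))  # lattice spacing
    expect_lt(max(dreg), s * sqrt(2))       # half-diagonal + jitter bound
    expect_lt(max(dreg), max(drnd))

    # clustered: quadrat counts are over-dispersed relative to random
    clu <- small_context(seed = 301L, M = 16L, R = 3, size = 100,
                         arrangement = "clustered")
    quad_var <- function(ctx) {
        cen <- ctx$centers
        var(table(factor(paste(pmin(cen[, 1] %/% 25, 3),
                               pmin(cen[, 2] %/% 25, 3)),
                         levels = outer(0:3, 0:3, paste)[1:16])))
    }
    expect_gt(quad_var(clu), quad_var(rnd))

    expect_error(scenarioSpec(domainSize = c(50, 50), M = 100L, R = 3),
                 "infeasible")
    expect_error(generateCircles(scenarioSpec(domainSize = c(40, 40),
        M = 36L, R = 3, arrangement = "regular", seed = 1)), "packing")
})

test_that("generators are deterministic given their seed", {
    s1 <- generateCircles(scenarioSpec(seed = 5))
    s2 <- generateCircles(scenarioSpec(seed = 5))
    s3 <- generateCircles(scenarioSpec(seed = 6))
    expect_identical(s1$centers, s2$centers)
    expect_false(identical(s1$centers, s3$centers))

    ctx <- small_context()
    p1 <- placePoints(ctx$domain, ctx$Y, NULL, 50L, seed = 9)
    p2 <- placePoints(ctx$domain, ctx$Y, NULL, 50L, seed = 9)
    p3 <- placePoints(ctx$domain, ctx$Y, NULL, 50L, seed = 10)
    expect_identical(p1, p2)
    expect_false(identical(p1, p3))
})

test_that("uniform placement is consistent with the state density", {
    ctx <- small_context()
    X <- placePoints(ctx$domain, ctx$Y, NULL, 2000L, seed = 11)
    d <- gibbsColoc:::.nn_signed(X, ctx$Y)
    ks <- suppressWarnings(stats::ks.test(d,
        function(v) baselineColoc(ctx$q, v)))
    expect_gt(ks$p.value, 0.01)
})

test_that("the rejection sampler realises the Gibbs distance model exactly", {
    ctx <- small_context()
    C0 <- baselineColoc(ctx$q, 0)
    # closed form for the step potential: P(inside) = C0 e^e/(C0 e^e+1-C0)
    e <- 1.5; n <- 3000L
    X <- placePoints(ctx$domain, ctx$Y,
                     interactionPotential("step", e, 1, 0), n, seed = 12)
    pin <- mean(gibbsColoc:::.nn_signed(X, ctx$Y) < 0)
    pexp <- C0 * exp(e) / (C0 * exp(e) + 1 - C0)
    expect_lt(abs(pin - pexp), 3 * sqrt(pexp * (1 - pexp) / n) + 0.01)

    # overwhelming attraction puts essentially all points inside
    Xdeep <- placePoints(ctx$domain, ctx$Y,
                         interactionPotential("step", 10, 1, 0), 500L,
                         seed = 13)
    expect_gte(mean(gibbsColoc:::.nn_signed(Xdeep, ctx$Y) < 0), 0.99)
})

test_that("complete scenarios carry consistent ground truth", {
    pot <- interactionPotential("plummer", 1, 5, 0)
    spec <- scenarioSpec(domainSize = c(100, 100), M = 25L, R = 3,
                         N = 120L, potential = pot, seed = 401L)
    cd <- generateScenario(spec, gridSpacing = 0.5)
    expect_s4_class(cd, "CellData")
    expect_equal(length(cd@distances), 120L)
    expect_identical(cd@truth$potential, pot)
    expect_s4_class(cd@objects, "ObjectSet")
    # distances recomputed from the stored objects agree
    expect_equal(distances(nnDistances(cd@objects)), distances(cd))

    # the model deformation pulls mass below zero relative to the null,
    # for any potential range
    q <- cd@q
    C0 <- baselineColoc(q, 0)
    for (s in c(0.2, 1, 5)) {
        md <- modelDensity(q, interactionPotential("plummer", 1, s, 0))
        expect_gt(gibbsColoc:::.pl_cdf_at(md@grid, md@density, 0), C0)
    }

    expect_error(scenarioSpec(N = 0L))
})
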