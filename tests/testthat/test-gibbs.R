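test_that("the partition function matches closed forms", {
    qu <- uniform_q(0, 10)
    expect_equal(partitionFunction(qu, NULL), 1, tolerance = 1e-9)
    expect_equal(partitionFunction(qu,
        interactionPotential("plummer", 0, 1, 0)), 1, tolerance = 1e-9)

    # step potential: Z = C0 e^eps + (1 - C0), here C0 = 0.1 at t = 1
    st <- interactionPotential("step", log(4), 1, 1)
    expect_equal(partitionFunction(qu, st), 1.3, tolerance = 1e-6)
    for (e in c(-1, 0.5, 2)) for (t in c(0.7, 3.2)) {
        C0 <- baselineColoc(qu, t)
        expect_equal(partitionFunction(qu,
                         interactionPotential("step", e, 1, t)),
                     C0 * exp(e) + 1 - C0, tolerance = 1e-6)
    }

    # monotone increasing in epsilon for attractive shapes
    Zs <- vapply(seq(0, 3, by = 0.5), function(e)
        partitionFunction(qu, interactionPotential("plummer", e, 2, 0)), 1)
    expect_true(all(diff(Zs) > 0))
})

test_that("the model density deforms q exactly as q e^(-phi)/Z", {
    qu <- uniform_q(0, 10)
    md0 <- modelDensity(qu, interactionPotential("hermquist", 0, 1, 0))
    expect_equal(stats::approx(md0@grid, md0@density, qu@grid)$y,
                 qu@density, tolerance = 1e-9)

    md <- modelDensity(qu, interactionPotential("step", log(4), 1, 1))
    expect_equal(gibbsColoc:::.pl_cdf_at(md@grid, md@density, 1),
                 0.4 / 1.3, tolerance = 1e-6)
    expect_equal(gibbsColoc:::.trapz(md@grid, md@density), 1,
                 tolerance = 1e-9)

    # attraction moves mass below the threshold for every eps >= 0
    for (e in c(0, 0.5, 2)) {
        mde <- modelDensity(qu, interactionPotential("step", e, 1, 2))
        expect_gte(gibbsColoc:::.pl_cdf_at(mde@grid, mde@density, 2) + 1e-12,
                   baselineColoc(qu, 2))
    }
})

test_that("log-likelihood composes log q, phi and Z consistently", {
    qu <- uniform_q(0, 10)
    expect_equal(logLikelihood(5, qu, NULL), log(0.1), tolerance = 1e-9)

    set.seed(4)
    d <- runif(50, 0, 10)
    expect_equal(logLikelihood(d, qu,
                     interactionPotential("plummer", 0, 1, 0)),
                 sum(log(densityAt(qu, d))), tolerance = 1e-9)
    expect_error(logLikelihood(c(3, 12), qu, NULL), "outside the q support")
    expect_error(logLikelihood(c(3, 12), qu, NULL), "12")

    # step-family likelihood is maximised at the closed-form estimator
    D <- distanceSample(runif(200, 0, 10))
    C <- colocMeasure(D, 2); C0 <- baselineColoc(qu, 2)
    ehat <- epsilonHatStep(C, C0)$epsilon
    lhat <- logLikelihood(D, qu, interactionPotential("step", ehat, 1, 2))
    for (e in seq(-2, 2, by = 0.1))
        expect_lte(logLikelihood(D, qu,
                       interactionPotential("step", e, 1, 2)), lhat + 1e-9)
})

test_that("inverse-CDF sampling reproduces the target distribution", {
    ctx <- small_context()
    q <- ctx$q
    D <- sampleDistances(q, NULL, 10000L, seed = 21)
    ks <- suppressWarnings(stats::ks.test(distances(D),
                                          function(v) baselineColoc(q, v)))
    expect_gt(ks$p.value, 0.01)

    # reproducibility and stream independence
    expect_equal(distances(sampleDistances(q, NULL, 100L, seed = 5)),
                 distances(sampleDistances(q, NULL, 100L, seed = 5)))
    expect_false(any(distances(sampleDistances(q, NULL, 100L, seed = 5)) ==
                     distances(sampleDistances(q, NULL, 100L, seed = 6))))

    # a very deep step potential pushes essentially all mass below t
    qu <- uniform_q(0, 10)
    Ddeep <- sampleDistances(qu, interactionPotential("step", 20, 1, 1),
                             20000L, seed = 9)
    expect_gt(colocMeasure(Ddeep, 1), 1 - 1e-3)
})

test_that("sufficient statistics count attraction evidence", {
    expect_equal(sufficientStatistic(c(-2, -1, 0.5), "step", 1, 0), 2)
    expect_equal(sufficientStatistic(0, "plummer", 1, 0), 1)
    d1 <- c(-1, 0.3, 2); d2 <- c(4, -0.5)
    for (fam in c("step", "plummer", "hermquist"))
        expect_equal(sufficientStatistic(c(d1, d2), fam, 2, 0),
                     sufficientStatistic(d1, fam, 2, 0) +
                     sufficientStatistic(d2, fam, 2, 0))
    # step statistic with t = 0 is the co-localization count
    set.seed(11)
    d <- rnorm(500, 2, 3)
    expect_identical(sufficientStatistic(d, "step", 1, 0) * 1,
                     sum(d < 0) * 1)
})

test_that("d/d(eps) log Z equals the expected statistic under p", {
    q <- small_context()$q
    h <- 1e-5
    for (e in c(0.5, 1.5)) {
        Zp <- partitionFunction(q, interactionPotential("plummer", e + h, 2, 0))
        Zm <- partitionFunction(q, interactionPotential("plummer", e - h, 2, 0))
        dlogZ <- (log(Zp) - log(Zm)) / (2 * h)
        md <- modelDensity(q, interactionPotential("plummer", e, 2, 0))
        ET <- gibbsColoc:::.trapz(md@grid,
            md@density * -shapeFunction("plummer", md@grid / 2))
        expect_equal(dlogZ, ET, tolerance = 1e-5)
    }
})
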