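test_that("step-family MLE coincides with the closed-form estimator", {
    ctx <- small_context()
    q <- ctx$q
    C0 <- baselineColoc(q, 0)
    for (i in 1:4) {
        pot <- interactionPotential("step", runif(1, -1, 2), 1, 0)
        D <- sampleDistances(q, pot, 300L, seed = 700 + i)
        C <- colocMeasure(D, 0)
        eh <- epsilonHatStep(C, C0)
        if (eh$status != "ok") next
        fit <- fitStrength(D, q, "step", sigma = 1, t = 0)
        expect_equal(fit$epsilon, eh$epsilon, tolerance = 1e-4)
    }
})

test_that("strength estimates recover the truth within their uncertainty", {
    ctx <- small_context()
    q <- ctx$q
    # null data at large N
    D0 <- sampleDistances(q, NULL, 2000L, seed = 41)
    f0 <- fitStrength(D0, q, "plummer", sigma = 1, t = 0)
    expect_lt(abs(f0$epsilon), 3 * f0$stderr)
    # true plummer strength 1 at sigma = 1
    pot <- interactionPotential("plummer", 1, 1, 0)
    D1 <- sampleDistances(q, pot, 1000L, seed = 42)
    f1 <- fitStrength(D1, q, "plummer", sigma = 1, t = 0)
    expect_lt(abs(f1$epsilon - 1), 3 * f1$stderr)
    # reported loglik is reproducible from the model
    expect_equal(f1$loglik,
                 logLikelihood(D1, q,
                     interactionPotential("plummer", f1$epsilon, 1, 0)),
                 tolerance = 1e-9)
})

test_that("joint (epsilon, sigma) fits recover simulated hermquist truths", {
    q <- small_context()$q
    pot <- interactionPotential("hermquist", 2, 4, 0)
    D <- sampleDistances(q, pot, 2000L, seed = 43)
    fit <- fitCell(D, q, "hermquist")
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$epsilon - 2), 3 * fit$stderr[1L])
    expect_lt(abs(fit$sigma - 4), 3 * fit$stderr[2L])
    expect_equal(fit$loglik,
                 logLikelihood(D, q, interactionPotential("hermquist",
                     fit$epsilon, fit$sigma, 0)), tolerance = 1e-9)
    # profile over sigma at the true strength peaks near the truth
    sig <- seq(1, 10, by = 0.25)
    prof <- vapply(sig, function(s)
        logLikelihood(D, q, interactionPotential("hermquist", 2, s, 0)), 1)
    expect_lt(abs(sig[which.max(prof)] - 4), 1.5)
})

test_that("null data do not fake a potential", {
    q <- small_context()$q
    D <- sampleDistances(q, NULL, 500L, seed = 44)
    fit <- fitCell(D, q, "plummer")
    l0 <- logLikelihood(D, q, NULL)
    lr_obs <- 2 * (fit$loglik - l0)
    # compare against refitted null replicates (exchangeable under H0)
    lr_null <- vapply(1:19, function(i) {
        Di <- sampleDistances(q, NULL, 500L, seed = 800 + i)
        2 * (fitCell(Di, q, "plummer")$loglik - logLikelihood(Di, q, NULL))
    }, 1)
    expect_lte(lr_obs, max(lr_null))
})

test_that("the pooled fit nests per-cell fits and recovers the shared scale", {
    q <- small_context()$q
    # single cell: pooled collapses to the per-cell joint fit
    pot <- interactionPotential("hermquist", 2, 4, 0)
    D <- sampleDistances(q, pot, 800L, seed = 45)
    single <- fitPooled(list(cellData(D, q)), "hermquist")
    joint <- fitCell(D, q, "hermquist")
    expect_equal(single$pooledLoglik, joint$loglik, tolerance = 1e-4)
    expect_equal(single$sigmaStar, joint$sigma, tolerance = 0.05)

    # several cells sharing sigma = 4 with varying strengths
    eps_true <- c(1, 1.5, 2, 2.5, 3)
    cells <- lapply(seq_along(eps_true), function(k)
        cellData(sampleDistances(q,
            interactionPotential("hermquist", eps_true[k], 4, 0),
            400L, seed = 900 + k, cellId = paste0("c", k)), q))
    pf <- fitPooled(cells, "hermquist")
    expect_equal(pf$nParams, 6L)
    expect_lt(abs(pf$sigmaStar - 4), 3 * pf$sigmaStarSE)
    ok <- abs(pf$epsilons - eps_true) < 3 * pf$stderrs
    expect_gte(sum(ok), 4L)
    expect_equal(pf$pooledLoglik, sum(pf$loglikPerCell), tolerance = 1e-9)

    # nesting inequality: common sigma cannot beat free per-cell scales
    free <- sum(vapply(cells, function(cd)
        fitCell(cd@distances, cd@q, "hermquist")$loglik, 1))
    expect_lte(pf$pooledLoglik, free + 1e-6)

    # model ranking: the generating family wins the pooled likelihood
    ll <- vapply(c("hermquist", "step", "plummer"), function(fam)
        fitPooled(cells, fam)$pooledLoglik, 1)
    expect_equal(names(which.max(ll)), "hermquist")
})

test_that("the penalised nonparametric potential shrinks under the null and tracks truths", {
    q <- small_context()$q
    dp <- nonparametricSupport(13L, -5, 5)   # up to 55 px, enough here
    # null: weights shrink toward zero
    cells0 <- lapply(1:3, function(k)
        cellData(sampleDistances(q, NULL, 300L, seed = 950 + k), q))
    f0 <- fitNonparametric(cells0, P = 13L, d1 = -5, spacing = 5, s = 2)
    expect_equal(f0$status, "ok")
    # under the null the weights stay well within the prior scale s = 2
    expect_lt(max(abs(f0$potential@weights)), 1.2)

    # attraction: the fitted potential dips below zero near the origin
    pot <- interactionPotential("hermquist", 3, 4, 0)
    cells1 <- lapply(1:3, function(k)
        cellData(sampleDistances(q, pot, 400L, seed = 960 + k), q))
    f1 <- fitNonparametric(cells1, P = 13L, d1 = -5, spacing = 5, s = 2)
    w <- f1$potential@weights
    expect_lt(w[2L], -1)                     # deep near d = 0
    # truth at the first node (d = -5): eps * f(-5/4) = -6.75
    expect_gt(min(w), -10)
    expect_lt(max(abs(w[dp > 30])), 0.75)    # flat far away
    # depth ordering resembles the generating potential
    truth <- potentialValue(pot, dp)
    expect_gt(cor(w, truth), 0.9)

    # loosening the prior (larger s) increases the penalised objective
    # at any fixed weight vector
    pen <- function(w, s) sum(diff(w)^2) / (2 * s^2)
    objs <- vapply(c(1, 2, 4, 8), function(s)
        f1$loglik - pen(f1$potential@weights, s), 1)
    expect_true(all(diff(objs) > 0))
})

test_that("fitNonparametric matches a derivative-free multistart oracle", {
    q <- small_context()$q
    pot <- interactionPotential("plummer", 1.5, 3, 0)
    cells <- list(cellData(sampleDistances(q, pot, 300L, seed = 971), q))
    fit <- fitNonparametric(cells, P = 7L, d1 = -5, spacing = 5, s = 2)
    # oracle: Nelder-Mead restarts on the same penalised objective
    D <- cells[[1L]]@distances
    obj <- function(w1) {
        np <- nonparametricPotential(nonparametricSupport(7L, -5, 5),
                                     c(w1, 0), smoothness = 2)
        logLikelihood(D, q, np) - sum(diff(c(w1, 0))^2) / (2 * 2^2)
    }
    best <- -Inf
    set.seed(5)
    for (i in 1:4) {
        op <- optim(rnorm(6, 0, 0.3), function(w) -obj(w),
                    method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-12))
        best <- max(best, -op$value)
    }
    expect_gte(fit$objective + 1e-4, best)
})

test_that("the Nadaraya-Watson smoother has the right limits", {
    x <- c(1, 2, 3, 4, 5)
    out <- kernelSmooth(x, rep(2.5, 5), bandwidth = 1)
    expect_true(all(abs(out$mean - 2.5) < 1e-12))
    expect_true(all(out$sd < 1e-6))

    out1 <- kernelSmooth(3, 7, bandwidth = 2, grid = c(2, 3, 4))
    expect_true(all(abs(out1$mean - 7) < 1e-12))

    y <- c(0, 1, 5, 2, 4)
    wide <- kernelSmooth(x, y, bandwidth = 1e6, grid = c(2.5))
    expect_equal(wide$mean, mean(y), tolerance = 1e-6)

    # far-away query points with negligible weight are dropped
    far <- kernelSmooth(x, y, bandwidth = 0.1, grid = c(3, 1000))
    expect_equal(nrow(far), 1L)
})
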