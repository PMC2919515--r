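test_that("MC rank test p-values hit their exact extremes", {
    qu <- uniform_q(0, 10)
    # all observed distances far below any plausible null draw
    Dlow <- distanceSample(rep(0.01, 50))
    r <- mcRankTest(Dlow, qu, "plummer", sigma = 1, K = 99, seed = 1)
    expect_equal(r$p.value, 1 / 100)
    expect_true(r$reject)
    # observed statistic below every null value
    Dhigh <- distanceSample(rep(9.99, 50))
    r2 <- mcRankTest(Dhigh, qu, "plummer", sigma = 1, K = 99, seed = 1)
    expect_equal(r2$p.value, 1)
    expect_false(r2$reject)
    # reproducibility
    D <- sampleDistances(qu, NULL, 60L, seed = 3)
    ra <- mcRankTest(D, qu, "plummer", K = 99, seed = 7)
    rb <- mcRankTest(D, qu, "plummer", K = 99, seed = 7)
    expect_equal(ra$p.value, rb$p.value)
    expect_error(mcRankTest(D, qu, "plummer", K = 5), "K")
})

test_that("the rank test holds its nominal size and p-values are super-uniform", {
    q <- small_context()$q
    reps <- 200L; K <- 99L; N <- 50L
    set.seed(17)
    pvals <- replicate(reps, {
        D <- sampleDistances(q, NULL, N)
        mcRankTest(D, q, "plummer", sigma = 1, K = K)$p.value
    })
    alpha <- 0.05
    tol <- 2 * sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(mean(pvals <= alpha) - alpha), tol + 0.01)
    for (u in c(0.01, 0.05, 0.1))
        expect_lte(mean(pvals <= u),
                   u + 2 * sqrt(u * (1 - u) / reps) + 0.01)
})

test_that("the nonparametric U test detects strong attraction and keeps size", {
    q <- small_context()$q
    # strongly attractive data reject essentially always
    pot <- interactionPotential("step", 3, 1, 0)
    rejs <- vapply(1:10, function(i) {
        D <- sampleDistances(q, pot, 150L, seed = 100 + i)
        nonparametricTest(D, q, K = 199, seed = 200 + i)$reject
    }, TRUE)
    expect_gte(mean(rejs), 0.9)
    # null calibration (loose: few replicates)
    set.seed(33)
    rej0 <- replicate(60, {
        D <- sampleDistances(q, NULL, 80L)
        nonparametricTest(D, q, K = 99)$reject
    })
    expect_lt(mean(rej0), 0.05 + 2 * sqrt(0.05 * 0.95 / 60) + 0.02)
    # U is a nonnegative quadratic form; p in (0, 1]
    D <- sampleDistances(q, NULL, 40L, seed = 5)
    r <- nonparametricTest(D, q, K = 99, seed = 6)
    expect_gte(r$observed, 0)
    expect_gt(r$p.value, 0)
    expect_lte(r$p.value, 1)
    # L > N is allowed (empty bins handled by the pseudo-inverse)
    r2 <- nonparametricTest(distanceSample(c(0.5, 1, 2)), q, L = 20,
                            K = 49, seed = 8)
    expect_true(is.finite(r2$observed))
})

test_that("the two MC stages of the U test use disjoint RNG stretches", {
    # reconstruct both stages from the seeded stream: the second sample
    # must continue, not reuse, the first
    q <- small_context()$q
    D <- sampleDistances(q, NULL, 30L, seed = 44)
    K <- 49L; N <- 30L
    res <- nonparametricTest(D, q, L = 10, K = K, alpha = 0.05, seed = 91)
    breaks <- gibbsColoc:::.q_bins(q, 10L)
    set.seed(91)
    s1 <- matrix(distances(sampleDistances(q, NULL, K * N)), nrow = N)
    s2 <- matrix(distances(sampleDistances(q, NULL, K * N)), nrow = N)
    expect_false(identical(s1, s2))
    C1 <- gibbsColoc:::.bin_counts(s1, breaks)
    E0 <- rowMeans(C1)
    Ci <- MASS::ginv(stats::cov(t(C1)), tol = 1e-10)
    U <- function(cnt) colSums((cnt - E0) * (Ci %*% (cnt - E0)))
    Uobs <- U(gibbsColoc:::.bin_counts(distances(D), breaks))
    Uk <- U(gibbsColoc:::.bin_counts(s2, breaks))
    expect_equal(res$observed, Uobs)
    expect_equal(res$p.value, (1 + sum(Uk >= Uobs)) / (K + 1))
})

test_that("power estimates respect size, monotonicity and statistic matching", {
    q <- small_context()$q
    # size equals the level under a null effect
    p0 <- estimatePower(q, NULL, list(family = "plummer", sigma = 1, t = 0),
                        N = 50, K = 99, reps = 200, seed = 3)
    expect_lt(abs(p0$power - 0.05), 2 * p0$mcse + 0.02)

    pot <- interactionPotential("plummer", 1, 5, 0)
    # monotone non-decreasing in N (within MC noise)
    ps <- vapply(c(25, 50, 100, 200), function(N)
        estimatePower(q, pot, list(family = "plummer", sigma = 5, t = 0),
                      N = N, K = 99, reps = 100, seed = 5)$power, 1)
    expect_true(all(diff(ps) > -0.1))
    expect_gt(ps[4], ps[1])

    # matched statistic beats the mismatched step statistic
    pm <- estimatePower(q, pot, list(family = "plummer", sigma = 5, t = 0),
                        N = 150, K = 99, reps = 200, seed = 6)
    pst <- estimatePower(q, pot, list(family = "step", sigma = 1, t = 0),
                         N = 150, K = 99, reps = 200, seed = 7)
    expect_gt(pm$power - 2 * pm$mcse, pst$power + 2 * pst$mcse)
})

test_that("minimal-N search brackets the power crossing", {
    q <- small_context()$q
    # very strong step effect: tiny N suffices; exact binomial agrees
    pot <- interactionPotential("step", 5, 1, 0)
    r <- minNForPower(q, pot, list(family = "step", sigma = 1, t = 0),
                      K = 199, reps = 100, seed = 12)
    expect_lte(r$N, 10L)
    C0 <- baselineColoc(q, 0)
    Nbin <- which(vapply(1:20, function(N)
        stepPower(C0, N, 0.05, 5)$power >= 0.8, TRUE))[1L]
    expect_lt(abs(r$N - Nbin), 4)

    # null effect: the cap is reached with an explicit status
    r0 <- minNForPower(q, NULL, list(family = "step", sigma = 1, t = 0),
                       K = 49, reps = 50, seed = 13, nCap = 64L)
    expect_match(r0$status, "not attainable")
    expect_true(is.na(r0$N))

    # stronger effects need fewer samples
    n1 <- minNForPower(q, interactionPotential("plummer", 1, 2, 0),
                       list(family = "plummer", sigma = 2, t = 0),
                       K = 99, reps = 100, seed = 14)$N
    n2 <- minNForPower(q, interactionPotential("plummer", 2, 2, 0),
                       list(family = "plummer", sigma = 2, t = 0),
                       K = 99, reps = 100, seed = 15)$N
    expect_lt(n2, n1)
})

test_that("the step rank test agrees with the exact binomial decision", {
    # scaled-down version of the full agreement check (see acceptance)
    q <- small_context()$q
    C0 <- baselineColoc(q, 0)
    N <- 40L
    agree <- vapply(1:40, function(i) {
        e <- runif(1, 0, 1.5)
        pot <- if (e < 0.2) NULL else interactionPotential("step", e, 1, 0)
        D <- sampleDistances(q, pot, N, seed = 500 + i)
        mc <- mcRankTest(D, q, "step", sigma = 1, t = 0, K = 999,
                         seed = 600 + i)
        k <- criticalColoc(C0, N, 0.05)$k
        exact <- !is.na(k) && sum(distances(D) < 0) >= k
        mc$reject == exact
    }, TRUE)
    expect_gte(mean(agree), 0.95)
})
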