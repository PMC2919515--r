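# Monte-Carlo rank tests (parametric sufficient statistic and
# non-parametric binned U), MC power estimation, and minimal-N search.

# Column-wise sufficient statistic for a matrix of distances (one sample
# per column).
.stat_cols <- function(dmat, family, sigma, t) {
    f <- shapeFunction(family, (dmat - t) / sigma)
    if (is.matrix(dmat)) {
        if (is.null(dim(f))) dim(f) <- dim(dmat)
        -colSums(f)
    } else -sum(f)
}

.mc_decision <- function(observed, nullValues, alpha) {
    K <- length(nullValues)
    nGE <- sum(nullValues >= observed)
    p <- (1 + nGE) / (K + 1)
    rank <- K + 1 - nGE
    list(p = p, rank = rank, reject = rank > ceiling((1 - alpha) * K))
}

#' Monte-Carlo rank test for interaction
#'
#' Tests H0 "no interaction" against attraction using the sufficient
#' statistic \eqn{T = -\sum_i f((d_i - t)/\sigma)} of a chosen potential
#' family. The null distribution is approximated by K i.i.d. samples of N
#' distances drawn from q; H0 is rejected when the observed statistic
#' ranks above the \eqn{\lceil (1-\alpha) K \rceil}-th null value
#' (equivalently, when the exact MC p-value
#' \eqn{(1 + \#\{T_k \ge T_{obs}\})/(K + 1)} is at most \eqn{\alpha}).
#'
#' @param D a [DistanceSample-class] (observed distances).
#' @param q a [StateDensity-class] (the null).
#' @param family potential family of the statistic.
#' @param sigma,t scale and threshold of the statistic.
#' @param K number of Monte-Carlo null samples (>= 19).
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return an object of class \code{testResult}: list with
#'   statisticName, observed, K, rank, p.value, alpha, reject, seed, N.
#' @export
mcRankTest <- function(D, q, family, sigma = 1, t = 0, K = 999L,
                       alpha = 0.05, seed = NULL) {
    stopifnot(is(D, "DistanceSample"), is(q, "StateDensity"), K >= 19)
    N <- length(D)
    Tobs <- sufficientStatistic(D, family, sigma, t)
    sampler <- .make_sampler(q, NULL)
    Tk <- .with_seed(seed,
        .stat_cols(matrix(sampler(K * N), nrow = N), family, sigma, t))
    dec <- .mc_decision(Tobs, Tk, alpha)
    structure(list(statisticName = paste0("T_", family), observed = Tobs,
                   K = as.integer(K), rank = dec$rank, p.value = dec$p,
                   alpha = alpha, reject = dec$reject, seed = seed, N = N,
                   cellId = D@cellId),
              class = "testResult")
}

#' @export
print.testResult <- function(x, ...) {
    cat(sprintf("MC rank test ('%s'): statistic %s = %.4g, N = %d, K = %d\n",
                x$cellId, x$statisticName, x$observed, x$N, x$K))
    cat(sprintf("  rank %d of %d, p = %.4g, alpha = %g -> %s\n",
                x$rank, x$K + 1L, x$p.value, x$alpha,
                if (x$reject) "reject H0" else "do not reject H0"))
    invisible(x)
}

# bin distances into L equal-width bins over q's non-zero range;
# returns breaks
.q_bins <- function(q, L) {
    nz <- q@grid[q@density > 1e-12 * max(q@density)]
    seq(min(nz), max(nz), length.out = L + 1L)
}

# column-wise bin counts for a matrix of distances (clamped to the range)
.bin_counts <- function(dmat, breaks) {
    L <- length(breaks) - 1L
    dmat <- matrix(dmat, ncol = if (is.matrix(dmat)) ncol(dmat) else 1L)
    idx <- findInterval(dmat, breaks, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > L] <- L
    K <- ncol(dmat)
    matrix(tabulate(idx + L * (col(dmat) - 1L), nbins = L * K), L, K)
}

#' Non-parametric Monte-Carlo test for interaction
#'
#' Shape-free test: distances are counted in L equal-width bins spanning
#' the non-zero range of q; a first MC sample (N draws from q, K times)
#' estimates the null mean E0 and covariance Cov0 of the count vector T;
#' the statistic \eqn{U = (T - E_0)^\top \mathrm{Cov}_0^{-}(T - E_0)}
#' (Moore-Penrose pseudo-inverse, so empty bins cannot crash the test) is
#' then ranked among U values of a second, independent MC sample.
#'
#' @param D a [DistanceSample-class].
#' @param q a [StateDensity-class].
#' @param L number of bins (>= 2).
#' @param K Monte-Carlo sample size per stage.
#' @param alpha significance level.
#' @param seed optional integer seed; the two MC stages consume disjoint
#'   stretches of the seeded stream.
#' @return a \code{testResult} (statisticName "U").
#' @export
nonparametricTest <- function(D, q, L = 20L, K = 999L, alpha = 0.05,
                              seed = NULL) {
    stopifnot(is(D, "DistanceSample"), is(q, "StateDensity"), L >= 2, K >= 19)
    N <- length(D)
    breaks <- .q_bins(q, L)
    sampler <- .make_sampler(q, NULL)
    res <- .with_seed(seed, {
        # stage 1: moments of the null count vector
        C1 <- .bin_counts(matrix(sampler(K * N), nrow = N), breaks)
        E0 <- rowMeans(C1)
        Cov0inv <- MASS::ginv(stats::cov(t(C1)), tol = 1e-10)
        Ustat <- function(cnt) {
            z <- cnt - E0
            colSums(z * (Cov0inv %*% z))
        }
        Uobs <- Ustat(.bin_counts(D@d, breaks))
        # stage 2: independent null sample for the ranking
        Uk <- Ustat(.bin_counts(matrix(sampler(K * N), nrow = N), breaks))
        list(Uobs = Uobs, Uk = Uk)
    })
    dec <- .mc_decision(res$Uobs, res$Uk, alpha)
    structure(list(statisticName = "U", observed = res$Uobs,
                   K = as.integer(K), rank = dec$rank, p.value = dec$p,
                   alpha = alpha, reject = dec$reject, seed = seed, N = N,
                   L = as.integer(L), cellId = D@cellId),
              class = "testResult")
}

#' Monte-Carlo power estimate of a rank test
#'
#' Repeatedly draws N distances from the model density under the true
#' potential, runs the MC rank test with the given statistic, and reports
#' the rejection fraction with its binomial Monte-Carlo standard error.
#'
#' @param q a [StateDensity-class].
#' @param truePotential the potential generating the data.
#' @param statistic list with elements \code{family}, \code{sigma},
#'   \code{t} defining the test statistic.
#' @param N sample size per replicate.
#' @param alpha significance level.
#' @param K null samples per test.
#' @param reps number of power replicates (>= 50).
#' @param seed optional integer seed.
#' @return a \code{powerResult} with fields power, mcse, alpha, N,
#'   effectSize, K, reps.
#' @export
estimatePower <- function(q, truePotential, statistic, N, alpha = 0.05,
                          K = 199L, reps = 200L, seed = NULL) {
    stopifnot(is(q, "StateDensity"), reps >= 50)
    fam <- statistic$family
    sg <- statistic$sigma %||% 1
    tt <- statistic$t %||% 0
    rej <- .with_seed(seed,
        .power_rejections(q, truePotential, fam, sg, tt, N, alpha, K, reps))
    p <- mean(rej)
    structure(list(alpha = alpha, N = as.integer(N),
                   effectSize = if (is(truePotential, "InteractionPotential"))
                       truePotential@epsilon else NA_real_,
                   power = p, mcse = sqrt(p * (1 - p) / reps),
                   K = as.integer(K), reps = as.integer(reps),
                   statisticName = paste0("T_", fam), status = "ok"),
              class = "powerResult")
}

# vectorised core: logical vector of `reps` rejection indicators;
# consumes the current RNG stream
.power_rejections <- function(q, truePotential, family, sigma, t, N, alpha,
                              K, reps, chunkTarget = 5e6) {
    samplerP <- .make_sampler(q, truePotential)
    samplerQ <- .make_sampler(q, NULL)
    Tobs <- .stat_cols(matrix(samplerP(reps * N), nrow = N), family, sigma, t)
    nGEcrit <- (K + 1) * alpha - 1     # reject iff #{T_k >= T_obs} <= this
    block <- max(1L, floor(chunkTarget / (K * N)))
    rej <- logical(reps)
    i <- 1L
    while (i <= reps) {
        j <- min(i + block - 1L, reps)
        nb <- j - i + 1L
        Tk <- matrix(.stat_cols(matrix(samplerQ(nb * K * N), nrow = N),
                                family, sigma, t), nrow = K)
        nGE <- colSums(Tk >= rep(Tobs[i:j], each = K))
        rej[i:j] <- nGE <= nGEcrit
        i <- j + 1L
    }
    rej
}

#' Minimal sample size reaching a target power
#'
#' Searches the smallest N whose Monte-Carlo power estimate reaches the
#' target, on a doubling-then-bisection schedule, and reports the
#' bracketing interval. The search stops with a status when the cap is
#' reached (e.g. a null effect can never exceed the level).
#'
#' @inheritParams estimatePower
#' @param target target power in (0, 1).
#' @param nStart first sample size of the doubling schedule.
#' @param nCap largest sample size tried.
#' @return an object of class \code{minNResult}: list with N (NA when not
#'   attainable), bracket, status, target, and the evaluation table.
#' @export
minNForPower <- function(q, truePotential, statistic, alpha = 0.05,
                         target = 0.8, K = 199L, reps = 200L, seed = NULL,
                         nStart = 4L, nCap = 4096L) {
    stopifnot(target > 0, target < 1)
    fam <- statistic$family
    sg <- statistic$sigma %||% 1
    tt <- statistic$t %||% 0
    .with_seed(seed, {
        evals <- list()
        powerAt <- function(N) {
            p <- mean(.power_rejections(q, truePotential, fam, sg, tt,
                                        N, alpha, K, reps))
            evals[[length(evals) + 1L]] <<- data.frame(N = N, power = p)
            p
        }
        lo <- 0L                      # largest N known to be below target
        hi <- NA_integer_             # smallest N known to reach target
        N <- as.integer(nStart)
        while (N <= nCap) {
            if (powerAt(N) >= target) { hi <- N; break }
            lo <- N
            N <- N * 2L
        }
        if (!is.na(hi)) {
            while (hi - lo > 1L) {
                mid <- lo + (hi - lo) %/% 2L
                if (powerAt(mid) >= target) hi <- mid else lo <- mid
            }
        }
        structure(list(N = hi,
                       bracket = if (is.na(hi)) c(lo, NA) else c(lo, hi),
                       status = if (is.na(hi)) "not attainable at cap" else "ok",
                       target = target, nCap = nCap,
                       evaluations = do.call(rbind, evals),
                       reps = reps, K = K),
                  class = "minNResult")
    })
}

#' @export
print.minNResult <- function(x, ...) {
    if (identical(x$status, "ok"))
        cat(sprintf("Minimal N for %.0f%% power: N = %d (bracket %d..%d)\n",
                    100 * x$target, x$N, x$bracket[1L], x$bracket[2L]))
    else
        cat(sprintf("Minimal N for %.0f%% power: %s (cap %d)\n",
                    100 * x$target, x$status, x$nCap))
    invisible(x)
}
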