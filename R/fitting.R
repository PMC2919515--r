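# Maximum-likelihood estimation of potentials: per-cell strength and
# scale, pooled common scale across cells, penalised non-parametric
# potential, and the Nadaraya-Watson time-course smoother.

.eps_bracket <- c(-20, 20)

#' Maximum-likelihood strength at fixed scale
#'
#' One-dimensional MLE of the strength \eqn{\epsilon} of a parametric
#' potential with fixed family, scale and threshold, by Brent line
#' optimisation of the log-likelihood (which is concave in
#' \eqn{\epsilon}: exponential family). The standard error comes from the
#' numerical observed information.
#'
#' @param D a [DistanceSample-class].
#' @param q a [StateDensity-class].
#' @param family potential family.
#' @param sigma fixed scale (pixels, > 0).
#' @param t threshold (pixels).
#' @return an object of class \code{strengthFit}: list with epsilon,
#'   loglik, stderr, status.
#' @export
fitStrength <- function(D, q, family, sigma, t = 0) {
    stopifnot(is(D, "DistanceSample"), is(q, "StateDensity"), sigma > 0)
    obj <- function(e)
        logLikelihood(D, q, interactionPotential(family, e, sigma, t))
    opt <- stats::optimize(obj, interval = .eps_bracket, maximum = TRUE,
                           tol = 1e-8)
    eh <- opt$maximum
    status <- if (min(abs(eh - .eps_bracket)) < 1e-3)
        "at bracket boundary" else "ok"
    h <- 1e-4
    info <- -(obj(eh + h) - 2 * opt$objective + obj(eh - h)) / h^2
    structure(list(epsilon = eh, loglik = opt$objective,
                   stderr = if (is.finite(info) && info > 0) 1 / sqrt(info)
                            else NA_real_,
                   family = family, sigma = sigma, t = t, status = status),
              class = "strengthFit")
}

#' @export
print.strengthFit <- function(x, ...) {
    cat(sprintf("Strength fit (%s, sigma = %g, t = %g): epsilon = %.4f +/- %s, loglik = %.4f\n",
                x$family, x$sigma, x$t, x$epsilon,
                ifelse(is.na(x$stderr), "NA", sprintf("%.4f", x$stderr)),
                x$loglik))
    if (!identical(x$status, "ok")) cat("  status:", x$status, "\n")
    invisible(x)
}

#' Joint maximum-likelihood fit of strength and scale for one cell
#'
#' Two-dimensional MLE over \eqn{(\epsilon, \log\sigma)} by Nelder-Mead
#' with multiple starting scales (0.5, 2, 8 px). Optimising
#' \eqn{\log\sigma} enforces positivity; standard errors come from the
#' numerical observed information matrix. A nearly singular information
#' matrix (the likelihood is ridge-like in \eqn{\sigma} when
#' \eqn{\epsilon \approx 0}) is reported as "weakly identified".
#'
#' @inheritParams fitStrength
#' @return an object of class \code{cellFit}: list with epsilon, sigma,
#'   loglik, stderr (length 2), status.
#' @export
fitCell <- function(D, q, family, t = 0) {
    stopifnot(is(D, "DistanceSample"), is(q, "StateDensity"))
    if (length(D) < 10L)
        warning("fewer than 10 distances: joint (epsilon, sigma) fit is fragile")
    nll <- function(par) {
        e <- par[1L]; s <- exp(par[2L])
        if (abs(e) > 25 || s > 1e4 || s < 1e-4) return(1e10)
        -logLikelihood(D, q, interactionPotential(family, e, s, t))
    }
    best <- NULL
    for (s0 in c(0.5, 2, 8)) {
        op <- stats::optim(c(0.5, log(s0)), nll, method = "Nelder-Mead",
                           control = list(maxit = 500, reltol = 1e-10))
        if (is.null(best) || op$value < best$value) best <- op
    }
    eh <- best$par[1L]; sh <- exp(best$par[2L])
    # observed information in (epsilon, sigma) coordinates
    H <- stats::optimHess(c(eh, sh), function(p) {
        if (p[2L] <= 0) return(1e10)
        -logLikelihood(D, q, interactionPotential(family, p[1L], p[2L], t))
    })
    se <- c(NA_real_, NA_real_)
    status <- if (best$convergence == 0) "ok" else "non-convergence"
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) c(-1, -1))
    if (all(ev > 0) && min(ev) / max(ev) > 1e-10) {
        se <- sqrt(diag(solve(H)))
    } else if (identical(status, "ok")) {
        status <- "weakly identified"
    }
    structure(list(epsilon = eh, sigma = sh, loglik = -best$value,
                   stderr = se, family = family, t = t, status = status),
              class = "cellFit")
}

#' @export
print.cellFit <- function(x, ...) {
    cat(sprintf("Cell fit (%s, t = %g): epsilon = %.4f, sigma = %.4f px, loglik = %.4f\n",
                x$family, x$t, x$epsilon, x$sigma, x$loglik))
    if (all(is.finite(x$stderr)))
        cat(sprintf("  se(epsilon) = %.4f, se(sigma) = %.4f\n",
                    x$stderr[1L], x$stderr[2L]))
    if (!identical(x$status, "ok")) cat("  status:", x$status, "\n")
    invisible(x)
}

#' Pooled fit: common scale, per-cell strengths
#'
#' Nested maximum likelihood across cells: an outer one-dimensional
#' optimisation over the common scale \eqn{\sigma^*} of the pooled
#' log-likelihood \eqn{l^* = \sum_k \max_{\epsilon_k} l(\epsilon_k,
#' \sigma^* | D_k)}, with the inner per-cell strength problems solved by
#' [fitStrength()]. Reports AIC = 2p - 2l* and BIC = p log(sum N_k) - 2l*
#' with p = number of cells + 1 free parameters, for ranking candidate
#' potential families. Per-cell failures are recorded; the pooled fit
#' proceeds when at least 80\% of cells succeed.
#'
#' @param cells list of [CellData-class] objects.
#' @param family potential family.
#' @param t threshold (pixels).
#' @param sigmaBracket search interval for \eqn{\sigma^*} (pixels).
#' @return an object of class \code{pooledFit}: list with family,
#'   sigmaStar, sigmaStarSE (profile-curvature standard error), epsilons,
#'   stderrs, loglikPerCell, pooledLoglik, nParams, aic, bic,
#'   convergence, perCell (data frame), failures.
#' @export
fitPooled <- function(cells, family, t = 0, sigmaBracket = c(0.05, 100)) {
    stopifnot(length(cells) >= 1L,
              all(vapply(cells, is, TRUE, "CellData")))
    innerFit <- function(s) {
        lapply(cells, function(cd)
            tryCatch(fitStrength(cd@distances, cd@q, family, s, t),
                     error = function(e) structure(list(error = conditionMessage(e)),
                                                   class = "failedFit")))
    }
    pooled <- function(logS) {
        fits <- innerFit(exp(logS))
        ok <- !vapply(fits, inherits, TRUE, "failedFit")
        if (mean(ok) < 0.8)
            .stopf("pooled fit failed: only %d/%d cells could be fitted",
                   sum(ok), length(cells))
        sum(vapply(fits[ok], `[[`, 1, "loglik"))
    }
    opt <- stats::optimize(pooled, interval = log(sigmaBracket),
                           maximum = TRUE, tol = 1e-6)
    sigmaStar <- exp(opt$maximum)
    # profile curvature in log sigma -> delta-method se for sigma*
    h <- 0.02
    info <- -(pooled(opt$maximum + h) - 2 * opt$objective +
              pooled(opt$maximum - h)) / h^2
    sigmaStarSE <- if (is.finite(info) && info > 0)
        sigmaStar / sqrt(info) else NA_real_
    fits <- innerFit(sigmaStar)
    ok <- !vapply(fits, inherits, TRUE, "failedFit")
    eps <- ifelse(ok, vapply(fits, function(f)
        if (inherits(f, "failedFit")) NA_real_ else f$epsilon, 1), NA_real_)
    ses <- vapply(fits, function(f)
        if (inherits(f, "failedFit")) NA_real_ else f$stderr, 1)
    lls <- vapply(fits, function(f)
        if (inherits(f, "failedFit")) NA_real_ else f$loglik, 1)
    lstar <- sum(lls[ok])
    nPar <- sum(ok) + 1L
    Ntot <- sum(vapply(cells[ok], function(cd) length(cd@distances), 1L))
    perCell <- data.frame(
        cellId = vapply(cells, function(cd) cd@cellId, ""),
        N = vapply(cells, function(cd) length(cd@distances), 1L),
        epsilon = eps, stderr = ses, loglik = lls, ok = ok)
    structure(list(family = family, t = t, sigmaStar = sigmaStar,
                   sigmaStarSE = sigmaStarSE,
                   epsilons = eps, stderrs = ses, loglikPerCell = lls,
                   pooledLoglik = lstar, nParams = nPar,
                   aic = 2 * nPar - 2 * lstar,
                   bic = nPar * log(Ntot) - 2 * lstar,
                   convergence = "ok", perCell = perCell,
                   failures = which(!ok)),
              class = "pooledFit")
}

#' @export
print.pooledFit <- function(x, ...) {
    cat(sprintf("Pooled fit (%s, t = %g): sigma* = %.4f px over %d cells\n",
                x$family, x$t, x$sigmaStar, nrow(x$perCell)))
    cat(sprintf("  pooled loglik = %.4f, AIC = %.2f, BIC = %.2f (%d params)\n",
                x$pooledLoglik, x$aic, x$bic, x$nParams))
    if (length(x$failures))
        cat("  failed cells:", paste(x$failures, collapse = ", "), "\n")
    invisible(x)
}

#' Penalised non-parametric potential fit
#'
#' Maximises the joint log-likelihood of all cells minus the smoothness
#' penalty \eqn{\sum_{p=1}^{P-1} (w_p - w_{p+1})^2 / (2 s^2)} (a Gaussian
#' prior with standard deviation s on the weight differences) over the
#' weights \eqn{w_1, \dots, w_{P-1}}, with \eqn{w_P = 0} fixed. The
#' objective is concave (exponential family plus concave penalty), so a
#' quasi-Newton optimiser with the analytic gradient finds the global
#' optimum; several restarts guard against numerical stalls.
#'
#' @param cells list of [CellData-class] objects.
#' @param P number of support points.
#' @param d1 first support point (pixels).
#' @param spacing support-point spacing h (pixels).
#' @param s smoothness (prior standard deviation on weight differences).
#' @return list with \code{potential} (a
#'   [NonparametricPotential-class]), \code{objective} (penalised
#'   log-likelihood at the optimum), \code{loglik}, \code{penalty},
#'   \code{convergence}, \code{status}.
#' @export
fitNonparametric <- function(cells, P = 21L, d1 = -5, spacing = 5, s = 2) {
    stopifnot(length(cells) >= 1L,
              all(vapply(cells, is, TRUE, "CellData")))
    dp <- nonparametricSupport(P, d1, spacing)
    hat <- function(d) {    # n x P triangular kernel basis, constant tails
        z <- outer(d, dp, function(a, b) pmax(0, 1 - abs(a - b) / spacing))
        z[d < dp[1L], 1L] <- 1         # continue at w_1 below the first node
        z
    }
    # per-cell precomputations: basis at data and at the q grid
    pre <- lapply(cells, function(cd) {
        g <- cd@q@grid
        wts <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)  # trapezoid weights
        list(Kd = hat(cd@distances@d), Kg = hat(g),
             qg = cd@q@density, wq = wts * cd@q@density,
             N = length(cd@distances),
             lq = sum(log(pmax(densityAt(cd@q, cd@distances@d), 1e-300))))
    })
    Dmat <- diff(diag(P))[, seq_len(P - 1L), drop = FALSE]  # difference map
    objgrad <- function(w1) {
        w <- c(w1, 0)
        ll <- 0
        grad <- numeric(P - 1L)
        for (pc in pre) {
            phid <- drop(pc$Kd %*% w)
            phig <- drop(pc$Kg %*% w)
            e <- exp(-phig)
            Z <- sum(pc$wq * e)
            ll <- ll + pc$lq - sum(phid) - pc$N * log(Z)
            gZ <- drop(crossprod(pc$Kg, pc$wq * e)) / Z  # E_p[kappa_p]
            grad <- grad + (-colSums(pc$Kd) + pc$N * gZ)[seq_len(P - 1L)]
        }
        dw <- -diff(w)                  # w_p - w_{p+1}
        pen <- sum(dw^2) / (2 * s^2)
        gpen <- drop(crossprod(Dmat, diff(w))) / s^2
        list(value = ll - pen, grad = grad - gpen)
    }
    fn <- function(w1) -objgrad(w1)$value
    gr <- function(w1) -objgrad(w1)$grad
    best <- NULL
    for (start in list(rep(0, P - 1L), rep(-0.5, P - 1L))) {
        op <- stats::optim(start, fn, gr, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-12))
        if (is.null(best) || op$value < best$value) best <- op
    }
    w <- c(best$par, 0)
    og <- objgrad(best$par)
    list(potential = nonparametricPotential(dp, w, spacing, s),
         objective = og$value,
         loglik = og$value + sum(diff(w)^2) / (2 * s^2),
         penalty = sum(diff(w)^2) / (2 * s^2),
         convergence = best$convergence,
         status = if (best$convergence == 0) "ok" else "non-convergence")
}

#' Nadaraya-Watson kernel smoother with a local-spread band
#'
#' Gaussian-kernel regression of estimates on a covariate (e.g. strength
#' estimates versus time post infection), with a same-weights estimate of
#' the local standard deviation as the band. Query points whose total
#' kernel weight falls below 1e-12 are omitted.
#'
#' @param x covariate values.
#' @param y estimates to smooth.
#' @param bandwidth Gaussian kernel bandwidth (same units as x).
#' @param grid query points (default: 101 points over the x range).
#' @return data frame with columns grid, mean, sd.
#' @export
kernelSmooth <- function(x, y, bandwidth,
                         grid = seq(min(x), max(x), length.out = 101L)) {
    stopifnot(length(x) == length(y), length(x) >= 1L, bandwidth > 0)
    out <- lapply(grid, function(g) {
        w <- stats::dnorm((x - g) / bandwidth)
        sw <- sum(w)
        if (sw < 1e-12) return(NULL)
        m <- sum(w * y) / sw
        data.frame(grid = g, mean = m, sd = sqrt(sum(w * (y - m)^2) / sw))
    })
    do.call(rbind, out)
}
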