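# The Gibbs distance model p(d | q, phi) = q(d) exp(-phi(d)) / Z:
# partition function, model density, log-likelihood, sampling, and the
# exponential-family sufficient statistic.

# Integration nodes: the q grid augmented with two-sided evaluations at
# any potential discontinuity (the step family), so that the trapezoid
# rule is exact for the piecewise-linear q times a piecewise-smooth
# Boltzmann factor. Returns nodes x, q(x) and phi(x).
.model_nodes <- function(q, pot) {
    x <- q@grid
    if (!is.null(pot)) {
        eps <- 1e-9 * diff(q@support)
        for (b in .potential_breaks(pot)) {
            if (b > q@support[1L] + eps && b < q@support[2L] - eps)
                x <- c(x, b - eps, b)
        }
        x <- sort(unique(x))
    }
    qx <- densityAt(q, x)
    phix <- if (is.null(pot)) rep(0, length(x)) else potentialValue(pot, x)
    if (any(!is.finite(phix)))
        .stopf("potential is not finite everywhere on the q support")
    list(x = x, qx = qx, phix = phix)
}

#' Partition function of the Gibbs distance model
#'
#' \eqn{Z = \int q(d) e^{-\phi(d)} dd}, computed by the trapezoid rule on
#' the state-density grid (augmented at potential discontinuities). For
#' \eqn{\phi \equiv 0}, Z = 1.
#'
#' @param q a [StateDensity-class].
#' @param pot a potential ([InteractionPotential-class] or
#'   [NonparametricPotential-class]), or NULL for \eqn{\phi \equiv 0}.
#' @return the partition function Z (> 0).
#' @export
partitionFunction <- function(q, pot) {
    stopifnot(is(q, "StateDensity"))
    nd <- .model_nodes(q, pot)
    Z <- .trapz(nd$x, nd$qx * exp(-nd$phix))
    if (!is.finite(Z) || Z <= 0)
        .stopf("partition function is not positive/finite (Z = %g)", Z)
    Z
}

#' Model distance density
#'
#' \eqn{p(d) = q(d) e^{-\phi(d)} / Z} on the (augmented) grid. With
#' \eqn{\epsilon = 0} this reduces to q(d) pointwise.
#'
#' @inheritParams partitionFunction
#' @return a [ModelDensity-class].
#' @export
modelDensity <- function(q, pot) {
    stopifnot(is(q, "StateDensity"))
    nd <- .model_nodes(q, pot)
    w <- nd$qx * exp(-nd$phix)
    Z <- .trapz(nd$x, w)
    if (!is.finite(Z) || Z <= 0)
        .stopf("partition function is not positive/finite (Z = %g)", Z)
    new("ModelDensity", grid = nd$x, density = w / Z, Z = Z)
}

#' Log-likelihood of a potential given observed distances
#'
#' \eqn{l = \sum_i [\log q(d_i) - \phi(d_i)] - N \log Z}. Distances
#' outside the support of q are a hard error (no silent clamping); inside
#' the support, interpolated q values are floored at 1e-300 before taking
#' the log to avoid spurious -Inf from underflow.
#'
#' @param D a [DistanceSample-class] (or numeric vector of distances).
#' @param q a [StateDensity-class].
#' @param pot a potential, or NULL for \eqn{\phi \equiv 0}.
#' @return the log-likelihood value.
#' @export
logLikelihood <- function(D, q, pot = NULL) {
    d <- if (is(D, "DistanceSample")) D@d else as.numeric(D)
    stopifnot(is(q, "StateDensity"))
    out <- d < q@support[1L] | d > q@support[2L]
    if (any(out))
        .stopf("%d distance(s) outside the q support [%g, %g]: %s",
               sum(out), q@support[1L], q@support[2L],
               paste(utils::head(signif(d[out], 6), 5L), collapse = ", "))
    lq <- log(pmax(densityAt(q, d), 1e-300))
    phi <- if (is.null(pot)) 0 else potentialValue(pot, d)
    Z <- partitionFunction(q, pot)
    sum(lq - phi) - length(d) * log(Z)
}

# Precompute an inverse-CDF sampler for p(d | q, pot); returns
# function(n) -> n i.i.d. draws. Used internally by the Monte-Carlo
# machinery to avoid recomputing the CDF.
.make_sampler <- function(q, pot = NULL) {
    nd <- .model_nodes(q, pot)
    qf <- .pl_sampler_factory(nd$x, nd$qx * exp(-nd$phix))
    function(n) qf(stats::runif(n))
}

#' Sample distances from the model density
#'
#' I.i.d. draws from \eqn{p(d | q, \phi)} by inverse-CDF sampling on the
#' trapezoid-integrated grid (exact with respect to the piecewise-linear
#' discretisation of p). Reproducible given a seed.
#'
#' @param q a [StateDensity-class].
#' @param pot a potential or NULL (draws from q itself).
#' @param n number of draws.
#' @param seed optional integer seed (the global RNG state is restored
#'   afterwards).
#' @param cellId label for the returned sample.
#' @return a [DistanceSample-class].
#' @export
sampleDistances <- function(q, pot = NULL, n, seed = NULL, cellId = "sim") {
    stopifnot(.is_count(n))
    sampler <- .make_sampler(q, pot)
    distanceSample(.with_seed(seed, sampler(n)), cellId)
}

#' Sufficient statistic of a potential family
#'
#' For the exponential-family model the statistic
#' \eqn{T = -\sum_i f((d_i - t)/\sigma)} is sufficient for the strength
#' \eqn{\epsilon}; larger T means stronger evidence of attraction. For
#' the step family with t = 0 it equals the co-localization count
#' \eqn{N C^0}.
#'
#' @param D a [DistanceSample-class] or numeric vector.
#' @param family potential family identifier.
#' @param sigma scale (pixels).
#' @param t threshold/shift (pixels).
#' @return the statistic T.
#' @export
sufficientStatistic <- function(D, family, sigma = 1, t = 0) {
    d <- if (is(D, "DistanceSample")) D@d else as.numeric(D)
    -sum(shapeFunction(family, (d - t) / sigma))
}
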