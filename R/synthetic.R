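# Synthetic cellular contexts and object sets with known ground truth:
# circles in a square domain, points placed under a chosen potential.

#' Synthetic scenario specification
#'
#' Describes a synthetic cellular context (M circular reference objects
#' of radius R in a rectangular domain, arranged randomly, regularly or
#' in clusters) plus N query points placed under an optional true
#' potential. The default corresponds to the reference context used
#' throughout the power studies: M = 100 circles of radius R = 3.57 in a
#' 200 x 200 px square, giving a nominal circle-covered area fraction
#' \eqn{M \pi R^2 / |\Omega|} of 0.1 (overlaps allowed, so this is the
#' nominal, not the union, fraction).
#'
#' @param domainSize width and height in pixels.
#' @param M number of circular reference objects.
#' @param R circle radius (pixels).
#' @param arrangement "random" (uniform independent centres), "regular"
#'   (jittered square lattice) or "clustered" (Thomas-style
#'   parent/offspring placement).
#' @param N number of query points.
#' @param potential true [InteractionPotential-class] /
#'   [NonparametricPotential-class], or NULL for no interaction.
#' @param seed integer seed; every generator operation is deterministic
#'   given the seed.
#' @param vertices number of polygon vertices used to render each circle.
#' @param parents,offspringSd clustered-mode parameters.
#' @return an object of class \code{scenarioSpec}.
#' @export
scenarioSpec <- function(domainSize = c(200, 200), M = 100L, R = 3.57,
                         arrangement = c("random", "regular", "clustered"),
                         N = 100L, potential = NULL, seed = NULL,
                         vertices = 64L, parents = 10L, offspringSd = 10) {
    arrangement <- match.arg(arrangement)
    stopifnot(length(domainSize) == 2L, all(domainSize > 0),
              .is_count(M), R > 0, .is_count(N))
    if (M * pi * R^2 >= prod(domainSize))
        .stopf("infeasible: nominal circle area M*pi*R^2 = %.3g >= domain area %.3g",
               M * pi * R^2, prod(domainSize))
    if (2 * R >= min(domainSize))
        .stopf("circle diameter exceeds the domain")
    structure(list(domainSize = domainSize, M = as.integer(M), R = R,
                   arrangement = arrangement, N = as.integer(N),
                   potential = potential, seed = seed,
                   vertices = as.integer(vertices),
                   parents = as.integer(parents), offspringSd = offspringSd),
              class = "scenarioSpec")
}

#' @export
print.scenarioSpec <- function(x, ...) {
    cat(sprintf("Scenario: %g x %g px, M = %d circles R = %g (%s), N = %d points\n",
                x$domainSize[1L], x$domainSize[2L], x$M, x$R,
                x$arrangement, x$N))
    cat(sprintf("  nominal covered area fraction: %.4f\n",
                nominalAreaFraction(x)))
    if (!is.null(x$potential)) { cat("  true "); show(x$potential) }
    invisible(x)
}

#' Nominal circle-covered area fraction
#'
#' \eqn{M \pi R^2 / |\Omega|} (overlaps not subtracted).
#'
#' @param spec a \code{scenarioSpec}.
#' @return the nominal fraction.
#' @export
nominalAreaFraction <- function(spec)
    spec$M * pi * spec$R^2 / prod(spec$domainSize)

# regular polygon approximating a circle
.circle_polygon <- function(center, R, V) {
    a <- 2 * pi * (seq_len(V) - 1L) / V
    cbind(center[1L] + R * cos(a), center[2L] + R * sin(a))
}

# circle centres for each arrangement, all within [R, size - R]
.circle_centers <- function(spec) {
    W <- spec$domainSize[1L]; H <- spec$domainSize[2L]
    R <- spec$R; M <- spec$M
    switch(spec$arrangement,
        random = cbind(stats::runif(M, R, W - R), stats::runif(M, R, H - R)),
        regular = {
            nside <- ceiling(sqrt(M))
            sx <- (W - 2 * R) / nside
            sy <- (H - 2 * R) / nside
            if (min(sx, sy) < 2 * R)
                .stopf("infeasible regular packing: %d circles of radius %g in %g x %g",
                       M, R, W, H)
            g <- expand.grid(i = seq_len(nside), j = seq_len(nside))[seq_len(M), ]
            jit <- min(sx, sy) / 2 - R
            cbind(R + (g$i - 0.5) * sx + stats::runif(M, -jit, jit),
                  R + (g$j - 0.5) * sy + stats::runif(M, -jit, jit))
        },
        clustered = {
            par <- cbind(stats::runif(spec$parents, R, W - R),
                         stats::runif(spec$parents, R, H - R))
            idx <- sample.int(spec$parents, M, replace = TRUE)
            pts <- matrix(NA_real_, M, 2L)
            for (i in seq_len(M)) {
                repeat {
                    p <- par[idx[i], ] + stats::rnorm(2L, 0, spec$offspringSd)
                    if (p[1L] >= R && p[1L] <= W - R &&
                        p[2L] >= R && p[2L] <= H - R) break
                }
                pts[i, ] <- p
            }
            pts
        })
}

#' Generate the circular reference objects of a scenario
#'
#' Draws the circle centres according to the arrangement, renders each
#' circle as a regular polygon, and returns the objects together with the
#' rectangular domain. Reproducible given the spec's seed.
#'
#' @param spec a \code{scenarioSpec}.
#' @return list with \code{Y} (list of polygon matrices) and
#'   \code{domain} (a [CellDomain-class]).
#' @export
generateCircles <- function(spec) {
    stopifnot(inherits(spec, "scenarioSpec"))
    centers <- .with_seed(spec$seed, .circle_centers(spec))
    Y <- lapply(seq_len(spec$M), function(i)
        .circle_polygon(centers[i, ], spec$R, spec$vertices))
    list(Y = Y, domain = rectangleDomain(spec$domainSize[1L],
                                         spec$domainSize[2L]),
         centers = centers)
}

#' Place query points under a potential
#'
#' Exact rejection sampler for the factorised Gibbs density: proposals
#' are uniform in the domain and accepted with probability
#' \eqn{\exp(-(\phi(d(x, Y)) - \phi_{\min}))}, where d is the signed
#' nearest-neighbour distance, so attractive potentials pull points into
#' the reference outlines. With \code{potential = NULL} the points are
#' uniform in the domain.
#'
#' @param domain a [CellDomain-class].
#' @param Y list of reference objects.
#' @param potential a potential or NULL.
#' @param n number of points to place.
#' @param seed optional integer seed.
#' @param batch proposals per rejection round.
#' @return numeric matrix of n points (columns x, y).
#' @export
placePoints <- function(domain, Y, potential = NULL, n, seed = NULL,
                        batch = 4096L) {
    stopifnot(is(domain, "CellDomain"), .is_count(n))
    phiMin <- 0
    if (!is.null(potential)) {
        # lower bound of phi over the range of attainable distances
        rng <- c(-max(vapply(Y, function(y)
                    if (nrow(y) > 1L) diff(range(y)) else 0, 1)),
                 sqrt(domain@width^2 + domain@height^2))
        dgrid <- seq(rng[1L], rng[2L], length.out = 4096L)
        phiMin <- min(potentialValue(potential, dgrid), 0)
        if (!is.finite(phiMin))
            .stopf("potential is unbounded below on the attainable distance range")
    }
    .with_seed(seed, {
        acc <- matrix(numeric(0), 0, 2L)
        proposed <- 0L
        while (nrow(acc) < n) {
            P <- cbind(stats::runif(batch, 0, domain@width),
                       stats::runif(batch, 0, domain@height))
            P <- P[.in_domain(domain, P), , drop = FALSE]
            proposed <- proposed + batch
            if (nrow(P)) {
                keep <- if (is.null(potential)) rep(TRUE, nrow(P)) else {
                    phi <- potentialValue(potential, .nn_signed(P, Y))
                    stats::runif(nrow(P)) < exp(-(phi - phiMin))
                }
                acc <- rbind(acc, P[keep, , drop = FALSE])
            }
            if (proposed >= 1e4 && nrow(acc) / proposed < 1e-4)
                .stopf(paste0("rejection sampler acceptance rate below 1e-4; ",
                              "rescale the potential or enlarge the domain"))
        }
        unname(acc[seq_len(n), , drop = FALSE])
    })
}

#' Generate a complete synthetic scenario
#'
#' Composes [generateCircles()], [placePoints()], [nnDistances()] and
#' [estimateStateDensity()] into a ready-to-analyse [CellData-class]
#' carrying its ground truth (the spec and the true potential).
#'
#' @param spec a \code{scenarioSpec}.
#' @param gridSpacing spacing h for the state-density grid sample.
#' @param cellId label for the generated cell.
#' @param q optional precomputed [StateDensity-class] for this context
#'   (saves recomputation when many cells share one context).
#' @return a [CellData-class].
#' @export
generateScenario <- function(spec, gridSpacing = 0.25, cellId = "sim",
                             q = NULL) {
    stopifnot(inherits(spec, "scenarioSpec"))
    ctx <- generateCircles(spec)
    X <- placePoints(ctx$domain, ctx$Y, spec$potential, spec$N,
                     seed = if (is.null(spec$seed)) NULL else spec$seed + 1L)
    objs <- objectSet(X, ctx$Y, cellId = cellId, domain = ctx$domain)
    D <- nnDistances(objs)
    if (is.null(q))
        q <- estimateStateDensity(ctx$domain, ctx$Y, gridSpacing = gridSpacing)
    # KDE smoothing can leave observed distances marginally outside the
    # padded support only in pathological cases; fail loudly if so.
    cellData(D, q, cellId = cellId,
             truth = list(spec = spec, potential = spec$potential),
             objects = objs)
}
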