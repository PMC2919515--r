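#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gibbsColoc, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# CellDomain: the bounded observation region Omega
# ---------------------------------------------------------------------------

#' Bounded observation domain
#'
#' The region \eqn{\Omega} in which both object populations live, e.g. the
#' outline of a cell. A domain is represented either as a simple polygon
#' (continuous coordinates, pixel units) or as a binary mask whose pixel
#' \code{(r, c)} (0-based) occupies \eqn{[c, c+1) \times [r, r+1)} so that
#' its centre is \eqn{(c + 0.5, r + 0.5)}.
#'
#' @slot type either \code{"polygon"} or \code{"mask"}.
#' @slot polygon numeric matrix of vertices (columns x, y); empty for masks.
#' @slot mask logical matrix (rows = y/pixel rows); empty for polygons.
#' @slot width,height bounding-box extent in pixels.
#'
#' @seealso [rectangleDomain()], [polygonDomain()], [maskDomain()]
#' @export
setClass("CellDomain",
    slots = c(type = "character", polygon = "matrix", mask = "matrix",
              width = "numeric", height = "numeric"),
    validity = function(object) {
        if (!object@type %in% c("polygon", "mask"))
            return("type must be 'polygon' or 'mask'")
        if (object@type == "polygon") {
            v <- object@polygon
            if (nrow(v) < 3L) return("domain polygon needs >= 3 vertices")
            if (.polygon_area(v) <= 0)
                return("domain polygon has non-positive area")
        } else {
            if (!is.logical(object@mask) || !any(object@mask))
                return("domain mask must contain at least one TRUE pixel")
        }
        if (object@width <= 0 || object@height <= 0)
            return("domain extent must be positive")
        TRUE
    })

# shoelace area (absolute)
.polygon_area <- function(v) {
    x <- v[, 1L]; y <- v[, 2L]
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    abs(sum(x[j] * y - x * y[j])) / 2
}

#' @describeIn CellDomain construct a rectangular polygon domain
#'   \eqn{[0, width] \times [0, height]}.
#' @param width,height extent in pixels.
#' @export
rectangleDomain <- function(width, height = width) {
    polygonDomain(cbind(x = c(0, width, width, 0),
                        y = c(0, 0, height, height)))
}

#' @describeIn CellDomain construct a domain from a simple polygon
#'   (matrix with columns x, y; a repeated closing vertex is dropped).
#' @param vertices numeric matrix of polygon vertices.
#' @export
polygonDomain <- function(vertices) {
    v <- .normalize_ring(vertices)
    new("CellDomain", type = "polygon", polygon = v,
        mask = matrix(logical(0), 0, 0),
        width = max(v[, 1L]), height = max(v[, 2L]))
}

#' @describeIn CellDomain construct a domain from a binary mask
#'   (logical or numeric matrix; nonzero = inside).
#' @param mask matrix; nonzero/TRUE pixels are inside the domain.
#' @export
maskDomain <- function(mask) {
    m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
    new("CellDomain", type = "mask", polygon = matrix(numeric(0), 0, 2),
        mask = m, width = ncol(m), height = nrow(m))
}

#' @describeIn CellDomain area of the domain in square pixels (polygon:
#'   shoelace formula; mask: number of TRUE pixels).
#' @param domain a \code{CellDomain}.
#' @export
domainArea <- function(domain) {
    stopifnot(is(domain, "CellDomain"))
    if (domain@type == "polygon") .polygon_area(domain@polygon)
    else sum(domain@mask)
}

setMethod("show", "CellDomain", function(object) {
    cat(sprintf("CellDomain (%s), %g x %g px, area %.4g px^2\n",
                object@type, object@width, object@height,
                domainArea(object)))
})

# drop a duplicated closing vertex and validate vertex count
.normalize_ring <- function(v) {
    v <- as.matrix(v)
    if (ncol(v) != 2L) .stopf("polygon vertices must be an n x 2 matrix")
    storage.mode(v) <- "double"
    n <- nrow(v)
    if (n >= 2L && all(abs(v[1L, ] - v[n, ]) < 1e-12)) v <- v[-n, , drop = FALSE]
    if (nrow(unique(round(v, 9L))) < 3L)
        .stopf("degenerate polygon: fewer than 3 distinct vertices")
    v
}

# ---------------------------------------------------------------------------
# ObjectSet: the two populations X (query points) and Y (reference objects)
# ---------------------------------------------------------------------------

#' Two populations of sub-cellular objects
#'
#' Holds the query points X (e.g. virus centroids) and the reference
#' objects Y (points or closed outlines, e.g. endosomes) of one cell,
#' optionally together with the bounded domain they live in.
#'
#' @slot X numeric matrix (columns x, y) of query point coordinates.
#' @slot Y list of reference objects; each element is a 1-row matrix
#'   (point object) or an n>=3-row matrix (polygon outline; the closing
#'   vertex is implicit).
#' @slot cellId opaque cell label.
#' @slot domain a [CellDomain-class] or NULL.
#' @export
setClass("ObjectSet",
    slots = c(X = "matrix", Y = "list", cellId = "character", domain = "ANY"),
    validity = function(object) {
        if (ncol(object@X) != 2L) return("X must have two columns (x, y)")
        for (y in object@Y) {
            if (!is.matrix(y) || ncol(y) != 2L)
                return("each Y object must be an n x 2 matrix")
            if (nrow(y) == 2L)
                return("Y outline with 2 vertices is degenerate")
        }
        if (!is.null(object@domain)) {
            if (!is(object@domain, "CellDomain"))
                return("domain must be a CellDomain or NULL")
            pts <- rbind(object@X, do.call(rbind, object@Y))
            if (nrow(pts) && !all(.in_domain(object@domain, pts)))
                return("all X and Y vertices must lie inside the domain")
        }
        TRUE
    })

#' @describeIn ObjectSet constructor. Polygon outlines may be given closed
#'   (first vertex repeated last); they are normalised to an open ring.
#' @param X numeric matrix (or 2-column data frame) of query points.
#' @param Y list of reference objects (1-row matrices for points, n x 2
#'   matrices for outlines).
#' @param cellId cell label.
#' @param domain optional [CellDomain-class].
#' @export
objectSet <- function(X, Y, cellId = "cell", domain = NULL) {
    X <- as.matrix(X)
    if (length(X) == 0L) X <- matrix(numeric(0), 0, 2)
    storage.mode(X) <- "double"
    dimnames(X) <- list(NULL, c("x", "y"))
    Y <- lapply(Y, function(y) {
        y <- as.matrix(y)
        storage.mode(y) <- "double"
        if (nrow(y) > 1L) y <- .normalize_ring(y)
        dimnames(y) <- list(NULL, c("x", "y"))
        y
    })
    new("ObjectSet", X = X, Y = Y, cellId = as.character(cellId),
        domain = domain)
}

setMethod("show", "ObjectSet", function(object) {
    np <- sum(vapply(object@Y, nrow, 1L) == 1L)
    cat(sprintf("ObjectSet '%s': %d X points, %d Y objects (%d points, %d outlines)%s\n",
                object@cellId, nrow(object@X), length(object@Y), np,
                length(object@Y) - np,
                if (is.null(object@domain)) "" else ", domain attached"))
})

# ---------------------------------------------------------------------------
# DistanceSample: observed NN distances, the sufficient data for inference
# ---------------------------------------------------------------------------

#' Sample of signed nearest-neighbour distances
#'
#' The distances \eqn{d_i = \min_j d(x_i, y_j)} of the query points to
#' their nearest reference object; negative values indicate points inside
#' a reference outline. This is the sufficient data for all inference in
#' the package.
#'
#' @slot d numeric vector of finite signed distances (pixels).
#' @slot cellId cell label.
#' @export
setClass("DistanceSample",
    slots = c(d = "numeric", cellId = "character"),
    validity = function(object) {
        if (length(object@d) < 1L) return("need at least one distance")
        if (!all(is.finite(object@d))) return("distances must be finite")
        TRUE
    })

#' @describeIn DistanceSample constructor.
#' @param d numeric vector of signed distances.
#' @param cellId cell label.
#' @export
distanceSample <- function(d, cellId = "cell")
    new("DistanceSample", d = as.numeric(d), cellId = as.character(cellId))

#' @describeIn DistanceSample extract the distance vector.
#' @param object a \code{DistanceSample}.
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))

#' @rdname DistanceSample-class
#' @export
setMethod("distances", "DistanceSample", function(object) object@d)

#' Number of observations
#'
#' @param x a [DistanceSample-class].
#' @return sample size N.
#' @export
setMethod("length", "DistanceSample", function(x) length(x@d))

setMethod("show", "DistanceSample", function(object) {
    cat(sprintf("DistanceSample '%s': N = %d, range [%.3g, %.3g] px\n",
                object@cellId, length(object@d), min(object@d), max(object@d)))
})

# ---------------------------------------------------------------------------
# StateDensity: the null distance distribution q(d)
# ---------------------------------------------------------------------------

#' State density q(d)
#'
#' The distribution of nearest-neighbour distances expected for a
#' uniformly random point in the domain given the reference objects: the
#' "no interaction" null distribution summarising the cellular context.
#' Stored on a dense grid; between grid nodes the density is understood
#' as piecewise linear, and all quadrature, CDF and sampling operations
#' in the package use that convention consistently.
#'
#' @slot grid strictly increasing distance values (pixels).
#' @slot density q evaluated on the grid (1/pixels), trapezoid-normalised.
#' @slot support range \code{c(dmin, dmax)} covered by the grid.
#' @slot gridSpacing spatial sampling step h used for the grid sample.
#' @slot bandwidth Gaussian KDE bandwidth (pixels).
#' @slot nSamples number of domain grid points the estimate is based on.
#' @export
setClass("StateDensity",
    slots = c(grid = "numeric", density = "numeric", support = "numeric",
              gridSpacing = "numeric", bandwidth = "numeric",
              nSamples = "numeric"),
    validity = function(object) {
        if (length(object@grid) < 2L) return("grid needs >= 2 nodes")
        if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
        if (length(object@grid) != length(object@density))
            return("grid and density lengths differ")
        if (any(object@density < 0)) return("density must be non-negative")
        if (abs(.trapz(object@grid, object@density) - 1) > 1e-6)
            return("density must integrate to 1 (trapezoid, 1e-6)")
        if (object@support[1L] < object@grid[1L] - 1e-9 ||
            object@support[2L] > object@grid[length(object@grid)] + 1e-9)
            return("grid must cover the support")
        TRUE
    })

setMethod("show", "StateDensity", function(object) {
    cat(sprintf(paste0("StateDensity: support [%.3g, %.3g] px, %d grid nodes, ",
                       "bandwidth %.3g px (h = %.3g, %g samples)\n"),
                object@support[1L], object@support[2L], length(object@grid),
                object@bandwidth, object@gridSpacing, object@nSamples))
})

# ---------------------------------------------------------------------------
# Potentials
# ---------------------------------------------------------------------------

.potential_families <- c("step", "plummer", "hermquist", "linear1", "linear2")

#' Parametric interaction potential
#'
#' A pairwise interaction potential \eqn{\phi(d) = \epsilon f((d - t)/\sigma)}
#' with strength \eqn{\epsilon} (dimensionless; positive = attraction),
#' length scale \eqn{\sigma > 0} (pixels) and threshold/shift \eqn{t}
#' (pixels). All shape functions \eqn{f} satisfy \eqn{f \le 0} and
#' \eqn{f(z) \to 0} as \eqn{z \to +\infty} with \eqn{f = -1} at the
#' origin region, so \eqn{\epsilon} is the potential depth.
#'
#' @slot family one of \code{"step"}, \code{"plummer"}, \code{"hermquist"},
#'   \code{"linear1"}, \code{"linear2"}.
#' @slot epsilon interaction strength.
#' @slot sigma length scale (pixels).
#' @slot t threshold/shift (pixels).
#' @seealso [shapeFunction()], [potentialValue()]
#' @export
setClass("InteractionPotential",
    slots = c(family = "character", epsilon = "numeric", sigma = "numeric",
              t = "numeric"),
    validity = function(object) {
        if (!object@family %in% .potential_families)
            return(sprintf("unknown potential family '%s'", object@family))
        if (!is.finite(object@sigma) || object@sigma <= 0)
            return("sigma must be positive")
        if (!is.finite(object@epsilon)) return("epsilon must be finite")
        TRUE
    })

#' @describeIn InteractionPotential constructor.
#' @param family shape family identifier.
#' @param epsilon strength.
#' @param sigma scale (pixels).
#' @param t threshold/shift (pixels).
#' @export
interactionPotential <- function(family, epsilon, sigma = 1, t = 0)
    new("InteractionPotential", family = match.arg(family, .potential_families),
        epsilon = epsilon, sigma = sigma, t = t)

setMethod("show", "InteractionPotential", function(object) {
    cat(sprintf("InteractionPotential: %s, epsilon = %.4g, sigma = %.4g px, t = %.4g px\n",
                object@family, object@epsilon, object@sigma, object@t))
})

#' Piecewise-linear non-parametric potential
#'
#' A potential expressed as a weighted sum of triangular (hat) kernels
#' centred on equally spaced support points, i.e. the piecewise-linear
#' interpolant through \code{(supportPoints, weights)}. The last weight is
#' fixed at 0 so the potential vanishes beyond the last support point;
#' below the first support point it is continued at \code{weights[1]}.
#'
#' @slot supportPoints strictly increasing, equally spaced nodes (pixels).
#' @slot weights kernel weights; the last one must be 0.
#' @slot spacing node spacing h (pixels).
#' @slot smoothness the prior scale s used when the potential was fitted.
#' @export
setClass("NonparametricPotential",
    slots = c(supportPoints = "numeric", weights = "numeric",
              spacing = "numeric", smoothness = "numeric"),
    validity = function(object) {
        P <- length(object@supportPoints)
        if (P < 2L) return("need >= 2 support points")
        if (length(object@weights) != P)
            return("weights and supportPoints lengths differ")
        dd <- diff(object@supportPoints)
        if (any(dd <= 0)) return("support points must be strictly increasing")
        if (max(abs(dd - object@spacing)) > 1e-8)
            return("support points must be equally spaced by `spacing`")
        if (abs(object@weights[P]) > 1e-12)
            return("last weight must be 0")
        TRUE
    })

#' @describeIn NonparametricPotential constructor.
#' @param supportPoints equally spaced nodes.
#' @param weights kernel weights (last must be 0).
#' @param spacing node spacing (defaults to the observed spacing).
#' @param smoothness prior scale s.
#' @export
nonparametricPotential <- function(supportPoints, weights,
                                   spacing = diff(supportPoints)[1L],
                                   smoothness = NA_real_)
    new("NonparametricPotential", supportPoints = supportPoints,
        weights = weights, spacing = spacing, smoothness = smoothness)

setMethod("show", "NonparametricPotential", function(object) {
    cat(sprintf(paste0("NonparametricPotential: %d support points on [%g, %g] px",
                       " (h = %g), depth %.4g\n"),
                length(object@supportPoints), min(object@supportPoints),
                max(object@supportPoints), object@spacing,
                min(object@weights)))
})

setClassUnion("AnyPotential", c("InteractionPotential", "NonparametricPotential"))

# ---------------------------------------------------------------------------
# ModelDensity: p(d | q, phi)
# ---------------------------------------------------------------------------

#' Model distance density p(d)
#'
#' The Gibbs distance model \eqn{p(d) = q(d) e^{-\phi(d)} / Z} evaluated
#' on the state-density grid (augmented with the potential's discontinuity
#' points, if any), together with the partition function Z.
#'
#' @slot grid distance nodes (pixels).
#' @slot density model density values.
#' @slot Z partition function.
#' @export
setClass("ModelDensity",
    slots = c(grid = "numeric", density = "numeric", Z = "numeric"),
    validity = function(object) {
        if (any(diff(object@grid) < 0)) return("grid must be non-decreasing")
        if (any(object@density < 0)) return("density must be non-negative")
        if (!is.finite(object@Z) || object@Z <= 0) return("Z must be positive")
        if (abs(.trapz(object@grid, object@density) - 1) > 1e-6)
            return("density must integrate to 1 (trapezoid, 1e-6)")
        TRUE
    })

setMethod("show", "ModelDensity", function(object) {
    cat(sprintf("ModelDensity: %d nodes, Z = %.6g\n",
                length(object@grid), object@Z))
})

# ---------------------------------------------------------------------------
# CellData: everything inference needs for one cell
# ---------------------------------------------------------------------------

#' Per-cell analysis bundle
#'
#' The observed distances and the state density of one cell, plus optional
#' covariates (e.g. time post infection) and, for synthetic scenarios, the
#' generating ground truth.
#'
#' @slot cellId cell label.
#' @slot distances a [DistanceSample-class].
#' @slot q a [StateDensity-class].
#' @slot covariates named list of covariates.
#' @slot truth named list with ground-truth information (synthetic data
#'   only; empty otherwise).
#' @slot objects the underlying [ObjectSet-class] or NULL.
#' @export
setClass("CellData",
    slots = c(cellId = "character", distances = "DistanceSample",
              q = "StateDensity", covariates = "list", truth = "list",
              objects = "ANY"),
    validity = function(object) {
        d <- object@distances@d
        s <- object@q@support
        if (any(d < s[1L] - 1e-9 | d > s[2L] + 1e-9))
            return("all distances must lie within the state-density support")
        TRUE
    })

#' @describeIn CellData constructor.
#' @param distances a [DistanceSample-class].
#' @param q a [StateDensity-class].
#' @param cellId cell label.
#' @param covariates named list.
#' @param truth named list (synthetic ground truth).
#' @param objects optional [ObjectSet-class].
#' @export
cellData <- function(distances, q, cellId = distances@cellId,
                     covariates = list(), truth = list(), objects = NULL)
    new("CellData", cellId = as.character(cellId), distances = distances,
        q = q, covariates = covariates, truth = truth, objects = objects)

#' @rdname CellData-class
#' @export
setMethod("distances", "CellData", function(object) object@distances@d)

setMethod("show", "CellData", function(object) {
    cat(sprintf("CellData '%s': N = %d distances%s%s\n", object@cellId,
                length(object@distances),
                if (length(object@covariates))
                    paste0(", covariates: ",
                           paste(names(object@covariates), collapse = ", "))
                else "",
                if (length(object@truth)) ", ground truth attached" else ""))
})
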