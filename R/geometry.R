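# Signed distances, domain grids, point-in-domain tests.
#
# Sign convention: the distance from a point to a polygonal reference
# object is the minimum distance to the outline, negative iff the point
# lies strictly inside, and 0 on the boundary (within 1e-9 px).

.boundary_tol <- 1e-9

# flatten a list of reference objects for the C++ kernel
.flatten_objects <- function(Y) {
    if (length(Y) == 0L) .stopf("reference object set Y is empty")
    lens <- vapply(Y, nrow, 1L)
    bad <- lens == 2L
    if (any(bad)) .stopf("degenerate polygon (object %d): 2 vertices",
                         which(bad)[1L])
    V <- do.call(rbind, Y)
    cx <- vapply(Y, function(y) mean(y[, 1L]), 1)
    cy <- vapply(Y, function(y) mean(y[, 2L]), 1)
    rmax <- vapply(seq_along(Y), function(j)
        sqrt(max((Y[[j]][, 1L] - cx[j])^2 + (Y[[j]][, 2L] - cy[j])^2)), 1)
    list(vx = V[, 1L], vy = V[, 2L],
         start = c(0L, cumsum(lens))[seq_along(Y)],
         len = as.integer(lens), cx = cx, cy = cy, rmax = rmax)
}

# nn signed distances from an n x 2 point matrix to a list of objects
.nn_signed <- function(P, Y) {
    fo <- .flatten_objects(Y)
    cpp_nn_signed(P[, 1L], P[, 2L], fo$vx, fo$vy, fo$start, fo$len,
                  fo$cx, fo$cy, fo$rmax, .boundary_tol)
}

#' Signed distance from a point to a reference object
#'
#' Euclidean distance for a point object; for a polygon outline, the
#' minimum distance to the outline, negative iff the point is inside
#' (even-odd rule, boundary tolerance 1e-9 px).
#'
#' @param x numeric length-2 point (pixels).
#' @param y reference object: a length-2 numeric (point) or an n x 2
#'   vertex matrix (closed outline; closing vertex optional).
#' @return signed distance in pixels.
#' @examples
#' signedDistance(c(3, 4), c(0, 0))  # 5
#' @export
signedDistance <- function(x, y) {
    stopifnot(is.numeric(x), length(x) == 2L)
    if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
    y <- as.matrix(y)
    if (nrow(y) > 1L) y <- .normalize_ring(y)
    .nn_signed(matrix(x, nrow = 1L), list(y))
}

#' Nearest-neighbour distances of an object set
#'
#' Computes \eqn{d_i = \min_j d(x_i, y_j)}, the signed distance from each
#' query point to its nearest reference object, in the order of the X
#' points.
#'
#' @param objs an [ObjectSet-class].
#' @return a [DistanceSample-class].
#' @export
nnDistances <- function(objs) {
    stopifnot(is(objs, "ObjectSet"))
    if (length(objs@Y) == 0L)
        .stopf("cannot compute nearest-neighbour distances: Y is empty")
    if (nrow(objs@X) == 0L)
        .stopf("cannot compute nearest-neighbour distances: X is empty")
    distanceSample(.nn_signed(objs@X, objs@Y), objs@cellId)
}

# is each point of P inside the domain?
.in_domain <- function(domain, P) {
    P <- as.matrix(P)
    if (domain@type == "polygon") {
        v <- domain@polygon
        cpp_in_polygon(P[, 1L], P[, 2L], v[, 1L], v[, 2L], .boundary_tol)
    } else {
        m <- domain@mask
        c0 <- floor(P[, 1L]); r0 <- floor(P[, 2L])
        ok <- c0 >= 0 & c0 < ncol(m) & r0 >= 0 & r0 < nrow(m)
        ins <- logical(nrow(P))
        ins[ok] <- m[cbind(r0[ok] + 1L, c0[ok] + 1L)]
        ins
    }
}

#' Cell-centred Cartesian grid clipped to a domain
#'
#' Lattice points with the given spacing, starting at
#' \code{(spacing/2, spacing/2)} (cell-centred, for unbiased area
#' coverage), restricted to the domain interior. Used to sample the state
#' density exhaustively.
#'
#' @param domain a [CellDomain-class].
#' @param spacing lattice spacing in pixels (> 0).
#' @return numeric matrix of points (columns x, y).
#' @export
domainGrid <- function(domain, spacing) {
    stopifnot(is(domain, "CellDomain"))
    if (!is.numeric(spacing) || spacing <= 0)
        .stopf("grid spacing must be positive")
    if (spacing / 2 >= domain@width || spacing / 2 >= domain@height)
        .stopf("grid spacing %g exceeds the domain extent", spacing)
    xs <- seq(spacing / 2, domain@width, by = spacing)
    ys <- seq(spacing / 2, domain@height, by = spacing)
    P <- cbind(x = rep(xs, times = length(ys)),
               y = rep(ys, each = length(xs)))
    P <- P[.in_domain(domain, P), , drop = FALSE]
    if (nrow(P) == 0L)
        .stopf("no grid points fall inside the domain at spacing %g", spacing)
    P
}
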