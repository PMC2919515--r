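# Potential shape families and evaluation.
#
# All shapes use the attractive convention: f <= 0 with depth -1 at/below
# the origin region and f -> 0 as z -> +infinity, so that a positive
# strength epsilon means attraction toward the reference objects.

#' Potential shape functions f(z)
#'
#' Dimensionless shapes of the parametric potential families, evaluated
#' at \code{z = (d - t)/sigma}:
#' \describe{
#'   \item{step}{\eqn{f(z) = -1} for \eqn{z < 0}, else 0 — the potential
#'     underlying classical threshold co-localization.}
#'   \item{plummer}{\eqn{f(z) = -1} for \eqn{z < 0},
#'     \eqn{-1/\sqrt{1 + z^2}} for \eqn{z \ge 0} — a step generalisation
#'     with a plateau below the origin and an overall 1/d tail, finite
#'     value and slope everywhere (the shape is C1: both one-sided slopes
#'     vanish at 0). As \eqn{\sigma \to 0} it degenerates to the step.}
#'   \item{hermquist}{\eqn{f(z) = -1/(1+z)} for \eqn{z \ge 0},
#'     continued as \eqn{f(z) = -1 + z} for \eqn{z < 0} (C1 continuation);
#'     a long-ranged 1/d tail.}
#'   \item{linear1}{\eqn{f(z) = \min(z - 1, 0)} — linear ramp, no plateau.}
#'   \item{linear2}{\eqn{f(z) = -1} for \eqn{z \le 0}, \eqn{z - 1} on
#'     \eqn{(0, 1)}, 0 beyond — a step generalisation with a plateau
#'     below the origin.}
#' }
#'
#' @param family family identifier.
#' @param z dimensionless argument (vectorised).
#' @return f(z), same length as z.
#' @examples
#' shapeFunction("step", c(-1, 0.5))   # -1, 0
#' shapeFunction("plummer", 0)         # -1
#' @export
shapeFunction <- function(family, z) {
    family <- match.arg(family, .potential_families)
    # branch-free forms: these run on multi-million element arrays inside
    # the Monte-Carlo machinery, and all preserve dim attributes
    switch(family,
        step      = -(z < 0),
        plummer   = -1 / sqrt(1 + (z > 0) * z * z),
        hermquist = {
            f <- -1 / (1 + (z > 0) * z)
            neg <- z < 0
            f[neg] <- -1 + z[neg]
            f
        },
        linear1   = {
            f <- z - 1
            f[f > 0] <- 0
            f
        },
        linear2   = {
            f <- z - 1
            f[f > 0] <- 0
            f[f < -1] <- -1
            f
        })
}

#' Evaluate a potential at given distances
#'
#' For a parametric potential, \eqn{\phi(d) = \epsilon f((d - t)/\sigma)};
#' for a non-parametric potential, the piecewise-linear interpolant
#' through its (supportPoints, weights), continued at \code{weights[1]}
#' below the first node and at 0 beyond the last.
#'
#' @param pot an [InteractionPotential-class] or
#'   [NonparametricPotential-class].
#' @param d distances in pixels (vectorised).
#' @return potential values \eqn{\phi(d)}.
#' @export
setGeneric("potentialValue", function(pot, d) standardGeneric("potentialValue"))

#' @rdname potentialValue
#' @export
setMethod("potentialValue", "InteractionPotential", function(pot, d) {
    pot@epsilon * shapeFunction(pot@family, (d - pot@t) / pot@sigma)
})

#' @rdname potentialValue
#' @export
setMethod("potentialValue", "NonparametricPotential", function(pot, d) {
    stats::approx(pot@supportPoints, pot@weights, xout = d,
                  yleft = pot@weights[1L], yright = 0)$y
})

# distances at which phi is discontinuous (quadrature must split there)
.potential_breaks <- function(pot) {
    if (is(pot, "InteractionPotential") && pot@family == "step") pot@t
    else numeric(0)
}

#' Default non-parametric support points
#'
#' P equally spaced nodes starting at \code{d1} with spacing \code{h}
#' (defaults: 21 points from -5 to 95 px, spacing 5).
#'
#' @param P number of support points.
#' @param d1 first node (pixels).
#' @param h node spacing (pixels).
#' @return numeric vector of nodes.
#' @export
nonparametricSupport <- function(P = 21L, d1 = -5, h = 5)
    d1 + h * (seq_len(P) - 1L)

#' Plot a potential
#'
#' @param x a potential object.
#' @param from,to distance range to draw (pixels).
#' @param n number of evaluation points.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the evaluated data frame.
#' @export
setMethod("plot", signature(x = "AnyPotential", y = "missing"),
    function(x, from = -10, to = 50, n = 512L, ...) {
        d <- seq(from, to, length.out = n)
        phi <- potentialValue(x, d)
        graphics::plot(d, phi, type = "l", xlab = "d [px]",
                       ylab = expression(phi(d)), ...)
        graphics::abline(h = 0, lty = 3)
        invisible(data.frame(d = d, phi = phi))
    })
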