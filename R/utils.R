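# internal numerical helpers

# trapezoid rule on arbitrary (sorted) nodes
.trapz <- function(x, y) {
    n <- length(x)
    if (n < 2L) return(0)
    sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
.cumtrapz <- function(x, y) {
    n <- length(x)
    c(0, cumsum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2))
}

# Run `code` under a temporary RNG state seeded with `seed`; if seed is
# NULL the global stream is used (and advanced) as usual.
.with_seed <- function(seed, code) {
    if (is.null(seed)) return(code)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    code
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L &&
    is.finite(x) && x >= 1 && x == round(x)

# Exact integral of the piecewise-linear density (x, y) over (-Inf, t].
# All densities in this package are understood as piecewise linear on
# their node set, so this is the canonical CDF used everywhere.
.pl_cdf_at <- function(x, y, t) {
    Fx <- .cumtrapz(x, y)
    tot <- Fx[length(Fx)]
    vapply(t, function(tt) {
        if (tt <= x[1L]) return(0)
        if (tt >= x[length(x)]) return(tot)
        i <- findInterval(tt, x)
        h <- x[i + 1L] - x[i]
        yt <- y[i] + (y[i + 1L] - y[i]) * (tt - x[i]) / h
        Fx[i] + (y[i] + yt) * (tt - x[i]) / 2
    }, numeric(1))
}

# Inverse-CDF sampler factory for a piecewise-linear density on nodes
# (x, y); the density need not be normalised. Within a cell the CDF is
# quadratic; the stable root s = 2 du / (y_i + sqrt(y_i^2 + 2 a du))
# degenerates gracefully to du/y_i for flat cells.
.pl_sampler_factory <- function(x, y) {
    Fx <- .cumtrapz(x, y)
    tot <- Fx[length(Fx)]
    if (tot <= 0) .stopf("degenerate density: zero total mass")
    nc <- length(x) - 1L
    slope <- (y[-1L] - y[-length(y)]) / (x[-1L] - x[-length(x)])
    h <- x[-1L] - x[-length(x)]
    function(u) {
        target <- u * tot
        i <- findInterval(target, Fx, rightmost.closed = TRUE)
        i[i < 1L] <- 1L
        i[i > nc] <- nc
        du <- target - Fx[i]
        yi <- y[i]
        disc <- yi * yi + 2 * slope[i] * du
        disc[disc < 0] <- 0
        den <- yi + sqrt(disc)
        den[den <= 0] <- 1             # du = 0 there; s = 0 is correct
        s <- 2 * du / den
        s[s < 0] <- 0
        hi <- h[i]
        over <- s > hi
        s[over] <- hi[over]
        x[i] + s
    }
}

# one-shot convenience wrapper
.pl_quantile <- function(x, y, u) .pl_sampler_factory(x, y)(u)
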