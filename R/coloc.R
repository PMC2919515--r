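# Classical object-based co-localization, the step-potential strength
# estimator, and the exact binomial test / power machinery.

#' Co-localization measure
#'
#' \eqn{C^t = \#\{d_i < t\} / N}: the fraction of query objects whose
#' nearest-neighbour distance is strictly below the threshold (ties at
#' exactly t count as not co-localized).
#'
#' @param D a [DistanceSample-class] or numeric vector.
#' @param t distance threshold (pixels).
#' @return C in \[0, 1\].
#' @export
colocMeasure <- function(D, t) {
    d <- if (is(D, "DistanceSample")) D@d else as.numeric(D)
    mean(d < t)
}

#' Step-potential strength estimator
#'
#' The closed-form maximum-likelihood estimator of the step-potential
#' strength obtained from the observed and baseline co-localization,
#' \eqn{\hat\epsilon = \log[C(1 - C_0) / (C_0(1 - C))]} (a log odds
#' ratio). Boundary values of C or C0 yield a flagged non-finite status
#' instead of a silent infinity.
#'
#' @param C observed co-localization in \[0, 1\].
#' @param C0 baseline co-localization in (0, 1).
#' @return list with \code{epsilon} (numeric, NA when flagged) and
#'   \code{status} ("ok", "infinite", or "undefined").
#' @examples
#' epsilonHatStep(0.8, 0.5)$epsilon  # log(4)
#' @export
epsilonHatStep <- function(C, C0) {
    stopifnot(length(C) == 1L, length(C0) == 1L,
              C >= 0, C <= 1, C0 >= 0, C0 <= 1)
    if (C0 <= 0 || C0 >= 1)
        return(list(epsilon = NA_real_, status = "undefined"))
    if (C <= 0 || C >= 1)
        return(list(epsilon = NA_real_, status = "infinite"))
    list(epsilon = log(C * (1 - C0) / (C0 * (1 - C))), status = "ok")
}

#' Full co-localization analysis of one sample
#'
#' Combines the observed measure, the baseline from the state density,
#' and the step-strength estimate.
#'
#' @param D a [DistanceSample-class].
#' @param q a [StateDensity-class].
#' @param t distance threshold (pixels).
#' @return an object of class \code{colocResult}: list with t, N, C, C0,
#'   epsilon, status.
#' @export
colocAnalysis <- function(D, q, t = 0) {
    stopifnot(is(D, "DistanceSample"), is(q, "StateDensity"))
    C <- colocMeasure(D, t)
    C0 <- baselineColoc(q, t)
    eh <- epsilonHatStep(C, C0)
    structure(list(t = t, N = length(D), C = C, C0 = C0,
                   epsilon = eh$epsilon, status = eh$status,
                   cellId = D@cellId),
              class = "colocResult")
}

#' @export
print.colocResult <- function(x, ...) {
    cat(sprintf("Co-localization ('%s'): t = %g px, N = %d\n",
                x$cellId, x$t, x$N))
    cat(sprintf("  C = %.4f, C0 = %.4f, epsilon_hat = %s (%s)\n",
                x$C, x$C0,
                if (is.na(x$epsilon)) "NA" else sprintf("%.4f", x$epsilon),
                x$status))
    invisible(x)
}

#' Critical co-localization for the exact binomial test
#'
#' Under the null, \eqn{N C^t} is binomial(N, C0). Returns the smallest
#' integer count k with \eqn{P(\mathrm{Bin}(N, C_0) \ge k) \le \alpha},
#' the corresponding critical \eqn{C^t = k/N}, and the critical strength
#' estimate. When even k = N fails the bound, the null cannot be rejected
#' at this sample size and a status says so.
#'
#' @param C0 baseline co-localization in (0, 1).
#' @param N sample size.
#' @param alpha significance level in (0, 1).
#' @return list with \code{k}, \code{criticalC}, \code{criticalEpsilon}
#'   (list as in [epsilonHatStep()]) and \code{status} ("ok" or
#'   "H0 cannot be rejected at this N").
#' @examples
#' criticalColoc(0.5, 10, 0.05)$k  # 9
#' @export
criticalColoc <- function(C0, N, alpha) {
    stopifnot(.is_count(N), C0 > 0, C0 < 1, alpha > 0, alpha < 1)
    # smallest k with upper tail <= alpha
    k <- stats::qbinom(alpha, N, C0, lower.tail = FALSE) + 1
    if (k > N || stats::pbinom(k - 1, N, C0, lower.tail = FALSE) > alpha)
        return(list(k = NA_integer_, criticalC = NA_real_,
                    criticalEpsilon = list(epsilon = NA_real_,
                                           status = "undefined"),
                    status = "H0 cannot be rejected at this N"))
    Ccrit <- k / N
    list(k = as.integer(k), criticalC = Ccrit,
         criticalEpsilon = epsilonHatStep(Ccrit, C0), status = "ok")
}

#' Exact power of the binomial co-localization test
#'
#' Under the alternative of a step potential with true strength a, the
#' per-object co-localization probability is
#' \eqn{p_1 = C_0 e^a / (C_0 e^a + 1 - C_0)}; the power is the exact
#' binomial upper tail at the critical count.
#'
#' @param C0 baseline co-localization in (0, 1).
#' @param N sample size.
#' @param alpha significance level.
#' @param a true interaction strength (effect size).
#' @return an object of class \code{powerResult}: list with alpha, N,
#'   effectSize, power, criticalCount, criticalC, status.
#' @export
stepPower <- function(C0, N, alpha, a) {
    stopifnot(is.finite(a))
    cc <- criticalColoc(C0, N, alpha)
    if (cc$status != "ok")
        return(structure(list(alpha = alpha, N = N, effectSize = a,
                              power = 0, criticalCount = NA_integer_,
                              criticalC = NA_real_, status = cc$status),
                         class = "powerResult"))
    p1 <- C0 * exp(a) / (C0 * exp(a) + 1 - C0)
    structure(list(alpha = alpha, N = N, effectSize = a,
                   power = stats::pbinom(cc$k - 1, N, p1, lower.tail = FALSE),
                   criticalCount = cc$k, criticalC = cc$criticalC,
                   status = "ok"),
              class = "powerResult")
}

#' @export
print.powerResult <- function(x, ...) {
    cat(sprintf("Power analysis: N = %d, alpha = %g, effect size a = %g\n",
                x$N, x$alpha, x$effectSize))
    if (!is.null(x$mcse))
        cat(sprintf("  power = %.4f (MC se %.4f)\n", x$power, x$mcse))
    else
        cat(sprintf("  power = %.4f (critical count %s)\n", x$power,
                    ifelse(is.na(x$criticalCount), "none",
                           as.character(x$criticalCount))))
    if (!identical(x$status, "ok")) cat("  status:", x$status, "\n")
    invisible(x)
}
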