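## The exponential-decay basis: m x n_tau matrix of (optionally
## Gaussian-IRF-convolved) causal exponential decays over a lifetime grid.

#' Build a lifetime grid
#'
#' Lifetimes distributed evenly along the experiment's time scale: by
#' default a geometric progression (even spacing in \eqn{\log_{10}\tau},
#' matching the lin-log axes of lifetime density maps); linear spacing is
#' available.
#'
#' @param tauMin,tauMax grid endpoints, \code{0 < tauMin < tauMax}.
#' @param n number of lifetimes (default 100).
#' @param spacing \code{"log"} (default) or \code{"linear"}.
#' @return A [LifetimeGrid-class] object.
#' @examples
#' lifetimes(makeLifetimeGrid(1, 100, 3))  # 1, 10, 100
#' @export
makeLifetimeGrid <- function(tauMin, tauMax, n = 100L,
                             spacing = c("log", "linear")) {
    spacing <- match.arg(spacing)
    if (tauMin <= 0) stop("tauMin must be > 0")
    if (tauMax <= tauMin) stop("tauMax must exceed tauMin")
    if (n < 2L) stop("n must be at least 2")
    taus <- if (spacing == "log")
        exp(seq(log(tauMin), log(tauMax), length.out = n))
    else seq(tauMin, tauMax, length.out = n)
    new("LifetimeGrid", taus = taus, spacing = spacing)
}

#' One column of the decay basis
#'
#' Without an IRF the column is the causal exponential \eqn{e^{-t/\tau}}
#' (zero before time zero). With a normalized Gaussian IRF of standard
#' deviation \eqn{\sigma = \mathrm{fwhm} / (2\sqrt{2\ln 2})} centered at
#' \code{t0}, the analytic convolution is
#' \deqn{\frac12 \exp\!\Big(\frac{\sigma^2}{2\tau^2} -
#'   \frac{t - t_0}{\tau}\Big)\,
#'   \mathrm{erfc}\!\Big(\frac{\sigma}{\tau\sqrt2} -
#'   \frac{t - t_0}{\sigma\sqrt2}\Big),}
#' evaluated through the scaled complementary error function so the large
#' positive exponent regime (small \eqn{\tau} relative to \eqn{\sigma})
#' cannot overflow: for argument \eqn{z \ge 0} the product equals
#' \eqn{\frac12\,\mathrm{erfcx}(z)\exp(-(t-t_0)^2/(2\sigma^2))}.
#'
#' @param tau lifetime, > 0.
#' @param times time axis.
#' @param irf an [IRFSpec-class] (scalar \code{t0}).
#' @return Numeric vector over \code{times}.
#' @examples
#' decayColumn(100, c(0, 100), irfNone())  # 1, exp(-1)
#' @export
decayColumn <- function(tau, times, irf = irfNone()) {
    if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
        stop("tau must be a single positive number")
    stopifnot(is(irf, "IRFSpec"))
    times <- as.numeric(times)
    if (irf@kind == "none") {
        out <- exp(-pmax(times, 0) / tau)
        out[times < 0] <- 0
        return(out)
    }
    t0 <- irf@t0[1L]
    sigma <- irf@fwhm / (2 * sqrt(2 * log(2)))
    u <- times - t0
    z <- sigma / (tau * sqrt(2)) - u / (sigma * sqrt(2))
    out <- numeric(length(times))
    pos <- z >= 0
    ## z >= 0: erfc(z) = erfcx(z) exp(-z^2); the combined exponent collapses
    ## to -(t-t0)^2/(2 sigma^2) <= 0, so no overflow for any tau/sigma.
    if (any(pos))
        out[pos] <- 0.5 * .erfcx(z[pos]) *
            exp(-u[pos]^2 / (2 * sigma^2))
    if (any(!pos)) {
        ## z < 0 implies the plain exponent is negative; direct evaluation.
        a <- sigma^2 / (2 * tau^2) - u[!pos] / tau
        out[!pos] <- 0.5 * exp(a) * pracma::erfc(z[!pos])
    }
    out
}

## Scaled complementary error function, stable for any non-negative
## argument: delegates to pracma up to z = 20, then switches to the
## asymptotic series 1/(z sqrt(pi)) * sum (-1)^n (2n-1)!!/(2 z^2)^n,
## whose truncation error at z = 20 is below 1e-12 relative.
.erfcx <- function(z) {
    out <- numeric(length(z))
    lo <- z <= 20
    if (any(lo)) out[lo] <- pracma::erfcx(z[lo])
    if (any(!lo)) {
        zz <- z[!lo]
        iz2 <- 1 / (2 * zz^2)
        s <- 1 - iz2 + 3 * iz2^2 - 15 * iz2^3 + 105 * iz2^4 - 945 * iz2^5
        out[!lo] <- s / (zz * sqrt(pi))
    }
    out
}

#' Build the decay design matrix
#'
#' Assembles the \code{m x n_tau} matrix \code{D} whose columns are
#' [decayColumn()] evaluated at each grid lifetime. The condition number
#' grows quickly with the number of lifetimes; this is expected (the
#' downstream inversion is regularized) and not an error.
#'
#' @param grid a [LifetimeGrid-class].
#' @param times time axis.
#' @param irf an [IRFSpec-class]; a vector \code{t0} is reduced to its
#'   first element here (per-channel offsets are applied by
#'   [computeLDM()]).
#' @return A [KineticBasis-class] object.
#' @export
buildDesignMatrix <- function(grid, times, irf = irfNone()) {
    stopifnot(is(grid, "LifetimeGrid"), is(irf, "IRFSpec"))
    times <- as.numeric(times)
    vals <- vapply(grid@taus, decayColumn, numeric(length(times)),
                   times = times, irf = irf)
    vals <- matrix(vals, nrow = length(times))
    new("KineticBasis", values = vals, grid = grid, irf = irf, times = times)
}

## Internal: accept either a KineticBasis or a bare matrix for solvers.
.basisValues <- function(d) {
    if (is(d, "KineticBasis")) d@values
    else if (is.matrix(d)) d
    else stop("expected a KineticBasis or a numeric matrix")
}
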