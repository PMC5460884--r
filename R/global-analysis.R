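## SVD inspection and variable-projection global fitting. A small number of
## shared lifetimes is fit to weighted left singular vectors (wLSVs): the
## outer Levenberg-Marquardt search runs over log-lifetimes only; at each
## iterate the amplitude matrix solves the linear subproblem exactly via QR.

#' Full singular value decomposition of a dataset
#'
#' \eqn{A = U S V^T}: the left singular vectors carry the temporal
#' dependence of the signal, the right singular vectors the spectral
#' dependence. The number of singular values significantly larger than the
#' rest estimates the number of orthogonal components (and hence lifetimes
#' resolvable by a global fit).
#'
#' @param ds a [TRSpectra-class] object.
#' @return A [TRSVD-class] object with full \code{u} and \code{v}.
#' @seealso [countSignificant()], [selectWLSV()]
#' @export
computeSVD <- function(ds) {
    stopifnot(is(ds, "TRSpectra"))
    if (any(!is.finite(ds@values))) stop("non-finite values in dataset")
    sv <- svd(ds@values, nu = nrow(ds@values), nv = ncol(ds@values))
    new("TRSVD", u = sv$u, d = sv$d, v = sv$v)
}

#' Count significant singular values
#'
#' Quantitative stand-in for visual inspection of the singular-value
#' spectrum: the default rule returns the largest \code{k} such that
#' \code{s[k] > factor * median(s[(k+1):end])} (factor 5). A different rule
#' can be plugged in as a function of the singular values; the rule used is
#' reported in the \code{"rule"} attribute.
#'
#' @param s non-increasing positive singular values (or a [TRSVD-class]).
#' @param factor threshold factor of the default median-ratio rule.
#' @param rule optional function \code{s -> count} replacing the default.
#' @return Integer count, with attribute \code{"rule"}. A degenerate
#'   spectrum with no separation (e.g. all values equal) returns 0 with a
#'   warning.
#' @examples
#' countSignificant(c(10, 10, 1e-12, 1e-12, 1e-12))  # 2
#' @export
countSignificant <- function(s, factor = 5, rule = NULL) {
    if (is(s, "TRSVD")) s <- s@d
    if (!length(s)) stop("empty singular value vector")
    if (!is.null(rule)) {
        k <- as.integer(rule(s))
        attr(k, "rule") <- "user"
        return(k)
    }
    n <- length(s)
    ok <- vapply(seq_len(n - 1L), function(k)
        s[k] > factor * stats::median(s[(k + 1L):n]), logical(1L))
    k <- if (any(ok)) max(which(ok)) else 0L
    if (k == 0L)
        warning("no singular value stands out from the rest; returning 0")
    k <- as.integer(k)
    attr(k, "rule") <- sprintf("median-ratio (factor %g)", factor)
    k
}

#' Extract weighted left singular vectors
#'
#' Columns of \code{U} scaled by their singular values, in the requested
#' order. Non-contiguous selections are supported: when a later left
#' singular vector has more regular structure than an earlier one (noise
#' can outrank small signal components), it can be used in its stead, e.g.
#' indices \code{c(1, 2, 3, 5)}.
#'
#' @param svdres a [TRSVD-class] object.
#' @param indices distinct 1-based column indices.
#' @return Matrix with one column per index, \code{u[, i] * d[i]}.
#' @export
selectWLSV <- function(svdres, indices) {
    stopifnot(is(svdres, "TRSVD"))
    indices <- as.integer(indices)
    if (anyDuplicated(indices)) stop("indices must be distinct")
    if (any(indices < 1L) || any(indices > length(svdres@d)))
        stop("index out of range [1, ", length(svdres@d), "]")
    svdres@u[, indices, drop = FALSE] %*%
        diag(svdres@d[indices], nrow = length(indices))
}

## Exact inner solve of D x = Y; least-norm via SVD if D is rank deficient.
.innerSolve <- function(D, Y) {
    qrD <- qr(D)
    if (qrD$rank == ncol(D)) {
        x <- qr.coef(qrD, Y)
    } else {
        warning("rank-deficient design in inner solve; ",
                "returning least-norm solution")
        sv <- svd(D)
        pos <- sv$d > max(sv$d) * 1e-12
        x <- sv$v[, pos, drop = FALSE] %*%
            ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    }
    matrix(x, ncol = ncol(Y))
}

#' Variable-projection multi-exponential fit
#'
#' Fits \code{length(tauInit)} shared exponential lifetimes to the columns
#' of \code{wlsvs} (typically weighted left singular vectors, but any
#' temporal traces on the same time axis work). Only the lifetimes enter
#' the outer Levenberg-Marquardt optimization, parameterized as
#' \eqn{\log\tau} to keep them positive without hard bound clipping; the
#' amplitude matrix is recomputed exactly at every iterate from the QR
#' factorization of the decay matrix. Divergent or bound-pinned fits are
#' flagged, never silently accepted.
#'
#' @param wlsvs matrix of temporal traces (one column per trace).
#' @param times time axis matching \code{nrow(wlsvs)}.
#' @param tauInit positive initial lifetimes; the number of lifetimes need
#'   not equal the number of traces.
#' @param irf optional [IRFSpec-class] used in the decay columns.
#' @param lower,upper optional per-lifetime bounds.
#' @param v optional matrix of retained right singular vectors (one column
#'   per trace) used to reconstruct decay-associated difference spectra.
#' @param control list: \code{ftol} relative objective-change tolerance
#'   (default 1e-10) and \code{maxIter} outer-iteration cap (default 500).
#' @return A [GlobalFit-class] object; lifetimes sorted ascending with
#'   amplitude rows permuted to match.
#' @examples
#' tt <- seq(0, 500, 2)
#' fit <- fitGlobal(cbind(exp(-tt / 100)), tt, tauInit = 50)
#' lifetimes(fit)  # ~100
#' @export
fitGlobal <- function(wlsvs, times, tauInit, irf = irfNone(),
                      lower = NULL, upper = NULL, v = NULL,
                      control = list()) {
    wlsvs <- as.matrix(wlsvs)
    times <- as.numeric(times)
    stopifnot(nrow(wlsvs) == length(times))
    if (any(tauInit <= 0)) stop("initial lifetimes must be positive")
    if (!is.null(lower) && any(tauInit < lower) ||
        !is.null(upper) && any(tauInit > upper))
        stop("tauInit must lie within the bounds")
    ftol <- if (is.null(control$ftol)) 1e-10 else control$ftol
    maxIter <- if (is.null(control$maxIter)) 500L else control$maxIter

    dmat <- function(taus)
        matrix(vapply(taus, decayColumn, numeric(length(times)),
                      times = times, irf = irf), nrow = length(times))
    residFun <- function(logTau) {
        D <- dmat(exp(logTau))
        x <- .innerSolve(D, wlsvs)
        as.vector(D %*% x - wlsvs)
    }
    fit <- minpack.lm::nls.lm(
        par = log(tauInit), fn = residFun,
        lower = if (is.null(lower)) NULL else log(lower),
        upper = if (is.null(upper)) NULL else log(upper),
        control = minpack.lm::nls.lm.control(
            ftol = ftol, maxiter = min(as.integer(maxIter), 1024L)))
    taus <- exp(fit$par)
    D <- dmat(taus)
    x <- .innerSolve(D, wlsvs)
    rnorm2 <- sum((D %*% x - wlsvs)^2)
    converged <- fit$info %in% 1:4
    pinned <- FALSE
    if (!is.null(lower))
        pinned <- pinned || any(abs(fit$par - log(lower)) < 1e-8)
    if (!is.null(upper))
        pinned <- pinned || any(abs(fit$par - log(upper)) < 1e-8)
    msg <- fit$message
    if (pinned) {
        converged <- FALSE
        msg <- paste(msg, "(lifetime pinned at a bound)")
    }
    ord <- order(taus)
    das <- if (is.null(v)) matrix(numeric(), length(taus), 0L)
           else x[ord, , drop = FALSE] %*% t(as.matrix(v))
    new("GlobalFit", taus = taus[ord],
        amplitudes = x[ord, , drop = FALSE],
        residualNorm = rnorm2, converged = converged,
        nIterations = as.integer(fit$niter), das = das,
        message = msg)
}
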