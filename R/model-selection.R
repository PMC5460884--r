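## Hyperparameter-selection statistics along a regularization path:
## generalized cross-validation, Mallows' Cp and the L-curve corner, per
## wavelength channel or globally.

#' Effective degrees of freedom of the Tikhonov smoother
#'
#' Trace of the hat matrix
#' \eqn{H = D (D^T D + \alpha L^T L)^{-1} D^T}, computed through a
#' factorization rather than an explicit inverse: when \code{l} is the
#' identity, \eqn{tr(H) = \sum_i s_i^2 / (s_i^2 + \alpha)} from the
#' singular values of \code{D}; otherwise via a Cholesky factorization of
#' the regularized normal matrix.
#'
#' @param d a [KineticBasis-class] or numeric design matrix.
#' @param alpha penalty weight \eqn{\ge 0}.
#' @param l penalty matrix (default identity).
#' @return \eqn{tr(H)} (scalar).
#' @examples
#' hatTrace(diag(4), 1)  # 4 * 1/2 = 2
#' @export
hatTrace <- function(d, alpha, l = NULL) {
    D <- .basisValues(d)
    if (alpha < 0) stop("alpha must be >= 0")
    if (is.null(l)) {
        s2 <- svd(D, nu = 0, nv = 0)$d^2
        if (alpha == 0 && any(s2 <= max(s2) * 1e-24))
            stop("design matrix is rank deficient at alpha = 0; ",
                 "use alpha > 0")
        return(sum(s2 / (s2 + alpha)))
    }
    M <- crossprod(D) + alpha * crossprod(l)
    R <- tryCatch(chol(M), error = function(e)
        stop("regularized normal matrix is singular; use alpha > 0 or a ",
             "penalty with full column rank"))
    W <- t(backsolve(R, t(D), transpose = TRUE))  # D R^{-1}
    sum(W^2)
}

#' Generalized cross-validation statistic
#'
#' \eqn{GCV(\alpha) = \|D\hat x_\alpha - A\|_2^2 / tr(I - H)^2} for the
#' Tikhonov solution at \eqn{\alpha}; the preferred \eqn{\alpha} is the
#' grid minimizer. When \code{a} has several columns the squared residuals
#' are summed over channels. A degenerate denominator
#' (\eqn{tr(I-H) \approx 0}) yields \code{NaN}, which [selectAlpha()]
#' excludes from the argmin.
#'
#' @param d a [KineticBasis-class] or numeric design matrix.
#' @param a data column or matrix of columns.
#' @param alpha penalty weight.
#' @param l penalty matrix (default identity).
#' @return GCV value (scalar).
#' @export
gcvStatistic <- function(d, a, alpha, l = NULL) {
    D <- .basisValues(d)
    x <- solveTikhonov(D, a, alpha, l = l)
    r2 <- sum((D %*% as.matrix(x) - as.matrix(a))^2)
    den <- nrow(D) - hatTrace(D, alpha, l = l)
    if (abs(den) < 1e-10) return(NaN)
    r2 / den^2
}

#' Mallows' Cp statistic
#'
#' \eqn{C_p(\alpha) = \|D\hat x_\alpha - A\|_2^2 + 2\sigma^2\,df} with
#' \eqn{df = tr(H)}. When \code{sigma2} is missing it is estimated from the
#' most complicated model on the supplied grid, i.e. the one with the
#' lowest \eqn{\alpha}: residual sum of squares there divided by
#' \eqn{(m - df)}.
#'
#' @param d a [KineticBasis-class] or numeric design matrix.
#' @param a data column or matrix of columns.
#' @param alpha penalty weight.
#' @param l penalty matrix (default identity).
#' @param sigma2 error variance; required unless \code{alphaMin} is given.
#' @param alphaMin lowest alpha of the evaluation grid, used to estimate
#'   \code{sigma2} when it is not supplied.
#' @return Cp value (scalar).
#' @export
cpStatistic <- function(d, a, alpha, l = NULL, sigma2 = NULL,
                        alphaMin = NULL) {
    D <- .basisValues(d)
    if (is.null(sigma2)) {
        if (is.null(alphaMin))
            stop("supply sigma2 or alphaMin to estimate it from")
        dfMin <- hatTrace(D, alphaMin, l = l)
        if (nrow(D) <= dfMin)
            stop("cannot estimate sigma2: m <= df at the lowest alpha")
        xMin <- solveTikhonov(D, a, alphaMin, l = l)
        rssMin <- sum((D %*% as.matrix(xMin) - as.matrix(a))^2)
        nch <- ncol(as.matrix(a))
        sigma2 <- rssMin / (nch * (nrow(D) - dfMin))
    }
    if (sigma2 < 0) stop("sigma2 must be >= 0")
    x <- solveTikhonov(D, a, alpha, l = l)
    r2 <- sum((D %*% as.matrix(x) - as.matrix(a))^2)
    r2 + 2 * sigma2 * hatTrace(D, alpha, l = l)
}

## numpy.gradient-style first derivative: central differences inside,
## one-sided stencils at the ends; supports non-uniform spacing.
.fdGradient <- function(y, x) {
    n <- length(y)
    if (n < 2L) return(rep(NA_real_, n))
    g <- numeric(n)
    g[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    g[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    if (n > 2L) {
        i <- 2L:(n - 1L)
        h1 <- x[i] - x[i - 1L]; h2 <- x[i + 1L] - x[i]
        g[i] <- (h1^2 * y[i + 1L] - h2^2 * y[i - 1L] +
                 (h2^2 - h1^2) * y[i]) / (h1 * h2 * (h1 + h2))
    }
    g
}

#' L-curve curvature along a regularization path
#'
#' The L-curve plots the smoothing norm \eqn{S(\alpha) = \|L\hat x\|}
#' against the squared residual norm \eqn{R(\alpha)}; its corner (maximum
#' curvature) marks the preferred \eqn{\alpha}. Curvature of the
#' parameterized curve,
#' \deqn{\kappa(\alpha) = \frac{R' S'' - R'' S'}
#'   {\big(R'^2 + S'^2\big)^{3/2}},}
#' is evaluated with finite differences in \eqn{\log\alpha} (central
#' stencils inside, one-sided at the ends), by default on the
#' \eqn{(\log R, \log S)} curve as is conventional for corner detection;
#' \code{logCoords = FALSE} uses the raw coordinates.
#'
#' @param alphas increasing positive grid (at least 5 points).
#' @param R squared residual norms along the path.
#' @param S smoothing norms along the path.
#' @param logCoords compute curvature of \eqn{(\log R, \log S)} (default)
#'   or of \eqn{(R, S)}.
#' @return Numeric curvature vector over the grid.
#' @export
lcurveCurvature <- function(alphas, R, S, logCoords = TRUE) {
    n <- length(alphas)
    if (n < 5L) stop("at least 5 grid points are required")
    stopifnot(length(R) == n, length(S) == n)
    u <- log(alphas)
    x <- if (logCoords) log(R) else R
    y <- if (logCoords) log(S) else S
    dx <- .fdGradient(x, u); dy <- .fdGradient(y, u)
    d2x <- .fdGradient(dx, u); d2y <- .fdGradient(dy, u)
    (dx * d2y - d2x * dy) / (dx^2 + dy^2)^1.5
}

#' Select alpha at the L-curve corner
#'
#' @param alphas,R,S,logCoords see [lcurveCurvature()].
#' @param cornerTol curvature magnitude below which the path is flagged as
#'   having no well-defined corner (e.g. \code{R} and \code{S} affine in
#'   \eqn{\alpha}: a straight line has zero curvature).
#' @return List with \code{alpha} (argmax of \eqn{|\kappa|}, \code{NA}
#'   when no corner), \code{curvature}, \code{noCorner}, and the plotted
#'   coordinates \code{x}, \code{y}.
#' @export
lcurveSelect <- function(alphas, R, S, logCoords = TRUE, cornerTol = 1e-8) {
    kap <- lcurveCurvature(alphas, R, S, logCoords = logCoords)
    noCorner <- all(!is.finite(kap)) || max(abs(kap), na.rm = TRUE) < cornerTol
    if (noCorner)
        warning("no well-defined L-curve corner (curvature ~ 0 everywhere)")
    best <- if (noCorner) NA_real_ else alphas[which.max(abs(kap))]
    list(alpha = best, curvature = kap, noCorner = noCorner,
         x = if (logCoords) log(R) else R,
         y = if (logCoords) log(S) else S)
}

#' Hyperparameter selection along a regularization path
#'
#' Solves the regularized inversion for every alpha on the grid and every
#' wavelength channel, tabulates \eqn{R(\alpha)} (squared residual norm),
#' \eqn{S(\alpha)} (smoothing norm: 2-norm of \eqn{L\hat x} for Tikhonov,
#' 1-norm for LASSO), effective degrees of freedom, GCV, Cp and L-curve
#' curvature, and selects alpha under the requested mode. Global scope sums
#' residual and smoothing norms over channels before applying the
#' statistic; per-channel scope applies it to each column independently.
#'
#' For LASSO paths, Cp uses the number of nonzero coefficients as the
#' degrees of freedom (a documented approximation) and GCV is not offered
#' (the penalty is not differentiable).
#'
#' @param ds a [TRSpectra-class] object.
#' @param dm a [KineticBasis-class] on the same time axis.
#' @param alphas increasing positive grid (default 30 points, log-spaced
#'   \eqn{10^{-5}}-\eqn{10^{2}}).
#' @param mode \code{"gcv"}, \code{"cp"} or \code{"lcurve"}.
#' @param scope \code{"global"} or \code{"per_channel"}.
#' @param method \code{"tikhonov"} (default) or \code{"lasso"}.
#' @param penalty penalty tag passed to [makePenaltyMatrix()].
#' @return An [AlphaPath-class] object; \code{selectedAlpha()} gives the
#'   chosen alpha (scalar in global scope, one per channel otherwise).
#' @export
selectAlpha <- function(ds, dm,
                        alphas = 10^seq(-5, 2, length.out = 30L),
                        mode = c("gcv", "cp", "lcurve"),
                        scope = c("global", "per_channel"),
                        method = c("tikhonov", "lasso"),
                        penalty = "identity") {
    stopifnot(is(ds, "TRSpectra"), is(dm, "KineticBasis"))
    mode <- match.arg(mode)
    scope <- match.arg(scope)
    method <- match.arg(method)
    if (any(alphas <= 0) || is.unsorted(alphas, strictly = TRUE))
        stop("alphas must be positive and strictly increasing")
    if (method == "lasso" && mode == "gcv")
        stop("GCV is not available for LASSO paths; use 'cp' or 'lcurve'")
    D <- dm@values
    A <- ds@values
    L <- makePenaltyMatrix(penalty, ncol(D))
    m <- nrow(D); nch <- ncol(A); na <- length(alphas)

    Rmat <- Smat <- matrix(NA_real_, na, nch)
    dfv <- numeric(na)
    if (method == "tikhonov") {
        for (i in seq_len(na)) {
            X <- solveTikhonov(D, A, alphas[i], l = L)
            Rmat[i, ] <- colSums((D %*% X - A)^2)
            Smat[i, ] <- sqrt(colSums((L %*% X)^2))
            dfv[i] <- hatTrace(D, alphas[i],
                               l = if (penalty == "identity") NULL else L)
        }
    } else {
        dfMat <- matrix(NA_real_, na, nch)
        for (i in seq_len(na)) for (ch in seq_len(nch)) {
            x <- solveLasso(D, A[, ch], alphas[i])
            Rmat[i, ch] <- sum((D %*% x - A[, ch])^2)
            Smat[i, ch] <- sum(abs(x))
            dfMat[i, ch] <- sum(x != 0)
        }
        dfv <- rowMeans(dfMat)
    }

    ## per-channel statistics
    denom <- (m - dfv)^2
    denom[abs(m - dfv) < 1e-10] <- NA_real_
    gcvC <- if (method == "tikhonov") Rmat / denom
            else matrix(NaN, na, nch)
    sig2C <- Rmat[1L, ] / pmax(m - dfv[1L], .Machine$double.eps)
    cpC <- Rmat + 2 * outer(dfv, sig2C)
    kapC <- apply(rbind(Rmat, Smat), 2L, function(col) {
        lcurveCurvature(alphas, col[seq_len(na)], col[na + seq_len(na)])
    })
    kapC <- matrix(kapC, na, nch)

    if (scope == "global") {
        Rg <- rowSums(Rmat); Sg <- rowSums(Smat)
        sig2 <- sum(Rmat[1L, ]) / (nch * (m - dfv[1L]))
        gcvM <- matrix(if (method == "tikhonov") Rg / denom
                       else NaN, na, 1L)
        cpM <- matrix(Rg + 2 * sig2 * nch * dfv, na, 1L)
        kapM <- matrix(lcurveCurvature(alphas, Rg, Sg), na, 1L)
        Rout <- matrix(Rg, na, 1L); Sout <- matrix(Sg, na, 1L)
        sig2out <- sig2
    } else {
        gcvM <- gcvC; cpM <- cpC; kapM <- kapC
        Rout <- Rmat; Sout <- Smat; sig2out <- sig2C
    }

    pickMin <- function(v) {
        ok <- is.finite(v)
        if (!any(ok)) return(NA_real_)
        alphas[which(ok)[which.min(v[ok])]]
    }
    sel <- switch(mode,
        gcv = apply(gcvM, 2L, pickMin),
        cp = apply(cpM, 2L, pickMin),
        lcurve = apply(rbind(Rout, Sout), 2L, function(col)
            lcurveSelect(alphas, col[seq_len(na)],
                         col[na + seq_len(na)])$alpha))

    new("AlphaPath", alphas = alphas, residualNorms = Rout,
        smoothingNorms = Sout, df = dfv, gcv = gcvM, cp = cpM,
        curvature = kapM, sigma2 = as.numeric(sig2out), scope = scope,
        mode = mode, method = method, selected = as.numeric(sel))
}
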