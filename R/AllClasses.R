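#' @import methods
NULL

## Central S4 containers. All matrices are base "matrix"; axes are plain
## numeric vectors carried alongside rather than dimnames, because both axes
## are physical coordinates (time delays, wavelengths) used in arithmetic.

#' Time-resolved difference-absorption data
#'
#' An \code{m x n} matrix of difference-absorbance values (\eqn{\Delta A},
#' dimensionless \eqn{\Delta}OD) recorded at \code{m} time delays across
#' \code{n} wavelength channels, together with both axes and a free-form
#' provenance list.
#'
#' @slot times numeric vector of \code{m} time delays, strictly increasing.
#'   Negative (pre-time-zero) delays are allowed and retained.
#' @slot wavelengths numeric vector of \code{n} channel coordinates (nm),
#'   strictly monotonic (increasing or decreasing).
#' @slot values \code{m x n} numeric matrix of \eqn{\Delta A}; all entries
#'   finite.
#' @slot meta list of provenance fields (source path, noise seed,
#'   truncation rank, ...).
#'
#' @seealso [TRSpectra()], [readDataset()], [simulateDataset()]
#' @export
setClass("TRSpectra",
    representation(times = "numeric", wavelengths = "numeric",
                   values = "matrix", meta = "list"),
    prototype(times = numeric(), wavelengths = numeric(),
              values = matrix(numeric(), 0L, 0L), meta = list()))

setValidity("TRSpectra", function(object) {
    msg <- character()
    m <- length(object@times); n <- length(object@wavelengths)
    if (nrow(object@values) != m)
        msg <- c(msg, sprintf("nrow(values) [%d] != length(times) [%d]",
                              nrow(object@values), m))
    if (ncol(object@values) != n)
        msg <- c(msg, sprintf("ncol(values) [%d] != length(wavelengths) [%d]",
                              ncol(object@values), n))
    if (m > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (n > 1L) {
        dw <- diff(object@wavelengths)
        if (!(all(dw > 0) || all(dw < 0)))
            msg <- c(msg, "wavelengths must be strictly monotonic")
    }
    if (anyNA(object@values) || any(!is.finite(object@values)))
        msg <- c(msg, "values contains non-finite entries")
    if (length(msg)) msg else TRUE
})

#' Construct a TRSpectra object
#'
#' @param times numeric vector of time delays (strictly increasing).
#' @param wavelengths numeric vector of channel coordinates (strictly
#'   monotonic).
#' @param values numeric matrix, \code{length(times)} rows by
#'   \code{length(wavelengths)} columns.
#' @param meta list of provenance fields.
#' @return A validated [TRSpectra-class] object.
#' @examples
#' ds <- TRSpectra(times = 0:3, wavelengths = c(500, 510),
#'                 values = matrix(rnorm(8), 4, 2))
#' dim(signalMatrix(ds))
#' @export
TRSpectra <- function(times, wavelengths, values, meta = list()) {
    new("TRSpectra", times = as.numeric(times),
        wavelengths = as.numeric(wavelengths),
        values = as.matrix(values), meta = meta)
}

#' Synthetic species specification
#'
#' Describes one emitting/absorbing species of a synthetic kinetic scheme: a
#' Gaussian spectral band whose population decays as an equal-weight mixture
#' of one or more exponential lifetimes, optionally red/blue-shifting its
#' band center over time (dynamic motion).
#'
#' @slot center band center (nm) at time zero.
#' @slot width Gaussian standard deviation of the band (nm), > 0.
#' @slot amplitude peak \eqn{\Delta A} (dimensionless).
#' @slot lifetimes decay lifetimes (time units), all > 0; the population is
#'   the equal-weight mixture \eqn{(1/J)\sum_j \exp(-t/\tau_j)}.
#' @slot shiftTarget final band center (nm) for dynamic motion, or
#'   \code{NA_real_} for a static band.
#' @slot shiftTau time constant of the center shift; required (> 0) when
#'   \code{shiftTarget} is set.
#' @export
setClass("SpeciesSpec",
    representation(center = "numeric", width = "numeric",
                   amplitude = "numeric", lifetimes = "numeric",
                   shiftTarget = "numeric", shiftTau = "numeric"),
    prototype(shiftTarget = NA_real_, shiftTau = NA_real_))

setValidity("SpeciesSpec", function(object) {
    msg <- character()
    if (length(object@width) != 1L || object@width <= 0)
        msg <- c(msg, "width must be a single positive number")
    if (!length(object@lifetimes) || any(object@lifetimes <= 0))
        msg <- c(msg, "lifetimes must all be > 0")
    if (!is.na(object@shiftTarget) &&
        (is.na(object@shiftTau) || object@shiftTau <= 0))
        msg <- c(msg, "shiftTau must be set and > 0 when shiftTarget is set")
    if (length(msg)) msg else TRUE
})

#' @rdname SpeciesSpec-class
#' @param center,width,amplitude,lifetimes,shiftTarget,shiftTau see slots.
#' @return A validated [SpeciesSpec-class] object.
#' @examples
#' sp <- SpeciesSpec(center = 500, width = 20, amplitude = 1,
#'                   lifetimes = c(1, 10, 100))
#' speciesConcentration(sp, 10)
#' @export
SpeciesSpec <- function(center, width, amplitude, lifetimes,
                        shiftTarget = NA_real_, shiftTau = NA_real_) {
    new("SpeciesSpec", center = as.numeric(center), width = as.numeric(width),
        amplitude = as.numeric(amplitude), lifetimes = as.numeric(lifetimes),
        shiftTarget = as.numeric(shiftTarget), shiftTau = as.numeric(shiftTau))
}

#' Instrument response function model
#'
#' Either no IRF (ideal causal exponentials) or a normalized Gaussian IRF of
#' a given full width at half maximum centered at a time-zero offset
#' \code{t0}. \code{t0} may be a per-wavelength vector, in which case the
#' design matrix is rebuilt per channel when assembling a lifetime density
#' map.
#'
#' @slot kind \code{"none"} or \code{"gaussian"}.
#' @slot fwhm full width at half maximum (time units); > 0 when gaussian.
#' @slot t0 time-zero offset (scalar, or one value per wavelength channel).
#' @export
setClass("IRFSpec",
    representation(kind = "character", fwhm = "numeric", t0 = "numeric"),
    prototype(kind = "none", fwhm = NA_real_, t0 = 0))

setValidity("IRFSpec", function(object) {
    msg <- character()
    if (!object@kind %in% c("none", "gaussian"))
        msg <- c(msg, "kind must be 'none' or 'gaussian'")
    if (object@kind == "gaussian" &&
        (is.na(object@fwhm) || object@fwhm <= 0))
        msg <- c(msg, "fwhm must be > 0 for a gaussian IRF")
    if (length(msg)) msg else TRUE
})

#' @rdname IRFSpec-class
#' @return A validated [IRFSpec-class] object.
#' @export
irfNone <- function() new("IRFSpec", kind = "none")

#' @rdname IRFSpec-class
#' @param fwhm full width at half maximum (time units).
#' @param t0 time-zero offset (scalar or per-channel vector).
#' @export
irfGaussian <- function(fwhm, t0 = 0)
    new("IRFSpec", kind = "gaussian", fwhm = as.numeric(fwhm),
        t0 = as.numeric(t0))

#' Lifetime grid
#'
#' The discrete set of \code{n_tau} lifetimes over which the semi-continuous
#' exponential basis is built. Lifetimes are distributed evenly along the
#' time scale of the experiment, by default evenly in \eqn{\log_{10}\tau}
#' (geometric progression).
#'
#' @slot taus strictly increasing positive lifetimes.
#' @slot spacing \code{"log"} or \code{"linear"}.
#' @seealso [makeLifetimeGrid()]
#' @export
setClass("LifetimeGrid",
    representation(taus = "numeric", spacing = "character"),
    prototype(spacing = "log"))

setValidity("LifetimeGrid", function(object) {
    msg <- character()
    if (any(object@taus <= 0)) msg <- c(msg, "all taus must be > 0")
    if (length(object@taus) > 1L && any(diff(object@taus) <= 0))
        msg <- c(msg, "taus must be strictly increasing")
    if (!object@spacing %in% c("log", "linear"))
        msg <- c(msg, "spacing must be 'log' or 'linear'")
    if (length(msg)) msg else TRUE
})

#' Exponential-decay design matrix
#'
#' The \code{m x n_tau} matrix \code{D} whose column \code{j} is the
#' (optionally IRF-convolved) exponential decay \eqn{\exp(-t/\tau_j)}
#' evaluated on the time axis. The per-channel amplitude vector solves
#' \eqn{A_\lambda = D x_\lambda}.
#'
#' @slot values \code{m x n_tau} numeric matrix.
#' @slot grid the [LifetimeGrid-class] used.
#' @slot irf the [IRFSpec-class] used (with scalar \code{t0}).
#' @slot times the time axis the columns were evaluated on.
#' @seealso [buildDesignMatrix()], [decayColumn()]
#' @export
setClass("KineticBasis",
    representation(values = "matrix", grid = "LifetimeGrid",
                   irf = "IRFSpec", times = "numeric"))

setValidity("KineticBasis", function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@times))
        msg <- c(msg, "nrow(values) != length(times)")
    if (ncol(object@values) != length(object@grid@taus))
        msg <- c(msg, "ncol(values) != number of lifetimes in grid")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "non-finite entries in design matrix")
    if (length(msg)) msg else TRUE
})

#' Singular value decomposition of a dataset
#'
#' Full SVD \eqn{A = U S V^T} of the data matrix: \code{u} holds the
#' temporal left singular vectors, \code{v} the spectral right singular
#' vectors, \code{d} the non-increasing singular values.
#'
#' @slot u \code{m x m} orthonormal matrix (temporal dependence).
#' @slot d singular values, non-increasing.
#' @slot v \code{n x n} orthonormal matrix (spectral dependence).
#' @seealso [computeSVD()], [selectWLSV()]
#' @export
setClass("TRSVD",
    representation(u = "matrix", d = "numeric", v = "matrix"))

setValidity("TRSVD", function(object) {
    msg <- character()
    k <- length(object@d)
    if (is.unsorted(rev(object@d)))
        msg <- c(msg, "singular values must be non-increasing")
    ortho <- function(x) max(abs(crossprod(x) - diag(ncol(x))))
    if (ortho(object@u) > 1e-10) msg <- c(msg, "u not orthonormal (1e-10)")
    if (ortho(object@v) > 1e-10) msg <- c(msg, "v not orthonormal (1e-10)")
    if (length(msg)) msg else TRUE
})

#' Variable-projection global fit result
#'
#' Result of fitting a small number of shared exponential lifetimes to a set
#' of weighted left singular vectors by variable projection: the outer
#' Levenberg-Marquardt search runs over the (log) lifetimes only and the
#' amplitude matrix is solved exactly at each iterate via QR.
#'
#' @slot taus fitted lifetimes, sorted ascending.
#' @slot amplitudes pre-exponential matrix (one row per lifetime, one column
#'   per fitted vector), rows permuted to match the sorted lifetimes.
#' @slot residualNorm final value of the squared-residual objective.
#' @slot converged logical convergence flag (optimizer converged and no
#'   lifetime pinned at a bound).
#' @slot nIterations outer iteration count.
#' @slot das decay-associated difference spectra (one row per lifetime), a
#'   derived view: amplitudes mapped back through the retained right
#'   singular vectors; 0-column matrix when those were not supplied.
#' @slot message optimizer status message.
#' @seealso [fitGlobal()]
#' @export
setClass("GlobalFit",
    representation(taus = "numeric", amplitudes = "matrix",
                   residualNorm = "numeric", converged = "logical",
                   nIterations = "integer", das = "matrix",
                   message = "character"))

setValidity("GlobalFit", function(object) {
    msg <- character()
    if (any(object@taus <= 0)) msg <- c(msg, "fitted taus must be positive")
    if (object@residualNorm < 0) msg <- c(msg, "residualNorm must be >= 0")
    if (nrow(object@amplitudes) != length(object@taus))
        msg <- c(msg, "one amplitude row per fitted lifetime required")
    if (length(msg)) msg else TRUE
})

#' Regularization configuration
#'
#' Bundles the solver choice and its hyperparameters for assembling a
#' lifetime density map.
#'
#' @slot method one of \code{"tsvd"}, \code{"tikhonov"}, \code{"lasso"},
#'   \code{"elastic_net"}.
#' @slot alpha penalty weight \eqn{\alpha \ge 0}.
#' @slot rho elastic-net mixing weight \eqn{\rho \in [0, 1]}.
#' @slot k retained rank (TSVD only).
#' @slot penalty penalty-matrix tag: \code{"identity"}, \code{"d1"},
#'   \code{"d2"} or \code{"fused"}.
#' @seealso [RegConfig()], [computeLDM()]
#' @export
setClass("RegConfig",
    representation(method = "character", alpha = "numeric", rho = "numeric",
                   k = "integer", penalty = "character"),
    prototype(method = "tikhonov", alpha = 0, rho = 0.5, k = NA_integer_,
              penalty = "identity"))

setValidity("RegConfig", function(object) {
    msg <- character()
    if (!object@method %in% c("tsvd", "tikhonov", "lasso", "elastic_net"))
        msg <- c(msg, "unknown method")
    if (any(object@alpha < 0)) msg <- c(msg, "alpha must be >= 0")
    if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
    if (object@method == "tsvd" && (is.na(object@k) || object@k < 1L))
        msg <- c(msg, "k must be a positive integer for tsvd")
    if (!object@penalty %in% c("identity", "d1", "d2", "fused"))
        msg <- c(msg, "unknown penalty tag")
    if (length(msg)) msg else TRUE
})

#' @rdname RegConfig-class
#' @param method,alpha,rho,k,penalty see slots.
#' @return A validated [RegConfig-class] object.
#' @examples
#' RegConfig("tikhonov", alpha = 0.1)
#' @export
RegConfig <- function(method = c("tikhonov", "tsvd", "lasso", "elastic_net"),
                      alpha = 0, rho = 0.5, k = NA_integer_,
                      penalty = c("identity", "d1", "d2", "fused")) {
    new("RegConfig", method = match.arg(method), alpha = as.numeric(alpha),
        rho = as.numeric(rho), k = as.integer(k),
        penalty = match.arg(penalty))
}

#' Regularization-path selection statistics
#'
#' Per-alpha (optionally per-channel) statistics along a regularization
#' path: squared residual norm \code{R}, smoothing norm \code{S}, effective
#' degrees of freedom \code{tr(H)}, GCV, Cp and L-curve curvature, plus the
#' alpha selected under the requested mode.
#'
#' @slot alphas evaluated alpha grid, increasing.
#' @slot residualNorms matrix (alpha x channel) of \eqn{\|Dx - A\|_2^2};
#'   a single column in global scope.
#' @slot smoothingNorms matrix of \eqn{\|Lx\|} (2-norm for Tikhonov,
#'   1-norm for LASSO).
#' @slot df effective degrees of freedom \eqn{tr(H)} per alpha (LASSO:
#'   number of nonzero coefficients, averaged over channels).
#' @slot gcv GCV statistic matrix (NaN where undefined).
#' @slot cp Cp statistic matrix.
#' @slot curvature L-curve curvature per alpha (per channel).
#' @slot sigma2 error-variance estimate(s) used by Cp.
#' @slot scope \code{"global"} or \code{"per_channel"}.
#' @slot mode selection mode the \code{selected} slot corresponds to.
#' @slot method regularization method the path was computed for.
#' @slot selected selected alpha (scalar in global scope, one per channel
#'   otherwise).
#' @seealso [selectAlpha()], [lcurveSelect()]
#' @export
setClass("AlphaPath",
    representation(alphas = "numeric", residualNorms = "matrix",
                   smoothingNorms = "matrix", df = "numeric",
                   gcv = "matrix", cp = "matrix", curvature = "matrix",
                   sigma2 = "numeric", scope = "character",
                   mode = "character", method = "character",
                   selected = "numeric"))

setValidity("AlphaPath", function(object) {
    msg <- character()
    na <- length(object@alphas)
    if (na > 1L && any(diff(object@alphas) <= 0))
        msg <- c(msg, "alphas must be strictly increasing")
    for (s in c("residualNorms", "smoothingNorms", "gcv", "cp", "curvature"))
        if (nrow(slot(object, s)) != na)
            msg <- c(msg, sprintf("%s must have one row per alpha", s))
    if (length(object@df) != na)
        msg <- c(msg, "df must have one entry per alpha")
    if (!object@scope %in% c("global", "per_channel"))
        msg <- c(msg, "scope must be 'global' or 'per_channel'")
    if (length(msg)) msg else TRUE
})

#' Lifetime density map
#'
#' The assembled \code{n_tau x n_lambda} matrix of pre-exponential
#' amplitudes \eqn{x(\tau, \lambda)}: lifetime on the vertical axis,
#' wavelength on the horizontal axis, positive and negative amplitudes as
#' the contour values. Channels that failed to solve are recorded in
#' \code{meta$failedChannels} and filled with \code{NA}.
#'
#' @slot taus lifetime axis.
#' @slot wavelengths wavelength axis.
#' @slot amplitudes \code{n_tau x n_lambda} matrix.
#' @slot config the [RegConfig-class] used.
#' @slot alphaUsed scalar or per-channel alpha actually applied.
#' @slot overlayTaus lifetimes from a global fit to draw as dashed
#'   horizontal lines on the map (may be empty).
#' @slot meta provenance list (failed channels, convergence flags, ...).
#' @seealso [computeLDM()], [plotLDM()], [exportLDM()]
#' @export
setClass("LifetimeDensityMap",
    representation(taus = "numeric", wavelengths = "numeric",
                   amplitudes = "matrix", config = "RegConfig",
                   alphaUsed = "numeric", overlayTaus = "numeric",
                   meta = "list"),
    prototype(overlayTaus = numeric(), meta = list()))

setValidity("LifetimeDensityMap", function(object) {
    msg <- character()
    if (nrow(object@amplitudes) != length(object@taus))
        msg <- c(msg, "nrow(amplitudes) != length(taus)")
    if (ncol(object@amplitudes) != length(object@wavelengths))
        msg <- c(msg, "ncol(amplitudes) != length(wavelengths)")
    if (!length(object@alphaUsed) %in% c(1L, length(object@wavelengths)))
        msg <- c(msg, "alphaUsed must be scalar or one per channel")
    if (length(msg)) msg else TRUE
})
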