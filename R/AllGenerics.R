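#' Accessors for ldmap objects
#'
#' Small accessor generics used across the package's classes instead of
#' direct slot access.
#'
#' @param x an ldmap S4 object.
#' @return The corresponding axis, matrix or scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("decaySpectra", function(x) standardGeneric("decaySpectra"))

#' @rdname accessors
#' @export
setGeneric("alphaGrid", function(x) standardGeneric("alphaGrid"))

#' @rdname accessors
#' @export
setGeneric("selectedAlpha", function(x) standardGeneric("selectedAlpha"))

#' @rdname accessors
#' @export
setGeneric("metaInfo", function(x) standardGeneric("metaInfo"))

#' @rdname accessors
setMethod("times", "TRSpectra", function(x) x@times)
#' @rdname accessors
setMethod("wavelengths", "TRSpectra", function(x) x@wavelengths)
#' @rdname accessors
setMethod("signalMatrix", "TRSpectra", function(x) x@values)
#' @rdname accessors
setMethod("metaInfo", "TRSpectra", function(x) x@meta)

#' @rdname accessors
setMethod("times", "KineticBasis", function(x) x@times)
#' @rdname accessors
setMethod("lifetimes", "KineticBasis", function(x) x@grid@taus)
#' @rdname accessors
setMethod("basisMatrix", "KineticBasis", function(x) x@values)

#' @rdname accessors
setMethod("lifetimes", "LifetimeGrid", function(x) x@taus)

#' @rdname accessors
setMethod("singularValues", "TRSVD", function(x) x@d)

#' @rdname accessors
setMethod("lifetimes", "GlobalFit", function(x) x@taus)
#' @rdname accessors
setMethod("amplitudes", "GlobalFit", function(x) x@amplitudes)
#' @rdname accessors
setMethod("residualNorm", "GlobalFit", function(x) x@residualNorm)
#' @rdname accessors
setMethod("isConverged", "GlobalFit", function(x) x@converged)
#' @rdname accessors
setMethod("decaySpectra", "GlobalFit", function(x) x@das)

#' @rdname accessors
setMethod("alphaGrid", "AlphaPath", function(x) x@alphas)
#' @rdname accessors
setMethod("selectedAlpha", "AlphaPath", function(x) x@selected)

#' @rdname accessors
setMethod("lifetimes", "LifetimeDensityMap", function(x) x@taus)
#' @rdname accessors
setMethod("wavelengths", "LifetimeDensityMap", function(x) x@wavelengths)
#' @rdname accessors
setMethod("amplitudes", "LifetimeDensityMap", function(x) x@amplitudes)
#' @rdname accessors
setMethod("selectedAlpha", "LifetimeDensityMap", function(x) x@alphaUsed)
#' @rdname accessors
setMethod("metaInfo", "LifetimeDensityMap", function(x) x@meta)

setMethod("show", "TRSpectra", function(object) {
    cat(sprintf("TRSpectra: %d time delays x %d wavelength channels\n",
                length(object@times), length(object@wavelengths)))
    cat(sprintf("  time range: [%g, %g]; wavelength range: [%g, %g]\n",
                min(object@times), max(object@times),
                min(object@wavelengths), max(object@wavelengths)))
    if (length(object@meta))
        cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "KineticBasis", function(object) {
    cat(sprintf(
        "KineticBasis: %d x %d (%s-spaced lifetimes in [%g, %g], IRF: %s)\n",
        nrow(object@values), ncol(object@values), object@grid@spacing,
        min(object@grid@taus), max(object@grid@taus), object@irf@kind))
})

setMethod("show", "TRSVD", function(object) {
    cat(sprintf("TRSVD: %d singular values; leading: %s\n",
                length(object@d),
                paste(signif(utils::head(object@d, 5), 4), collapse = ", ")))
})

setMethod("show", "GlobalFit", function(object) {
    cat(sprintf("GlobalFit: %d component(s), %sconverged (%d iterations)\n",
                length(object@taus), if (object@converged) "" else "NOT ",
                object@nIterations))
    cat("  lifetimes:", paste(signif(object@taus, 5), collapse = ", "), "\n")
    cat(sprintf("  residual norm: %.6g\n", object@residualNorm))
})

setMethod("show", "AlphaPath", function(object) {
    cat(sprintf("AlphaPath (%s, %s scope): %d alphas in [%g, %g]\n",
                object@method, object@scope, length(object@alphas),
                min(object@alphas), max(object@alphas)))
    cat(sprintf("  mode '%s' selected alpha: %s\n", object@mode,
                paste(signif(object@selected, 4), collapse = ", ")))
})

setMethod("show", "LifetimeDensityMap", function(object) {
    cat(sprintf("LifetimeDensityMap: %d lifetimes x %d channels (%s)\n",
                length(object@taus), length(object@wavelengths),
                object@config@method))
    cat(sprintf("  alpha used: %s\n",
                paste(signif(unique(object@alphaUsed), 4), collapse = ", ")))
    if (length(object@overlayTaus))
        cat("  overlay lifetimes:",
            paste(signif(object@overlayTaus, 4), collapse = ", "), "\n")
    fc <- object@meta$failedChannels
    if (length(fc)) cat("  failed channels:", length(fc), "\n")
})
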