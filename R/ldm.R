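## Assembly of per-wavelength amplitude solutions into a lifetime density
## map, its lin-log plotting convention, and text/plot export.

#' Compute a lifetime density map
#'
#' Solves the regularized inversion \eqn{A_\lambda = D x_\lambda}
#' independently for every wavelength channel with the configured method
#' and assembles the amplitude columns into the \code{n_tau x n_lambda}
#' map. No smoothing couples neighbouring channels. A channel whose solve
#' fails is filled with \code{NA} and recorded in
#' \code{metaInfo(ldm)$failedChannels} rather than silently zeroed.
#'
#' @param ds a [TRSpectra-class] object.
#' @param dm a [KineticBasis-class] built on the same time axis.
#' @param config a [RegConfig-class]; its \code{alpha} slot is overridden
#'   by \code{alpha} when supplied.
#' @param alpha scalar or per-channel penalty weight(s).
#' @param overlayTaus optional global-fit lifetimes stored for plotting as
#'   dashed horizontal lines.
#' @return A [LifetimeDensityMap-class] object.
#' @examples
#' ds <- presetDataset("dynamic", noiseFraction = 0, seed = 1)
#' dm <- buildDesignMatrix(makeLifetimeGrid(2, 500, 40), times(ds))
#' ldm <- computeLDM(ds, dm, RegConfig("tikhonov", alpha = 0.1))
#' @export
computeLDM <- function(ds, dm, config, alpha = NULL, overlayTaus = numeric()) {
    stopifnot(is(ds, "TRSpectra"), is(dm, "KineticBasis"),
              is(config, "RegConfig"))
    if (!isTRUE(all.equal(dm@times, ds@times, tolerance = 1e-12)))
        stop("design matrix and dataset must share the same time axis")
    if (is.null(alpha)) alpha <- config@alpha
    nch <- length(ds@wavelengths)
    if (!length(alpha) %in% c(1L, nch))
        stop("alpha must be a scalar or one value per channel")
    alphaVec <- rep_len(as.numeric(alpha), nch)
    D <- dm@values
    taus <- dm@grid@taus
    L <- makePenaltyMatrix(config@penalty, ncol(D))
    A <- ds@values
    perChannelT0 <- dm@irf@kind == "gaussian" && length(dm@irf@t0) > 1L
    if (perChannelT0 && length(dm@irf@t0) != nch)
        stop("per-channel t0 must have one entry per wavelength")

    out <- matrix(NA_real_, ncol(D), nch)
    failed <- integer()
    conv <- rep(TRUE, nch)
    uniformAlpha <- length(unique(alphaVec)) == 1L && !perChannelT0
    if (uniformAlpha && config@method %in% c("tsvd", "tikhonov")) {
        ## shared factorization across channels
        out <- if (config@method == "tsvd")
            solveTSVD(D, A, config@k)
        else solveTikhonov(D, A, alphaVec[1L], l = L)
        out <- as.matrix(out)
    } else {
        for (ch in seq_len(nch)) {
            Dch <- if (perChannelT0)
                buildDesignMatrix(dm@grid, ds@times,
                                  irfGaussian(dm@irf@fwhm,
                                              dm@irf@t0[ch]))@values
            else D
            res <- tryCatch(switch(config@method,
                tsvd = solveTSVD(Dch, A[, ch], config@k),
                tikhonov = solveTikhonov(Dch, A[, ch], alphaVec[ch], l = L),
                lasso = solveLasso(Dch, A[, ch], alphaVec[ch]),
                elastic_net = solveElasticNet(Dch, A[, ch], alphaVec[ch],
                                              rho = config@rho, l = L)),
                error = function(e) e)
            if (inherits(res, "error")) {
                failed <- c(failed, ch)
            } else {
                out[, ch] <- as.numeric(res)
                if (!is.null(attr(res, "converged")))
                    conv[ch] <- attr(res, "converged")
            }
        }
        if (length(failed))
            warning(length(failed), " channel(s) failed to solve; filled ",
                    "with NA (see metaInfo()$failedChannels)")
    }
    new("LifetimeDensityMap", taus = taus, wavelengths = ds@wavelengths,
        amplitudes = out, config = config, alphaUsed = as.numeric(alpha),
        overlayTaus = as.numeric(overlayTaus),
        meta = list(failedChannels = failed,
                    nonConvergedChannels = which(!conv),
                    irf = dm@irf@kind))
}

#' Lin-log plotting coordinate
#'
#' The conventional lifetime-axis transform for these maps: linear up to
#' the breakpoint (default 1 time unit), logarithmic beyond it;
#' continuous and monotone, \code{t = breakpoint} maps to 1.
#'
#' @param t non-negative time value(s).
#' @param breakpoint linear/log transition point (> 0).
#' @return Transformed coordinate(s).
#' @examples
#' linlogCoordinate(c(0.5, 1, 100))  # 0.5, 1, 3
#' @export
linlogCoordinate <- function(t, breakpoint = 1) {
    if (any(t < 0)) stop("t must be non-negative")
    stopifnot(breakpoint > 0)
    ifelse(t <= breakpoint, t / breakpoint, 1 + log10(t / breakpoint))
}

#' Plot a lifetime density map
#'
#' Contour map with wavelength on the x-axis and lifetime on a lin-log
#' y-axis; positive amplitudes drawn as solid contours, negative as dashed,
#' with symmetric levels spanning the 99th percentile of the absolute
#' amplitudes. Global-fit lifetimes stored in the object are overlaid as
#' dashed horizontal lines.
#'
#' @param ldm a [LifetimeDensityMap-class] object.
#' @param nLevels number of contour levels per sign.
#' @param breakpoint lin-log breakpoint for the lifetime axis.
#' @param ... further arguments to [graphics::contour()].
#' @return Invisibly, \code{NULL}.
#' @export
plotLDM <- function(ldm, nLevels = 8L, breakpoint = 1, ...) {
    stopifnot(is(ldm, "LifetimeDensityMap"))
    amp <- ldm@amplitudes
    y <- linlogCoordinate(ldm@taus, breakpoint)
    x <- ldm@wavelengths
    if (length(x) > 1L && x[1L] > x[2L]) {  # contour needs increasing axes
        x <- rev(x)
        amp <- amp[, rev(seq_along(ldm@wavelengths)), drop = FALSE]
    }
    z <- t(amp)  # contour wants x along rows
    top <- stats::quantile(abs(amp[is.finite(amp)]), 0.99, names = FALSE)
    if (top <= 0) top <- max(abs(amp[is.finite(amp)]), 1)
    lev <- seq(0, top, length.out = nLevels + 1L)[-1L]
    graphics::plot(range(x), range(y), type = "n", xlab = "wavelength (nm)",
                   ylab = "lifetime (lin-log)", yaxt = "n", ...)
    ticks <- pretty(ldm@taus, n = 6)
    ticks <- ticks[ticks >= min(ldm@taus) & ticks > 0]
    graphics::axis(2, at = linlogCoordinate(ticks, breakpoint),
                   labels = signif(ticks, 3))
    graphics::contour(x, y, z, levels = lev, col = "firebrick", lty = 1,
                      add = TRUE, drawlabels = FALSE)
    graphics::contour(x, y, z, levels = -rev(lev), col = "navy", lty = 2,
                      add = TRUE, drawlabels = FALSE)
    if (length(ldm@overlayTaus))
        graphics::abline(h = linlogCoordinate(ldm@overlayTaus, breakpoint),
                         lty = 2, col = "grey30")
    invisible(NULL)
}

## Stable hash of the serialized configuration (md5 of its JSON text).
.configHash <- function(cfg) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
    unname(tools::md5sum(tf))
}

.configAsList <- function(ldm)
    list(method = ldm@config@method, alpha = ldm@alphaUsed,
         rho = ldm@config@rho,
         k = if (is.na(ldm@config@k)) NULL else ldm@config@k,
         penalty = ldm@config@penalty, overlayTaus = ldm@overlayTaus,
         failedChannels = ldm@meta$failedChannels)

#' Export a lifetime density map
#'
#' Writes \code{<stem>_ldm.csv} (amplitudes with the lifetime axis as the
#' first column and the wavelength axis as the header row, re-readable with
#' [readLDM()]), \code{<stem>_config.json} (method, alpha(s), penalty,
#' overlay lifetimes and a hash of that configuration), and optionally
#' \code{<stem>_ldm.png} via [plotLDM()].
#'
#' @param ldm a [LifetimeDensityMap-class] object.
#' @param stem output path stem.
#' @param plot \code{"png"} or \code{"none"}.
#' @return Invisibly, the vector of files written.
#' @export
exportLDM <- function(ldm, stem, plot = c("none", "png")) {
    stopifnot(is(ldm, "LifetimeDensityMap"))
    plot <- match.arg(plot)
    csv <- paste0(stem, "_ldm.csv")
    ## same layout as the dataset writer: corner cell, header row, axis col
    tmp <- TRSpectra(ldm@taus, ldm@wavelengths,
                     ifelse(is.finite(ldm@amplitudes), ldm@amplitudes, 0))
    hasNA <- any(!is.finite(ldm@amplitudes))
    if (hasNA)
        warning("non-finite amplitudes written as 0 in the CSV export ",
                "(failed channels listed in the sidecar)")
    writeDataset(tmp, csv)
    cfg <- .configAsList(ldm)
    cfg$configHash <- .configHash(cfg)
    side <- paste0(stem, "_config.json")
    jsonlite::write_json(cfg, side, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(csv, side)
    if (plot == "png") {
        png <- paste0(stem, "_ldm.png")
        grDevices::png(png, width = 900, height = 700)
        plotLDM(ldm)
        grDevices::dev.off()
        files <- c(files, png)
    }
    invisible(files)
}

#' Read back an exported lifetime density map CSV
#'
#' @param path a \code{*_ldm.csv} written by [exportLDM()].
#' @return List with \code{taus}, \code{wavelengths}, \code{amplitudes}.
#' @export
readLDM <- function(path) {
    ds <- readDataset(path)
    list(taus = ds@times, wavelengths = ds@wavelengths,
         amplitudes = ds@values)
}
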