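## Synthetic kinetic schemes: Gaussian spectral bands decaying as
## equal-weight mixtures of exponential lifetimes, optionally red-shifting
## (dynamic motion). Used throughout the tests; also the reference inputs
## for the end-to-end validation scenarios.

#' Population of a species at time t
#'
#' The population decays as an equal-weight mixture of the species'
#' lifetimes: \eqn{c(t) = (1/J)\sum_{j=1}^J \exp(-t/\tau_j)} (each molecule
#' has an equal chance of decaying with any of the J lifetimes).
#'
#' @param spec a [SpeciesSpec-class] object.
#' @param t time(s), all \code{>= 0}.
#' @return Numeric vector of concentrations, \code{c(0) = 1}.
#' @examples
#' sp <- SpeciesSpec(500, 20, 1, lifetimes = 100)
#' speciesConcentration(sp, 100)  # exp(-1)
#' @export
speciesConcentration <- function(spec, t) {
    stopifnot(is(spec, "SpeciesSpec"))
    if (any(t < 0)) stop("t must be non-negative")
    rowMeans(exp(-outer(as.numeric(t), 1 / spec@lifetimes)))
}

## Band center at time t (red/blue shift saturating at shiftTarget).
.bandCenter <- function(spec, t) {
    if (is.na(spec@shiftTarget)) rep(spec@center, length(t))
    else spec@center + (spec@shiftTarget - spec@center) *
        (1 - exp(-t / spec@shiftTau))
}

#' Spectral band of a species at time t
#'
#' Gaussian band \eqn{a \exp(-(\lambda - \mu(t))^2 / (2 w^2))} with
#' time-dependent center \eqn{\mu(t)} when the species shifts
#' (\eqn{\mu(t) = c_0 + (c_\infty - c_0)(1 - e^{-t/\tau_s})}), else the
#' static center.
#'
#' @param spec a [SpeciesSpec-class] object.
#' @param t a single time.
#' @param wavelengths wavelength axis (nm).
#' @return Numeric vector over \code{wavelengths}.
#' @export
speciesSpectrum <- function(spec, t, wavelengths) {
    stopifnot(is(spec, "SpeciesSpec"), length(t) == 1L)
    mu <- .bandCenter(spec, t)
    spec@amplitude * exp(-(wavelengths - mu)^2 / (2 * spec@width^2))
}

#' Simulate a time-resolved dataset from a kinetic scheme
#'
#' Sums \code{concentration(t) * spectrum(t, lambda)} over all species and
#' adds i.i.d. Gaussian noise with standard deviation
#' \code{noiseFraction * max(abs(noiseless signal))}. Identical seed and
#' inputs give a bit-identical dataset.
#'
#' @param specs list of [SpeciesSpec-class] objects (at least one).
#' @param times time axis, strictly increasing, all \code{>= 0}.
#' @param wavelengths wavelength axis, strictly monotonic.
#' @param noiseFraction noise amplitude as a fraction of the maximum
#'   absolute noiseless signal (default 0.10).
#' @param seed RNG seed for the noise draw.
#' @return A [TRSpectra-class] object; \code{meta} records the noise
#'   fraction, seed and species parameters.
#' @examples
#' sp <- SpeciesSpec(500, 20, 1, lifetimes = 100)
#' ds <- simulateDataset(list(sp), times = seq(0, 500, 5),
#'                       wavelengths = seq(450, 550, 2), noiseFraction = 0)
#' @export
simulateDataset <- function(specs, times, wavelengths, noiseFraction = 0.10,
                            seed = 1L) {
    if (!length(specs)) stop("at least one species is required")
    if (!length(times) || !length(wavelengths)) stop("empty axis")
    stopifnot(all(vapply(specs, is, logical(1L), "SpeciesSpec")))
    if (noiseFraction < 0) stop("noiseFraction must be >= 0")
    times <- as.numeric(times); wavelengths <- as.numeric(wavelengths)
    m <- length(times); n <- length(wavelengths)
    clean <- matrix(0, m, n)
    for (sp in specs) {
        conc <- speciesConcentration(sp, times)
        mu <- .bandCenter(sp, times)
        band <- exp(-outer(-mu, wavelengths, "+")^2 / (2 * sp@width^2))
        clean <- clean + (conc * sp@amplitude) * band
    }
    vals <- clean
    if (noiseFraction > 0) {
        sigma <- noiseFraction * max(abs(clean))
        set.seed(as.integer(seed))
        vals <- clean + matrix(stats::rnorm(m * n, sd = sigma), m, n)
    }
    TRSpectra(times, wavelengths, vals,
              meta = list(noiseFraction = noiseFraction,
                          seed = as.integer(seed),
                          species = lapply(specs, .speciesAsList)))
}

.speciesAsList <- function(sp)
    list(center = sp@center, width = sp@width, amplitude = sp@amplitude,
         lifetimes = sp@lifetimes, shiftTarget = sp@shiftTarget,
         shiftTau = sp@shiftTau)

#' Built-in synthetic scenarios
#'
#' Three reference kinetic schemes exercising the analysis end to end:
#' \describe{
#'   \item{heterogeneous}{three static species, each decaying with an
#'     equal-weight mixture of three lifetimes (nine distinct lifetimes in
#'     total, spanning two decades, 5-500 time units).}
#'   \item{dynamic}{a single Gaussian band red-shifting (485 to 525 nm,
#'     shift time constant 16) while decaying with a single 100-unit
#'     lifetime.}
#'   \item{combined}{five species mixing heterogeneous decay and dynamic
#'     motion, including lifetimes longer than the last time point.}
#' }
#' The exact band centers, widths and lifetimes are documented package
#' configuration, not fitted quantities; [presetAxes()] returns the default
#' time/wavelength axes for each scenario and [presetDataset()] simulates it
#' in one call.
#'
#' @param name \code{"heterogeneous"}, \code{"dynamic"} or
#'   \code{"combined"}.
#' @return \code{presetSpecies}: list of [SpeciesSpec-class];
#'   \code{presetAxes}: list with \code{times} and \code{wavelengths};
#'   \code{presetDataset}: a [TRSpectra-class] object.
#' @examples
#' length(presetSpecies("combined"))  # 5
#' ds <- presetDataset("dynamic", noiseFraction = 0, seed = 1)
#' @export
presetSpecies <- function(name = c("heterogeneous", "dynamic", "combined")) {
    name <- match.arg(name)
    switch(name,
        heterogeneous = list(
            SpeciesSpec(450, 25, 1.0, lifetimes = c(5, 15, 50)),
            SpeciesSpec(550, 30, 0.8, lifetimes = c(10, 40, 160)),
            SpeciesSpec(650, 25, 0.9, lifetimes = c(30, 100, 500))),
        dynamic = list(
            SpeciesSpec(485, 35, 1.0, lifetimes = 100,
                        shiftTarget = 525, shiftTau = 16)),
        combined = list(
            SpeciesSpec(430, 20, 0.9, lifetimes = c(1, 5, 20)),
            SpeciesSpec(480, 22, 0.7, lifetimes = c(15, 60, 240)),
            SpeciesSpec(530, 18, 1.0, lifetimes = 100,
                        shiftTarget = 560, shiftTau = 8),
            SpeciesSpec(620, 25, -0.6, lifetimes = c(50, 200, 800)),
            SpeciesSpec(670, 20, 0.8, lifetimes = c(400, 2000))))
}

#' @rdname presetSpecies
#' @export
presetAxes <- function(name = c("heterogeneous", "dynamic", "combined")) {
    name <- match.arg(name)
    switch(name,
        heterogeneous = list(times = seq(0, 2500, length.out = 500L),
                             wavelengths = seq(400, 700, by = 2.5)),
        dynamic = list(times = seq(0, 750, length.out = 750L),
                       wavelengths = seq(400, 650, by = 0.8)),
        combined = list(times = seq(0, 500, length.out = 400L),
                        wavelengths = seq(400, 740, by = 2.5)))
}

#' @rdname presetSpecies
#' @param noiseFraction,seed passed to [simulateDataset()].
#' @export
presetDataset <- function(name = c("heterogeneous", "dynamic", "combined"),
                          noiseFraction = 0.10, seed = 1L) {
    name <- match.arg(name)
    ax <- presetAxes(name)
    ds <- simulateDataset(presetSpecies(name), ax$times, ax$wavelengths,
                          noiseFraction = noiseFraction, seed = seed)
    ds@meta$preset <- name
    ds
}

#' Dump or load a species configuration as plain text
#'
#' Writes one \code{key = value} line per field, numbered per species
#' (\code{species1.center = 450}, ...), so a scheme can be archived and
#' re-simulated exactly.
#'
#' @param specs list of [SpeciesSpec-class] objects.
#' @param path file path.
#' @return \code{readSpeciesConfig} returns a list of
#'   [SpeciesSpec-class] objects; \code{writeSpeciesConfig} returns
#'   \code{path} invisibly.
#' @export
writeSpeciesConfig <- function(specs, path) {
    fmt <- function(x) paste(formatC(x, digits = 17, format = "g"),
                             collapse = ", ")
    lines <- character()
    for (i in seq_along(specs)) {
        sp <- specs[[i]]
        pre <- sprintf("species%d.", i)
        lines <- c(lines,
            paste0(pre, "center = ", fmt(sp@center)),
            paste0(pre, "width = ", fmt(sp@width)),
            paste0(pre, "amplitude = ", fmt(sp@amplitude)),
            paste0(pre, "lifetimes = ", fmt(sp@lifetimes)),
            paste0(pre, "shiftTarget = ", fmt(sp@shiftTarget)),
            paste0(pre, "shiftTau = ", fmt(sp@shiftTau)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSpeciesConfig
#' @export
readSpeciesConfig <- function(path) {
    lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, "", 1L))
    vals <- lapply(kv, function(x) {
        y <- trimws(strsplit(paste(x[-1L], collapse = "="),
                             ",", fixed = TRUE)[[1L]])
        out <- suppressWarnings(as.numeric(y))
        bad <- is.na(out) & !y %in% c("NA", "NaN")
        if (any(bad)) stop("non-numeric config value: ", y[bad][1L])
        out
    })
    names(vals) <- keys
    ids <- sort(unique(sub("^species(\\d+)\\..*$", "\\1",
                           keys[grepl("^species\\d+\\.", keys)])))
    lapply(ids, function(i) {
        g <- function(f) vals[[sprintf("species%s.%s", i, f)]]
        SpeciesSpec(g("center"), g("width"), g("amplitude"), g("lifetimes"),
                    g("shiftTarget"), g("shiftTau"))
    })
}
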