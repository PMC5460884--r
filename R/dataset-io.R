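## Delimited-text I/O for time-resolved data matrices.
## Layout: first row = wavelengths with an empty corner cell, first column =
## time delays (the common transient-absorption export shape); the
## "wavelength_rows" dialect reads the transpose.

.delimFor <- function(path) {
    if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a time-resolved data matrix from delimited text
#'
#' Parses a CSV/TSV file (delimiter chosen by extension) whose first row
#' holds the wavelength axis (with an empty corner cell) and whose first
#' column holds the time-delay axis. The \code{"wavelength_rows"} dialect
#' reads the transposed layout (rows = wavelengths).
#'
#' @param path file path.
#' @param dialect \code{"time_rows"} (default) or \code{"wavelength_rows"}.
#' @return A validated [TRSpectra-class] object; \code{meta$source} records
#'   the path.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ds <- TRSpectra(0:3, c(500, 510), matrix(rnorm(8), 4, 2))
#' writeDataset(ds, f)
#' ds2 <- readDataset(f)
#' all.equal(signalMatrix(ds), signalMatrix(ds2))
#' @export
readDataset <- function(path, dialect = c("time_rows", "wavelength_rows")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .delimFor(path)
    raw <- utils::read.table(path, header = FALSE, sep = sep,
                             colClasses = "character",
                             stringsAsFactors = FALSE, strip.white = TRUE)
    if (nrow(raw) < 2L || ncol(raw) < 2L)
        stop("file must contain at least one axis row and one axis column")
    num <- function(x, what) {
        y <- suppressWarnings(as.numeric(x))
        bad <- which(is.na(y) & !(x %in% c("NA", "NaN")) )
        if (length(bad))
            stop(sprintf("non-numeric cell in %s at position %d: '%s'",
                         what, bad[1L], x[bad[1L]]))
        y
    }
    colAxis <- num(unlist(raw[1L, -1L], use.names = FALSE), "header row")
    rowAxis <- num(raw[-1L, 1L], "first column")
    body <- raw[-1L, -1L, drop = FALSE]
    vals <- matrix(NA_real_, nrow(body), ncol(body))
    for (j in seq_len(ncol(body)))
        vals[, j] <- num(body[[j]], sprintf("data column %d", j + 1L))
    if (dialect == "time_rows") {
        tms <- rowAxis; wls <- colAxis
    } else {
        tms <- colAxis; wls <- rowAxis; vals <- t(vals)
    }
    if (length(tms) > 1L && any(diff(tms) <= 0))
        stop("time axis is not strictly increasing (duplicated or ",
             "non-monotone delays)")
    TRSpectra(tms, wls, vals, meta = list(source = path, dialect = dialect))
}

#' Write a time-resolved data matrix as delimited text
#'
#' Writes the layout read by [readDataset()] (header row of wavelengths with
#' an empty corner cell, first column of time delays). Values are formatted
#' at 17 significant digits so a read/write round trip is the identity up to
#' float formatting.
#'
#' @param ds a [TRSpectra-class] object with all-finite values.
#' @param path output file path (\code{.tsv}/\code{.tab} switches the
#'   delimiter to tab).
#' @return Invisibly, \code{path}.
#' @export
writeDataset <- function(ds, path) {
    stopifnot(is(ds, "TRSpectra"))
    validObject(ds)  # refuses non-finite values
    sep <- .delimFor(path)
    fmt <- function(x) trimws(formatC(x, digits = 17, format = "g"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("", fmt(ds@wavelengths)), collapse = sep), con)
    body <- cbind(fmt(ds@times),
                  matrix(fmt(ds@values), nrow(ds@values), ncol(ds@values)))
    writeLines(apply(body, 1L, paste, collapse = sep), con)
    invisible(path)
}

#' Best rank-k approximation of a dataset
#'
#' Low-rank data approximation: replaces the data matrix with its best
#' rank-\code{k} approximation (leading \code{k} singular triplets), a
#' cut-off filter applied to the data matrix itself as a dimension-reduction
#' or denoising step, distinct from truncated-SVD regularization of the
#' design matrix.
#'
#' @param ds a [TRSpectra-class] object.
#' @param k retained rank, \code{1 <= k <= min(dim)}.
#' @return A [TRSpectra-class] object with the truncated values;
#'   \code{meta$truncationRank} records \code{k}.
#' @export
truncateData <- function(ds, k) {
    stopifnot(is(ds, "TRSpectra"))
    kmax <- min(dim(ds@values))
    if (!is.numeric(k) || length(k) != 1L || k < 1L || k > kmax ||
        k != round(k))
        stop("k must be an integer in [1, ", kmax, "]")
    k <- as.integer(k)
    sv <- svd(ds@values, nu = k, nv = k)
    approx <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    meta <- ds@meta
    meta$truncationRank <- k
    TRSpectra(ds@times, ds@wavelengths, approx, meta)
}
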