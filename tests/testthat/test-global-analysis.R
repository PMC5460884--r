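test_that("the SVD is orthonormal and reconstructs the data", {
    ds <- TRSpectra(1:3, 1:3, diag(3))
    sv <- computeSVD(ds)
    expect_equal(singularValues(sv), rep(1, 3))
    set.seed(5)
    A <- matrix(rnorm(60), 12, 5)
    sv <- computeSVD(TRSpectra(1:12, 1:5, A))
    rec <- sv@u[, 1:5] %*% (singularValues(sv) * t(sv@v))
    expect_equal(rec, A, tolerance = 1e-10)
})

test_that("significant singular values are counted by the median-ratio rule", {
    expect_identical(as.integer(countSignificant(c(10, 10, rep(1e-12, 8)))),
                     2L)
    expect_warning(k0 <- countSignificant(rep(3, 10)), "no singular value")
    expect_identical(as.integer(k0), 0L)
    expect_error(countSignificant(numeric()), "empty")
    ## pluggable rule is honoured and reported
    k <- countSignificant(c(5, 4, 3), rule = function(s) sum(s > 3.5))
    expect_identical(as.integer(k), 2L)
    expect_identical(attr(k, "rule"), "user")
})

test_that("weighted left singular vectors honour order and selection", {
    set.seed(9)
    sv <- computeSVD(TRSpectra(1:20, 1:8, matrix(rnorm(160), 20, 8)))
    w <- selectWLSV(sv, c(1, 2, 3, 5))
    expect_identical(ncol(w), 4L)
    expect_equal(w[, 4], sv@u[, 5] * singularValues(sv)[5])
    expect_equal(selectWLSV(sv, c(3, 1))[, 2], selectWLSV(sv, 1)[, 1])
    expect_error(selectWLSV(sv, c(1, 1)), "distinct")
    expect_error(selectWLSV(sv, 99), "out of range")
    ## rank-1 input: first wLSV is proportional to the temporal profile
    prof <- exp(-(0:49) / 10)
    r1 <- TRSpectra(0:49, 1:4, outer(prof, c(1, 2, 3, 4)))
    w1 <- selectWLSV(computeSVD(r1), 1)
    expect_lt(abs(abs(cor(w1[, 1], prof)) - 1), 1e-12)
})

test_that("variable projection recovers noiseless lifetimes exactly", {
    tt <- seq(0, 500, 2)
    fit1 <- fitGlobal(cbind(exp(-tt / 100)), tt, tauInit = 50)
    expect_lt(abs(lifetimes(fit1) - 100) / 100, 1e-6)
    expect_true(isConverged(fit1))
    ## 2- and 3-exponential recovery within 0.1% (decade-separated)
    Y2 <- cbind(2 * exp(-tt / 5) - exp(-tt / 80),
                exp(-tt / 5) + 0.5 * exp(-tt / 80))
    fit2 <- fitGlobal(Y2, tt, tauInit = c(3, 120))
    expect_lt(max(abs(lifetimes(fit2) - c(5, 80)) / c(5, 80)), 1e-3)
    tt3 <- seq(0, 2000, 1)
    Y3 <- cbind(exp(-tt3 / 2) + exp(-tt3 / 30) + exp(-tt3 / 400))
    fit3 <- fitGlobal(Y3, tt3, tauInit = c(1, 50, 600))
    expect_lt(max(abs(lifetimes(fit3) - c(2, 30, 400)) /
                  c(2, 30, 400)), 1e-3)
    ## lifetimes reported ascending with amplitude rows permuted to match
    fitr <- fitGlobal(Y2, tt, tauInit = c(120, 3))
    expect_equal(lifetimes(fitr), sort(lifetimes(fitr)))
    expect_equal(amplitudes(fitr)[, 1], c(2, -1), tolerance = 1e-4)
})

test_that("the inner amplitude solve matches normal equations", {
    tt <- seq(0, 300, 3)
    taus <- c(10, 90)
    D <- cbind(exp(-tt / taus[1]), exp(-tt / taus[2]))
    Y <- cbind(D %*% c(1.5, -0.7), D %*% c(0.2, 1.1))
    fit <- fitGlobal(Y, tt, tauInit = taus)
    Dhat <- cbind(exp(-tt / lifetimes(fit)[1]),
                  exp(-tt / lifetimes(fit)[2]))
    xNE <- solve(crossprod(Dhat), crossprod(Dhat, Y))
    expect_equal(unname(amplitudes(fit)), unname(xNE), tolerance = 1e-8)
})

test_that("the objective does not increase over the fit", {
    tt <- seq(0, 500, 2)
    set.seed(21)
    Y <- cbind(exp(-tt / 100) + rnorm(length(tt), sd = 0.05))
    D0 <- cbind(exp(-tt / 30))
    x0 <- qr.coef(qr(D0), Y)
    obj0 <- sum((D0 %*% x0 - Y)^2)
    fit <- fitGlobal(Y, tt, tauInit = 30)
    expect_lte(residualNorm(fit), obj0 + 1e-12)
})

test_that("bound-pinned and ill-posed fits are flagged, not hidden", {
    tt <- seq(0, 500, 2)
    fit <- fitGlobal(cbind(exp(-tt / 100)), tt, tauInit = 20,
                     lower = 5, upper = 40)
    expect_false(isConverged(fit))
    expect_match(fit@message, "pinned")
    expect_error(fitGlobal(cbind(exp(-tt / 100)), tt, tauInit = -5),
                 "positive")
    expect_error(fitGlobal(cbind(exp(-tt / 100)), tt, tauInit = 50,
                           lower = 60), "within the bounds")
})

test_that("two-component fits of the moving band invent a fast artifact", {
    ## a single red-shifting species decays with one lifetime only; the
    ## second exponential a two-component fit settles on is an artifact of
    ## the motion (band-overlap transient), absent from the scheme
    ds <- presetDataset("dynamic", noiseFraction = 0.10, seed = 4)
    sv <- computeSVD(ds)
    w <- selectWLSV(sv, c(1, 2))
    fit <- fitGlobal(w, times(ds), tauInit = c(5, 100))
    taus <- lifetimes(fit)
    expect_length(taus, 2L)
    expect_lt(abs(taus[2] - 100) / 100, 0.15)  # the real decay
    expect_lt(taus[1], 50)                     # no generating counterpart
})
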