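test_that("hat-matrix traces match closed forms and a dense oracle", {
    expect_equal(hatTrace(diag(6), 1), 3)
    D <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
    expect_equal(hatTrace(D, 0), 4, tolerance = 1e-8)
    set.seed(15)
    D <- matrix(rnorm(84), 12, 7)
    H <- D %*% solve(crossprod(D) + 0.3 * diag(7)) %*% t(D)
    expect_equal(hatTrace(D, 0.3), sum(diag(H)), tolerance = 1e-8)
    L <- makePenaltyMatrix("fused", 7)
    H2 <- D %*% solve(crossprod(D) + 0.3 * crossprod(L)) %*% t(D)
    expect_equal(hatTrace(D, 0.3, l = L), sum(diag(H2)), tolerance = 1e-8)
    ## rank-deficient design at alpha = 0 is a hard error pointing to alpha
    Dlow <- cbind(1:5, 2 * (1:5))
    expect_error(hatTrace(Dlow, 0), "alpha > 0")
})

test_that("degrees of freedom decrease strictly in alpha for L = identity", {
    set.seed(8)
    D <- matrix(rnorm(60), 12, 5)
    dfs <- vapply(10^seq(-4, 3, length.out = 15), hatTrace, numeric(1),
                  d = D)
    expect_true(all(diff(dfs) < 0))
    expect_true(all(dfs > 0 & dfs <= 5))
})

test_that("GCV matches its closed form and full-shrinkage limit", {
    ## identity design: x = a/(1+a), residual^2 = 1, tr(I-H) = 1
    expect_equal(gcvStatistic(diag(2), c(2, 0), 1), 1)
    ## full-shrinkage limit: residual -> ||A||^2, tr(I-H) -> m
    a <- c(2, 0)
    tail <- vapply(10^seq(2, 6, 1), gcvStatistic, numeric(1),
                   d = diag(2), a = a)
    expect_equal(tail[5], sum(a^2) / 4, tolerance = 1e-3)
    expect_true(all(diff(tail) >= 0))  # monotone approach from below
})

test_that("Cp matches its closed form and a direct evaluation", {
    expect_equal(cpStatistic(diag(2), c(2, 0), 1, sigma2 = 1), 3)
    ## sigma2 = 0 degenerates to the residual norm (min at smallest alpha)
    set.seed(23)
    D <- matrix(rnorm(50), 10, 5)
    a <- rnorm(10)
    alphas <- 10^seq(-3, 2, 1)
    cps <- vapply(alphas, cpStatistic, numeric(1), d = D, a = a, sigma2 = 0)
    expect_identical(which.min(cps), 1L)
    ## direct-formula oracle
    al <- 0.7; s2 <- 0.4
    x <- solveTikhonov(D, a, al)
    direct <- sum((D %*% x - a)^2) + 2 * s2 * hatTrace(D, al)
    expect_equal(cpStatistic(D, a, al, sigma2 = s2), direct,
                 tolerance = 1e-10)
    ## sigma2 estimated from the most complicated model on the grid
    est <- cpStatistic(D, a, al, alphaMin = 1e-3)
    x0 <- solveTikhonov(D, a, 1e-3)
    s2hat <- sum((D %*% x0 - a)^2) / (10 - hatTrace(D, 1e-3))
    expect_equal(est, sum((D %*% x - a)^2) + 2 * s2hat * hatTrace(D, al),
                 tolerance = 1e-10)
})

test_that("L-curve curvature recovers a circle and flags a line", {
    ## quarter circle of radius r: curvature magnitude 1/r within 2%
    r <- 3.7
    alphas <- 10^seq(-2, 2, length.out = 50)
    theta <- seq(0.1, pi / 2 - 0.1,
                 length.out = 50)  # linear in log(alpha)
    kap <- lcurveCurvature(alphas, r * cos(theta), r * sin(theta),
                           logCoords = FALSE)
    inner <- kap[5:46]
    expect_lt(max(abs(abs(inner) - 1 / r)) / (1 / r), 0.02)
    ## affine R and S: no corner
    expect_warning(
        sel <- lcurveSelect(alphas, 1 + 2 * alphas, 5 - 0.1 * alphas,
                            logCoords = FALSE), "no well-defined")
    expect_true(sel$noCorner)
    expect_true(is.na(sel$alpha))
    expect_error(lcurveCurvature(alphas[1:4], 1:4, 1:4), "at least 5")
})

test_that("alpha selection is consistent across scopes and channels", {
    sp <- SpeciesSpec(500, 25, 1, lifetimes = 60)
    tt <- seq(0, 300, 4)
    ds1 <- simulateDataset(list(sp), tt, 500, noiseFraction = 0.1, seed = 2)
    dm <- buildDesignMatrix(makeLifetimeGrid(4, 300, 30), tt)
    alphas <- 10^seq(-4, 1, length.out = 12)
    pg <- selectAlpha(ds1, dm, alphas, mode = "gcv", scope = "global")
    pc <- selectAlpha(ds1, dm, alphas, mode = "gcv", scope = "per_channel")
    expect_equal(selectedAlpha(pg), selectedAlpha(pc))
    ## two identical channels give identical per-channel selections
    ds2 <- TRSpectra(tt, c(500, 501),
                     cbind(signalMatrix(ds1), signalMatrix(ds1)))
    p2 <- selectAlpha(ds2, dm, alphas, mode = "cp", scope = "per_channel")
    expect_equal(selectedAlpha(p2)[1], selectedAlpha(p2)[2])
    ## GCV unavailable for LASSO paths
    expect_error(selectAlpha(ds1, dm, alphas, mode = "gcv",
                             method = "lasso"), "not available")
})

test_that("Tikhonov paths are monotone and never select the grid ends", {
    ds <- presetDataset("heterogeneous", noiseFraction = 0.10, seed = 5)
    tt <- times(ds)
    dm <- buildDesignMatrix(makeLifetimeGrid(min(tt[tt > 0]), max(tt), 50),
                            tt)
    path <- selectAlpha(ds, dm, mode = "gcv", scope = "global")
    R <- path@residualNorms[, 1]; S <- path@smoothingNorms[, 1]
    expect_true(all(diff(R) >= -1e-8 * max(R)))
    expect_true(all(diff(S) <= 1e-8 * max(S)))
    expect_true(all(diff(path@df) < 0))
    al <- alphaGrid(path)
    aG <- selectedAlpha(path)
    aC <- selectedAlpha(selectAlpha(ds, dm, mode = "cp", scope = "global"))
    expect_true(aG > min(al) && aG < max(al))
    expect_true(aC > min(al) && aC < max(al))
    ## the L-curve corner lies within an order of magnitude of GCV
    aL <- selectedAlpha(selectAlpha(ds, dm, mode = "lcurve",
                                    scope = "global"))
    expect_lt(abs(log10(aL) - log10(aG)), 1.000001)
})
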