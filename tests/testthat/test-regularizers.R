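test_that("penalty matrices annihilate their null spaces", {
    expect_identical(makePenaltyMatrix("identity", 3), diag(3))
    expect_equal(drop(makePenaltyMatrix("d1", 6) %*% rep(4, 6)), rep(0, 5))
    j <- 1:7
    expect_equal(drop(makePenaltyMatrix("d2", 7) %*% (2 + 3 * j)),
                 rep(0, 5), tolerance = 1e-12)
    f <- makePenaltyMatrix("fused", 5)
    expect_identical(dim(f), c(9L, 5L))
    expect_identical(f[1:5, ], diag(5))
    expect_error(makePenaltyMatrix("d2", 2), "n >= 3")
    expect_error(makePenaltyMatrix("d1", 1), "n >= 2")
})

test_that("truncated SVD matches the explicit pseudo-inverse", {
    ## orthonormal square design: full-rank TSVD is the transpose solve
    Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    a <- rnorm(5)
    expect_equal(solveTSVD(Q, a, 5), drop(crossprod(Q, a)),
                 tolerance = 1e-10)
    inst <- randomInstance(8, 5, seed = 31)
    ## full rank equals ordinary least squares
    ols <- qr.solve(inst$D, inst$a)
    expect_equal(solveTSVD(inst$D, inst$a, 5), ols, tolerance = 1e-8)
    ## rank 3 equals the independent SVD-based oracle
    expect_equal(solveTSVD(inst$D, inst$a, 3),
                 pinvSolveOracle(inst$D, inst$a, 3), tolerance = 1e-10)
    ## k above the numerical rank is clamped with a warning
    Dlow <- inst$D[, c(1, 2, 3)] %*% matrix(rnorm(15), 3, 5)
    expect_warning(xc <- solveTSVD(Dlow, inst$a, 5), "clamp")
    expect_equal(xc, pinvSolveOracle(Dlow, inst$a, 3), tolerance = 1e-8)
})

test_that("Tikhonov solutions satisfy the normal equations", {
    inst <- randomInstance(10, 6, seed = 7)
    ## penalty off: plain least squares
    expect_equal(solveTikhonov(inst$D, inst$a, 0),
                 qr.solve(inst$D, inst$a), tolerance = 1e-8)
    ## identity design: componentwise shrinkage a / (1 + alpha)
    a2 <- c(3, -1)
    expect_equal(solveTikhonov(diag(2), a2, 0.5), a2 / 1.5,
                 tolerance = 1e-12)
    ## first-difference penalty vs normal-equations oracle
    L <- makePenaltyMatrix("d1", 6)
    expect_equal(solveTikhonov(inst$D, inst$a, 0.5, l = L),
                 tikhonovOracle(inst$D, inst$a, 0.5, L), tolerance = 1e-8)
    expect_error(solveTikhonov(inst$D, inst$a, -1), "alpha")
})

test_that("the iterative LASSO solves the l1 problem", {
    ## 1-D: minimizer of (x - 3)^2 + 2|x| is 2 (brute-force oracle)
    expect_equal(as.numeric(solveLasso(matrix(1), 3, 2)),
                 lasso1dOracle(1, 3, 2), tolerance = 1e-5)
    inst <- randomInstance(12, 6, seed = 13)
    ## penalty off: ordinary least squares
    expect_equal(as.numeric(solveLasso(inst$D, inst$a, 0)),
                 qr.solve(inst$D, inst$a), tolerance = 1e-6)
    ## full-shrinkage threshold gives the zero vector
    big <- 2 * max(abs(crossprod(inst$D, inst$a))) * 1.01
    expect_equal(as.numeric(solveLasso(inst$D, inst$a, big)), rep(0, 6))
    ## subgradient optimality on a generic instance
    x <- solveLasso(inst$D, inst$a, 0.8)
    expect_true(attr(x, "converged"))
    grad <- 2 * crossprod(inst$D, inst$D %*% as.numeric(x) - inst$a)
    act <- as.numeric(x) != 0
    expect_lt(max(abs(grad[act] + 0.8 * sign(as.numeric(x)[act]))), 1e-5)
    if (any(!act)) expect_lt(max(abs(grad[!act])), 0.8 + 1e-5)
    ## non-identity penalties only via square invertible substitution
    expect_error(solveLasso(inst$D, inst$a, 1,
                            l = makePenaltyMatrix("d1", 6)), "square")
})

test_that("the LASSO agrees with an independent coordinate-descent solver", {
    inst <- randomInstance(40, 12, seed = 77)
    alpha <- 1.5
    x <- as.numeric(solveLasso(inst$D, inst$a, alpha))
    gl <- glmnet::glmnet(inst$D, inst$a, intercept = FALSE,
                         standardize = FALSE,
                         lambda = alpha / (2 * nrow(inst$D)),
                         thresh = 1e-14)
    expect_equal(x, as.numeric(gl$beta), tolerance = 1e-5)
})

test_that("the elastic net reduces to its limits and satisfies KKT", {
    inst <- randomInstance(8, 5, seed = 19)
    expect_equal(as.numeric(solveElasticNet(inst$D, inst$a, 0.7, rho = 1)),
                 as.numeric(solveLasso(inst$D, inst$a, 0.7)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(solveElasticNet(inst$D, inst$a, 0.7, rho = 0)),
                 solveTikhonov(inst$D, inst$a, 0.7), tolerance = 1e-6)
    x <- as.numeric(solveElasticNet(inst$D, inst$a, 1, rho = 0.5))
    expect_lt(enetKKTResidual(inst$D, inst$a, 0.5, 0.5, diag(5), x), 1e-6)
    ## invariance to the direct (alpha1, alpha2) parameterization
    x2 <- as.numeric(solveElasticNet(inst$D, inst$a, alpha = NULL,
                                     alpha1 = 0.5, alpha2 = 0.5))
    expect_equal(x, x2, tolerance = 1e-8)
    ## the reweighted variant scales the minimizer by (1 + alpha2)
    xr <- as.numeric(solveElasticNet(inst$D, inst$a, 1, rho = 0.5,
                                     rescale = TRUE))
    expect_equal(xr, 1.5 * x, tolerance = 1e-8)
})

test_that("all solvers meet ordinary least squares in the weak limit", {
    inst <- randomInstance(10, 4, seed = 3)
    ols <- qr.solve(inst$D, inst$a)
    expect_equal(solveTSVD(inst$D, inst$a, 4), ols, tolerance = 1e-6)
    expect_equal(solveTikhonov(inst$D, inst$a, 1e-12), ols,
                 tolerance = 1e-6)
    expect_equal(as.numeric(solveLasso(inst$D, inst$a, 1e-12)), ols,
                 tolerance = 1e-6)
    expect_equal(as.numeric(solveElasticNet(inst$D, inst$a, 1e-12,
                                            rho = 0.5)), ols,
                 tolerance = 1e-6)
})

test_that("regularization paths are monotone and LASSO paths sparser", {
    ds <- presetDataset("heterogeneous", noiseFraction = 0.10, seed = 2)
    tt <- times(ds)
    dm <- buildDesignMatrix(makeLifetimeGrid(min(tt[tt > 0]), max(tt), 40),
                            tt)
    D <- basisMatrix(dm)
    ch <- which.max(colSums(abs(signalMatrix(ds))))
    a <- signalMatrix(ds)[, ch]
    alphas <- 10^seq(-4, 2, length.out = 20)
    xt <- sapply(alphas, function(al) solveTikhonov(D, a, al))
    xl <- sapply(alphas, function(al)
        as.numeric(suppressWarnings(solveLasso(D, a, al, kktTol = 1e-4))))
    normT <- sqrt(colSums(xt^2))
    residT <- colSums((D %*% xt - a)^2)
    expect_true(all(diff(normT) <= 1e-8))
    expect_true(all(diff(residT) >= -1e-8))
    ## LASSO zero counts grow along the path (monotone trend; the exact
    ## active set can fluctuate locally between neighbouring alphas)
    zerosL <- colSums(xl == 0)
    expect_gt(cor(log(alphas), zerosL, method = "spearman"), 0.9)
    expect_identical(zerosL[1], 0)          # no shrinkage at tiny alpha
    expect_identical(zerosL[20], 40)        # full shrinkage at the end
    ## mid-path: LASSO is strictly sparser than Tikhonov at matched residual
    mid <- 12
    residL <- sum((D %*% xl[, mid] - a)^2)
    j <- which.min(abs(residT - residL))
    expect_gt(zerosL[mid], sum(abs(xt[, j]) < 1e-12))
})
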