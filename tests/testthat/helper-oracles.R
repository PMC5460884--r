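## Shared fixtures and independent oracles used across the test files.

## seeded random least-squares instance
randomInstance <- function(m, n, seed) {
    set.seed(seed)
    list(D = matrix(rnorm(m * n), m, n), a = rnorm(m))
}

## independent rank-k pseudo-inverse solution (explicit SVD route)
pinvSolveOracle <- function(D, a, k) {
    sv <- svd(D)
    x <- numeric(ncol(D))
    for (i in seq_len(k))
        x <- x + sv$v[, i] * sum(sv$u[, i] * a) / sv$d[i]
    x
}

## normal-equations oracle for Tikhonov: (D'D + a L'L) x = D'a
tikhonovOracle <- function(D, a, alpha, L)
    drop(solve(crossprod(D) + alpha * crossprod(L), crossprod(D, a)))

## brute-force 1-D LASSO objective minimizer: coarse grid then refinement
lasso1dOracle <- function(dcol, a, alpha, lo = -5, hi = 5) {
    obj <- function(x) sum((dcol * x - a)^2) + alpha * abs(x)
    xs <- seq(lo, hi, by = 1e-3)
    x0 <- xs[which.min(vapply(xs, obj, numeric(1L)))]
    xs <- seq(x0 - 2e-3, x0 + 2e-3, by = 1e-6)
    xs[which.min(vapply(xs, obj, numeric(1L)))]
}

## subgradient residual of ||Dx-a||^2 + a1 ||x||_1 + a2 ||Lx||_2^2
enetKKTResidual <- function(D, a, alpha1, alpha2, L, x) {
    grad <- drop(2 * crossprod(D, D %*% x - a) +
                 2 * alpha2 * crossprod(L, L %*% x))
    act <- x != 0
    v <- 0
    if (any(act)) v <- max(abs(grad[act] + alpha1 * sign(x[act])))
    if (any(!act)) v <- max(v, max(pmax(abs(grad[!act]) - alpha1, 0)))
    v
}

## numerical convolution of a causal exponential with a Gaussian IRF
irfConvOracle <- function(t, tau, fwhm, t0) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    vapply(t, function(ti) stats::integrate(
        function(u) exp(-(ti - u) / tau) * stats::dnorm(u, t0, sigma),
        lower = t0 - 13 * sigma, upper = ti, rel.tol = 1e-13)$value,
        numeric(1L))
}
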