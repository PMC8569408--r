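# Independent brute-force oracles, kept deliberately naive: they assemble
# every matrix element-by-element from the definitions and never share code
# with the package's fast paths.

# maximal canonical correlation via the generalized eigenproblem
# (XX')^-1 XY' (YY')^-1 YX' assembled directly from the data matrices
ccaOracle <- function(X, Y) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    m <- ncol(X)
    X <- X - rowMeans(X)
    Y <- Y - rowMeans(Y)
    Sxx <- X %*% t(X) / m
    Syy <- Y %*% t(Y) / m
    Sxy <- X %*% t(Y) / m
    Mx <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
    ev <- eigen(Mx)$values
    sqrt(max(Re(ev)))
}

# S-estimator assembled element-by-element: joint correlation matrix,
# blockwise inverse square roots, whitened matrix, eigenvalue entropy
msiOracle <- function(X, Y) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    m <- ncol(X)
    X <- X - rowMeans(X)
    Y <- Y - rowMeans(Y)
    n <- nrow(X)
    q <- nrow(Y)
    p <- n + q
    Z <- rbind(X, Y)
    C <- matrix(0, p, p)
    for (i in seq_len(p))
        for (j in seq_len(p))
            C[i, j] <- sum(Z[i, ] * Z[j, ]) / m
    invSqrt <- function(A) {
        e <- eigen(A, symmetric = TRUE)
        e$vectors %*% diag(1 / sqrt(e$values), nrow(A)) %*% t(e$vectors)
    }
    U <- matrix(0, p, p)
    U[seq_len(n), seq_len(n)] <- invSqrt(C[seq_len(n), seq_len(n),
                                           drop = FALSE])
    U[n + seq_len(q), n + seq_len(q)] <- invSqrt(C[n + seq_len(q),
                                                   n + seq_len(q),
                                                   drop = FALSE])
    R <- U %*% C %*% t(U)
    lam <- eigen((R + t(R)) / 2, symmetric = TRUE)$values
    lamN <- lam / sum(lam)
    ent <- sum(vapply(lamN, function(l) if (l > 1e-300) l * log(l) else 0,
                      numeric(1)))
    1 + ent / log(p)
}

# random small problem instance: N-channel gaussian signal with a weak
# sinusoidal component so correlations are neither 0 nor 1
randomInstance <- function(n = 2L, nh = 2L, m = 128L, fs = 256,
                           f = sample(c(6, 7.5, 10), 1L),
                           coupling = stats::runif(1, 0, 0.8)) {
    Y <- makeReference(f, nh, fs, m)
    X <- matrix(stats::rnorm(n * m), n, m) +
        coupling * matrix(rep(Y[1L, ], n), n, m, byrow = TRUE)
    list(X = X, Y = Y)
}
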