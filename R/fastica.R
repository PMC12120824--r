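# Deflation-mode FastICA (negentropy maximization, logcosh contrast),
# implemented in-package for the wavelet/ICA correction stage.
#
# Input X is n_obs x p. Columns are centered, the data are whitened through
# the SVD, and K unit-norm projection directions are extracted one at a time
# with Gram-Schmidt deflation. Returns component scores S (n x K) and the
# mixing matrix A (K x p) such that X_centered ~ S %*% A in the retained
# subspace; removing a component set R from X amounts to subtracting
# S[, R] %*% A[R, ], which leaves X untouched when R is empty regardless of
# K. Sign and order of components are indeterminate; downstream scoring uses
# sign-invariant statistics (R^2) only.

.fastICA <- function(x, K, maxit = 200, tol = 1e-6) {
    n <- nrow(x); p <- ncol(x)
    if (K < 1) stop("number of ICA components must be >= 1")
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    sv <- svd(xc, nu = min(n, p), nv = 0)
    pos <- sv$d > max(sv$d[1], 1) * 1e-10
    K <- min(K, sum(pos))
    if (K < 1) {           # rank-zero (constant) matrix: nothing to unmix
        return(list(S = matrix(0, n, 0), A = matrix(0, 0, p),
                    center = ctr, K = 0L))
    }
    Zw <- sv$u[, seq_len(K), drop = FALSE] * sqrt(n)   # whitened, unit var
    W <- matrix(0, K, K)
    for (k in seq_len(K)) {
        w <- stats::rnorm(K)
        w <- w / sqrt(sum(w^2))
        for (it in seq_len(maxit)) {
            wx <- Zw %*% w                 # n x 1 projections
            gwx <- tanh(wx)
            w_new <- colMeans(Zw * as.numeric(gwx)) -
                mean(1 - gwx^2) * w
            if (k > 1) {                   # deflation: orthogonalize
                Wp <- W[seq_len(k - 1), , drop = FALSE]
                w_new <- w_new - as.numeric(crossprod(Wp %*% w_new, Wp))
            }
            nrm <- sqrt(sum(w_new^2))
            if (nrm < 1e-12) { w_new <- stats::rnorm(K); nrm <- sqrt(sum(w_new^2)) }
            w_new <- w_new / nrm
            conv <- abs(abs(sum(w_new * w)) - 1) < tol
            w <- w_new
            if (conv) break
        }
        W[k, ] <- w
    }
    S <- Zw %*% t(W)                       # n x K, uncorrelated scores
    A <- qr.solve(S, xc)                   # K x p least-squares mixing
    list(S = S, A = A, center = ctr, K = K)
}

# R^2 of each column of S explained by a factor (batch dummies)
.batchR2 <- function(S, batch) {
    batch <- factor(batch)
    apply(S, 2, function(s) {
        sst <- sum((s - mean(s))^2)
        if (sst == 0) return(0)
        gm <- tapply(s, batch, mean)
        ssm <- sum(tabulate(batch) * (gm - mean(s))^2)
        min(max(ssm / sst, 0), 1)
    })
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
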