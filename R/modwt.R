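# Maximal-overlap discrete wavelet transform (MODWT), circular boundary.
#
# The MODWT is shift-invariant, defined for any series length (no power-of-2
# requirement), exactly invertible with circular filtering, and satisfies the
# energy decomposition ||x||^2 = sum_j ||W_j||^2 + ||V_J||^2. Implemented
# in-package (pyramid algorithm) for the wavelet/ICA correction stage.

.WAVE_FILTERS <- list(
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
)

.waveFilters <- function(wavelet) {
    g <- .WAVE_FILTERS[[wavelet]]
    if (is.null(g))
        stop("unknown wavelet '", wavelet, "'; available: ",
             paste(names(.WAVE_FILTERS), collapse = ", "))
    L <- length(g)
    h <- rev(g) * (-1)^(seq_len(L) - 1)   # QMF wavelet filter
    # MODWT rescaling
    list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# circular filter with filter upsampled by 2^(j-1):
# out[t] = sum_l f[l] * x[(t - 2^(j-1) * (l-1)) mod N]
.modwtFilt <- function(x, f, j) {
    N <- length(x)
    out <- numeric(N)
    step <- 2^(j - 1)
    t0 <- seq_len(N)
    for (l in seq_along(f)) {
        idx <- ((t0 - 1 - step * (l - 1)) %% N) + 1
        out <- out + f[l] * x[idx]
    }
    out
}

# inverse step: out[t] = sum_l f[l] * x[(t + 2^(j-1) * (l-1)) mod N]
.imodwtFilt <- function(x, f, j) {
    N <- length(x)
    out <- numeric(N)
    step <- 2^(j - 1)
    t0 <- seq_len(N)
    for (l in seq_along(f)) {
        idx <- ((t0 - 1 + step * (l - 1)) %% N) + 1
        out <- out + f[l] * x[idx]
    }
    out
}

# returns list(W = N x J matrix of detail coefficients, V = smooth at level J)
.modwt <- function(x, wavelet = "haar", J = NULL) {
    N <- length(x)
    if (N < 2) stop("series too short for MODWT")
    if (is.null(J)) J <- max(1L, floor(log2(N)))
    flt <- .waveFilters(wavelet)
    W <- matrix(0, N, J)
    V <- x
    for (j in seq_len(J)) {
        W[, j] <- .modwtFilt(V, flt$h, j)
        V <- .modwtFilt(V, flt$g, j)
    }
    list(W = W, V = V, wavelet = wavelet, J = J)
}

.imodwt <- function(dec) {
    flt <- .waveFilters(dec$wavelet)
    V <- dec$V
    for (j in rev(seq_len(dec$J)))
        V <- .imodwtFilt(dec$W[, j], flt$h, j) + .imodwtFilt(V, flt$g, j)
    V
}
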