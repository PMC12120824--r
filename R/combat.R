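#' Empirical-Bayes location-scale batch correction (ComBat-type)
#'
#' Native implementation of the classic empirical-Bayes location-scale batch
#' adjustment for intensity tables, run unsupervised (no biological
#' covariates), as appropriate when QC standards and tissue samples are
#' corrected together in one matrix.
#'
#' Procedure, per feature g on log-transformed intensities
#' `Y = log(x + eps)` with `eps = 0.5 * min positive intensity`:
#' \enumerate{
#'   \item fit grand intercept `alpha_g` and batch deviations `gamma_hat_ig`
#'     by least squares under the weighted constraint
#'     `sum_i n_i gamma_hat_ig = 0`; pooled residual variance `sigma2_g`;
#'   \item standardize `Z = (Y - alpha_g) / sigma_g`;
#'   \item parametric EB: the per-batch moments of `gamma_hat` give a normal
#'     prior `N(gamma_bar_i, tau2_i)`; the per-batch sample variances of `Z`
#'     give inverse-gamma hyperparameters `(lambda_i, theta_i)` by method of
#'     moments;
#'   \item iterate the conditional posterior means
#'     `gamma* = (n tau2 gamma_hat + delta2* gamma_bar) / (n tau2 + delta2*)`
#'     and
#'     `delta2* = (theta + 0.5 sum_j (Z - gamma*)^2) / (n/2 + lambda - 1)`
#'     to convergence (max absolute change < 1e-4, at most 100 iterations);
#'   \item adjust `Y* = sigma_g / delta*_ig * (Z - gamma*_ig) + alpha_g` and
#'     back-transform to the linear scale.
#' }
#'
#' Zero-variance features cannot be standardized and are passed through
#' unchanged with a log entry. A single-batch table has no batch deviations
#' to estimate; the standardize/restore round trip then returns the input
#' (within floating-point error).
#'
#' @param table a \linkS4class{FeatureTable}
#' @param batch_key observation metadata column holding the batch label
#'   (default `"day"`; `"slide_id"` selects slide-level batches)
#' @param parametric only the parametric EB variant is provided; `FALSE`
#'   raises an error
#' @param eps log-transform offset; default `0.5 * min(x[x > 0])`
#' @return a \linkS4class{CorrectionResult} whose model is a
#'   \linkS4class{CombatModel}
#' @references Johnson, Li & Rabinovic (2007) Biostatistics 8:118-127.
#' @export
combatCorrect <- function(table, batch_key = "day", parametric = TRUE,
                          eps = NULL) {
    stopifnot(is(table, "FeatureTable"))
    if (!parametric)
        stop("only the parametric empirical-Bayes variant is implemented")
    om <- obsMeta(table)
    if (!batch_key %in% colnames(om))
        stop("batch key not found in observation metadata: ", batch_key)
    batch <- factor(om[[batch_key]])
    ni <- table(batch)
    if (nlevels(batch) > 1 && any(ni < 2))
        stop("every batch needs >= 2 observations; offending batch(es): ",
             paste(names(ni)[ni < 2], collapse = ", "))
    x <- intensities(table)
    if (is.null(eps)) {
        pos <- x[x > 0]
        eps <- if (length(pos)) 0.5 * min(pos) else 0.5
    }
    y <- t(log(x + eps))                       # features x obs, log scale
    G <- nrow(y); n <- ncol(y); I <- nlevels(batch)
    keep <- apply(y, 1, stats::var) > 0
    skipped <- rownames(y)[!keep]
    logmsg <- character()
    if (length(skipped))
        logmsg <- c(logmsg, paste0("skipped zero-variance feature(s): ",
                                   paste(skipped, collapse = ", ")))
    yk <- y[keep, , drop = FALSE]
    Gk <- nrow(yk)
    if (I == 1L || Gk == 0L) {
        out <- exp(t(y)) - eps
        out[out < 0] <- 0
        model <- new("CombatModel", alpha = numeric(), gammaHat = matrix(0, 0, 0),
                     gammaStar = matrix(0, 0, 0), delta2Hat = matrix(0, 0, 0),
                     delta2Star = matrix(0, 0, 0), sigma2 = numeric(),
                     priors = data.frame(), batchSizes = as.integer(ni),
                     converged = TRUE, iterations = 0L, skipped = skipped,
                     logOffset = eps)
        return(new("CorrectionResult", table = .setIntensities(table, out),
                   model = model, method = "combat", label = "Combat",
                   parameters = list(batch_key = batch_key, eps = eps),
                   log = c(logmsg, "single batch: standardize/restore only")))
    }
    idx <- split(seq_len(n), batch)
    # batch means per feature, weighted grand mean (LS under sum n_i gamma = 0)
    M <- matrix(0, Gk, I)                      # Gk x I batch means
    for (i in seq_len(I)) M[, i] <- rowMeans(yk[, idx[[i]], drop = FALSE])
    w <- as.numeric(ni) / n
    alpha <- as.numeric(M %*% w)
    sigma2 <- rowSums((yk - M[, as.integer(batch), drop = FALSE])^2) / n
    if (any(sigma2 == 0)) {
        # residual variance zero: feature constant within every batch
        zi <- sigma2 == 0
        skipped <- c(skipped, rownames(yk)[zi])
        logmsg <- c(logmsg, paste0("skipped feature(s) with zero residual ",
                                   "variance: ",
                                   paste(rownames(yk)[zi], collapse = ", ")))
        yk <- yk[!zi, , drop = FALSE]
        M <- M[!zi, , drop = FALSE]
        alpha <- alpha[!zi]
        sigma2 <- sigma2[!zi]
        Gk <- nrow(yk)
    }
    Z <- (yk - alpha) / sqrt(sigma2)
    gamma_hat <- delta2_hat <- matrix(0, Gk, I)
    for (i in seq_len(I)) {
        Zi <- Z[, idx[[i]], drop = FALSE]
        gamma_hat[, i] <- rowMeans(Zi)
        delta2_hat[, i] <- rowSums((Zi - gamma_hat[, i])^2) /
            (length(idx[[i]]) - 1)
    }
    gamma_bar <- colMeans(gamma_hat)
    tau2 <- apply(gamma_hat, 2, stats::var)
    m_d <- colMeans(delta2_hat)
    s2_d <- apply(delta2_hat, 2, stats::var)
    s2_d[!is.finite(s2_d) | s2_d < 1e-12] <- 1e-12  # degenerate prior guard
    lambda <- (2 * s2_d + m_d^2) / s2_d        # inverse-gamma shape (MoM)
    theta <- (m_d * s2_d + m_d^3) / s2_d       # inverse-gamma rate  (MoM)
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    iters <- 0L
    converged <- FALSE
    for (it in seq_len(100L)) {
        g_old <- gamma_star; d_old <- delta2_star
        for (i in seq_len(I)) {
            nb <- as.numeric(ni[i])
            gamma_star[, i] <- (nb * tau2[i] * gamma_hat[, i] +
                                delta2_star[, i] * gamma_bar[i]) /
                               (nb * tau2[i] + delta2_star[, i])
            Zi <- Z[, idx[[i]], drop = FALSE]
            ss <- rowSums((Zi - gamma_star[, i])^2)
            delta2_star[, i] <- (theta[i] + 0.5 * ss) /
                                (nb / 2 + lambda[i] - 1)
        }
        iters <- it
        if (max(abs(gamma_star - g_old), abs(delta2_star - d_old)) < 1e-4) {
            converged <- TRUE
            break
        }
    }
    bidx <- as.integer(batch)
    Zadj <- (Z - gamma_star[, bidx, drop = FALSE]) /
            sqrt(delta2_star[, bidx, drop = FALSE])
    yk_adj <- Zadj * sqrt(sigma2) + alpha
    y_out <- y
    y_out[rownames(yk), ] <- yk_adj
    out <- exp(t(y_out)) - eps
    out[out < 0] <- 0
    dimnames(gamma_hat) <- dimnames(gamma_star) <-
        dimnames(delta2_hat) <- dimnames(delta2_star) <-
        list(rownames(yk), levels(batch))
    model <- new("CombatModel",
                 alpha = stats::setNames(alpha, rownames(yk)),
                 gammaHat = gamma_hat, gammaStar = gamma_star,
                 delta2Hat = delta2_hat, delta2Star = delta2_star,
                 sigma2 = stats::setNames(sigma2, rownames(yk)),
                 priors = data.frame(batch = levels(batch),
                                     gamma.bar = gamma_bar, tau2 = tau2,
                                     lambda.bar = lambda, theta.bar = theta,
                                     row.names = NULL),
                 batchSizes = as.integer(ni), converged = converged,
                 iterations = iters, skipped = skipped, logOffset = eps)
    new("CorrectionResult", table = .setIntensities(table, out),
        model = model, method = "combat", label = "Combat",
        parameters = list(batch_key = batch_key, eps = eps,
                          parametric = TRUE),
        log = c(logmsg,
                sprintf("EB iteration %s after %d iterations",
                        if (converged) "converged" else "did not converge",
                        iters)))
}

# one EB shrinkage step for a single batch (exposed for numerical checks of
# the shrinkage limits: tau2 -> Inf gives gamma_hat, tau2 -> 0 gives gamma_bar)
.combatShrinkGamma <- function(gamma_hat, delta2_star, n, gamma_bar, tau2) {
    (n * tau2 * gamma_hat + delta2_star * gamma_bar) /
        (n * tau2 + delta2_star)
}
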