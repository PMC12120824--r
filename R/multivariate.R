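#' Principal component analysis with centering and scaling
#'
#' PCA via singular value decomposition of the column-centered (and, by
#' default, unit-variance-scaled) data. Zero-variance features are dropped
#' before scaling (with a message). Component signs are made deterministic by
#' flipping each component so its largest-magnitude loading is positive.
#'
#' @param x numeric matrix (observations x features) or
#'   \linkS4class{FeatureTable}
#' @param n_components number of components to keep (default
#'   `min(n_obs - 1, n_feat)`)
#' @param center,scale centering/unit-variance scaling (default both TRUE)
#' @return a \linkS4class{PCAResult}
#' @export
pcaScores <- function(x, n_components = NULL, center = TRUE, scale = TRUE) {
    if (is(x, "FeatureTable")) x <- intensities(x)
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("need at least 2 observations for PCA")
    dropped <- character()
    if (scale) {
        v <- apply(x, 2, stats::var)
        zero <- v == 0
        if (any(zero)) {
            dropped <- colnames(x)[zero]
            if (is.null(dropped)) dropped <- as.character(which(zero))
            message("dropping ", sum(zero),
                    " zero-variance feature(s) before scaling")
            x <- x[, !zero, drop = FALSE]
        }
    }
    maxcomp <- min(nrow(x) - 1L, ncol(x))
    if (is.null(n_components)) n_components <- maxcomp
    if (n_components > maxcomp)
        stop("n_components (", n_components, ") exceeds min(n_obs - 1, n_feat) = ",
             maxcomp)
    pc <- stats::prcomp(x, center = center, scale. = scale)
    A <- n_components
    load <- pc$rotation[, seq_len(A), drop = FALSE]
    scores <- pc$x[, seq_len(A), drop = FALSE]
    for (a in seq_len(A)) {                       # deterministic signs
        i <- which.max(abs(load[, a]))
        if (load[i, a] < 0) {
            load[, a] <- -load[, a]
            scores[, a] <- -scores[, a]
        }
    }
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    ctr <- if (isTRUE(center)) pc$center else rep(0, ncol(x))
    scl <- if (isTRUE(scale)) pc$scale else rep(1, ncol(x))
    new("PCAResult", scores = scores, loadings = load,
        explained = expl[seq_len(A)], center = unname(ctr),
        scale = unname(scl), dropped = dropped)
}

.scoreMatrix <- function(scores) {
    if (is(scores, "PCAResult")) scores <- scores@scores
    scores <- as.matrix(scores)
    if (ncol(scores) < 2)
        stop("need at least 2 score components (PC1-PC2)")
    scores[, 1:2, drop = FALSE]
}

#' Intragroup distance in PC1-PC2 score space
#'
#' Average straight-line (Euclidean) distance of each sample point from its
#' group centroid, using the first and second principal component only; the
#' grand average is the mean of the per-group means. Smaller values indicate
#' tighter within-group proximity.
#'
#' @param scores \linkS4class{PCAResult} or score matrix (>= 2 columns)
#' @param group_labels one label per observation
#' @return list with `per_group` (named numeric) and `average`
#' @export
intragroupDistance <- function(scores, group_labels) {
    s <- .scoreMatrix(scores)
    g <- as.character(group_labels)
    if (length(g) != nrow(s)) stop("one group label per observation required")
    per <- vapply(unique(g), function(gr) {
        pts <- s[g == gr, , drop = FALSE]
        ctr <- colMeans(pts)
        mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
    }, 0)
    list(per_group = per, average = mean(per))
}

#' Intergroup centroid distances in PC1-PC2 score space
#'
#' Euclidean distances between group centroids in the first two principal
#' components, averaged over all k(k-1)/2 pairs. Larger values indicate a
#' more distinctive separation between sample types.
#'
#' @inheritParams intragroupDistance
#' @return list with `pairwise` (dist object) and `average`
#' @export
intergroupDistance <- function(scores, group_labels) {
    s <- .scoreMatrix(scores)
    g <- as.character(group_labels)
    if (length(g) != nrow(s)) stop("one group label per observation required")
    groups <- unique(g)
    if (length(groups) < 2) stop("need at least 2 groups")
    ctr <- t(vapply(groups, function(gr)
        colMeans(s[g == gr, , drop = FALSE]), numeric(2)))
    d <- stats::dist(ctr)
    list(pairwise = d, average = mean(d))
}

#' QCS proximity in PCA score space, per method
#'
#' For each corrected table, fits a centered+scaled PCA on the combined
#' QCS+tissue table (all detected features) and reports the mean distance of
#' the QCS spots from their common centroid in PC1-PC2 - the "distance in
#' PCA" column of a method-comparison table. All QCS spots are treated as a
#' single group; the smaller the distance, the better the correction pulled
#' replicate standards together.
#'
#' @param corrected_tables named list of \linkS4class{FeatureTable} or
#'   \linkS4class{CorrectionResult}
#' @return named numeric vector of distances, one per method
#' @export
qcsProximity <- function(corrected_tables) {
    if (is(corrected_tables, "FeatureTable") ||
        is(corrected_tables, "CorrectionResult"))
        corrected_tables <- list(corrected_tables)
    vapply(corrected_tables, function(tb) {
        if (is(tb, "CorrectionResult")) tb <- tb@table
        om <- obsMeta(tb)
        if (!any(om$region_type == "qcs"))
            stop("table contains no QCS observations")
        pc <- pcaScores(tb, n_components = 2)
        qcs_scores <- pc@scores[om$region_type == "qcs", , drop = FALSE]
        intragroupDistance(qcs_scores, rep("qcs", nrow(qcs_scores)))$average
    }, 0)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Partial least-squares discriminant analysis by NIPALS PLS2 on autoscaled
#' features against a one-hot (centered) group-membership response, with
#' per-feature VIP scores
#' `VIP_j = sqrt( p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a )`
#' where `SS_a` is the response variance explained by component a. Features
#' with VIP above the threshold (default 1.2) are selected as distinctive.
#' By the formula, the mean squared VIP is exactly 1.
#'
#' @param x matrix (observations x features) or \linkS4class{FeatureTable}
#'   (tissue observations are used when region metadata is present)
#' @param group_labels one class label per observation (>= 2 classes, each
#'   with >= 2 observations)
#' @param n_components PLS components; default `n_groups - 1`, capped at the
#'   data rank
#' @param threshold VIP selection threshold (default 1.2)
#' @return a \linkS4class{VIPResult}
#' @export
plsdaVIP <- function(x, group_labels = NULL, n_components = NULL,
                     threshold = 1.2) {
    if (is(x, "FeatureTable")) {
        om <- obsMeta(x)
        tis <- om$region_type == "tissue"
        if (any(tis)) {
            if (is.null(group_labels)) group_labels <- om$group[tis]
            x <- intensities(x)[tis, , drop = FALSE]
        } else {
            if (is.null(group_labels)) group_labels <- om$group
            x <- intensities(x)
        }
    }
    x <- as.matrix(x)
    g <- factor(as.character(group_labels))
    if (nlevels(g) < 2) stop("need at least 2 groups for PLS-DA")
    if (any(table(g) < 2)) stop("every group needs >= 2 observations")
    if (length(g) != nrow(x)) stop("one group label per observation required")
    v <- apply(x, 2, stats::var)
    keep <- v > 0
    if (any(!keep))
        message("dropping ", sum(!keep),
                " zero-variance feature(s) before autoscaling")
    ids <- colnames(x)
    if (is.null(ids)) ids <- paste0("f", seq_len(ncol(x)))
    X <- scale(x[, keep, drop = FALSE])            # autoscale
    Y <- scale(stats::model.matrix(~ g - 1), scale = FALSE)  # centered one-hot
    p <- ncol(X)
    maxA <- min(nrow(X) - 1L, p)
    A <- if (is.null(n_components)) min(nlevels(g) - 1L, maxA) else n_components
    if (A > maxA)
        stop("n_components (", A, ") exceeds the data rank bound ", maxA)
    Wmat <- matrix(0, p, A)
    ssY <- numeric(A)
    E <- X; F_ <- Y
    for (a in seq_len(A)) {
        u <- F_[, which.max(apply(F_, 2, stats::var))]
        t_old <- rep(Inf, nrow(E))
        for (it in seq_len(500)) {
            w <- crossprod(E, u)
            w <- w / sqrt(sum(w^2))
            t_ <- E %*% w
            q <- crossprod(F_, t_) / sum(t_^2)
            u <- F_ %*% q / sum(q^2)
            if (sqrt(sum((t_ - t_old)^2)) < 1e-10 * sqrt(sum(t_^2))) break
            t_old <- t_
        }
        pl <- crossprod(E, t_) / sum(t_^2)
        b <- sum(u * t_) / sum(t_^2)
        ssY[a] <- sum((t_ %*% t(q) * b)^2)         # explained response SS
        E <- E - t_ %*% t(pl)
        F_ <- F_ - b * t_ %*% t(q)
        Wmat[, a] <- w
    }
    vip <- stats::setNames(sqrt(p * as.numeric(Wmat^2 %*% ssY) / sum(ssY)),
                           ids[keep])
    sel <- names(vip)[vip > threshold]
    new("VIPResult", vip = vip, ncomp = as.integer(A),
        threshold = threshold, selected = sel, explainedY = ssY)
}

#' Feature-robustness comparison across correction methods
#'
#' Crosses the VIP selections of several methods over an identical feature
#' set: the robust set contains features selected as distinctive under every
#' method (correction-invariant markers); the dropped set contains features
#' selected without correction (`raw`) but under none of the corrected
#' methods (raw-only hits, candidate batch artifacts).
#'
#' @param vip_results_by_method named list of \linkS4class{VIPResult}
#' @param threshold selection threshold re-applied to the stored VIP scores
#' @param raw_label name of the uncorrected entry (default `"raw"`)
#' @return list with `grid` (feature x method logical data.frame), `robust`,
#'   `dropped`
#' @export
robustFeatureComparison <- function(vip_results_by_method, threshold = 1.2,
                                    raw_label = "raw") {
    stopifnot(length(vip_results_by_method) >= 2)
    feats <- names(vip_results_by_method[[1]]@vip)
    for (v in vip_results_by_method)
        if (!identical(names(v@vip), feats))
            stop("VIP results cover mismatched feature sets")
    grid <- as.data.frame(lapply(vip_results_by_method,
                                 function(v) v@vip > threshold),
                          row.names = feats, check.names = FALSE)
    robust <- feats[apply(as.matrix(grid), 1, all)]
    dropped <- character()
    if (raw_label %in% colnames(grid)) {
        corr <- as.matrix(grid[, setdiff(colnames(grid), raw_label),
                               drop = FALSE])
        dropped <- feats[grid[[raw_label]] & !apply(corr, 1, any)]
    }
    list(grid = grid, robust = robust, dropped = dropped)
}
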