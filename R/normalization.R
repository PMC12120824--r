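#' TIC normalization
#'
#' Divides each observation's feature abundances by the observation's total
#' ion count (the sum over all feature columns of the supplied table), so
#' that every row sums to 1. The TIC sum is scoped to the table passed in:
#' to TIC-normalize QCS spots against the QCS-region export, pass the
#' QCS-region table. TIC is a ratio correction: it cancels any multiplicative
#' factor shared by all features of an observation, and it is idempotent.
#'
#' @param table a \linkS4class{FeatureTable} with strictly positive row sums
#' @return a \linkS4class{FeatureTable} with provenance `"tic"`
#' @export
ticNormalize <- function(table) {
    stopifnot(is(table, "FeatureTable"))
    m <- intensities(table)
    s <- rowSums(m)
    bad <- which(s <= 0)
    if (length(bad))
        stop("zero-sum observation(s), TIC undefined: ",
             paste(rownames(m)[bad], collapse = ", "))
    .setIntensities(table, m / s, provenance = "tic")
}

#' Internal-standard normalization
#'
#' Replaces the analyte column by the per-observation ratio
#' analyte / internal standard (e.g. propranolol / propranolol-d7). Because
#' the isotope-labelled standard is co-deposited and co-measured, any
#' multiplicative artifact shared by the pair (matrix spraying, ionization
#' efficiency, detector response, slide and day effects) cancels exactly in
#' the ratio. All other columns are left untouched; the transform is only
#' applied to the declared analyte, not to endogenous tissue features.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param analyte_feat analyte feature id (default: the feature with role
#'   `analyte`)
#' @param is_feat internal-standard feature id (default: the feature with
#'   role `internal_standard`)
#' @return a \linkS4class{FeatureTable} with provenance `"is"`; the analyte
#'   column now holds the dimensionless ratio
#' @export
isNormalize <- function(table, analyte_feat = NULL, is_feat = NULL) {
    stopifnot(is(table, "FeatureTable"))
    fm <- featMeta(table)
    if (is.null(analyte_feat))
        analyte_feat <- fm$feat_id[fm$role == "analyte"][1]
    if (is.null(is_feat))
        is_feat <- fm$feat_id[fm$role == "internal_standard"][1]
    if (is.na(analyte_feat) || is.null(analyte_feat) ||
        !analyte_feat %in% fm$feat_id)
        stop("analyte feature not found in table")
    if (is.na(is_feat) || is.null(is_feat) || !is_feat %in% fm$feat_id)
        stop("internal-standard feature not found in table")
    m <- intensities(table)
    is_vals <- m[, is_feat]
    zero <- which(is_vals <= 0)
    if (length(zero))
        stop("internal-standard intensity is zero for observation(s): ",
             paste(rownames(m)[zero], collapse = ", "))
    m[, analyte_feat] <- m[, analyte_feat] / is_vals
    out <- .setIntensities(table, m, provenance = "is")
    metadata(out)$is_pair <- c(analyte = analyte_feat,
                               internal_standard = is_feat)
    out
}

#' Z-score values per feature across the whole experiment
#'
#' Centers and scales to unit sample standard deviation (n - 1), pooling all
#' observations of a feature across slides and days. Pooled scoring keeps
#' slide-level shifts visible when the z-scores are plotted per slide, which
#' is the point of the violin-plot display. For a numeric vector the whole
#' vector is one scored set; for a \linkS4class{FeatureTable} every feature
#' column is scored independently and a plain matrix is returned (z-scores
#' are a display transform, not a normalization mode, so no FeatureTable is
#' produced).
#'
#' @param x numeric vector or \linkS4class{FeatureTable}
#' @return numeric vector, or observations x features matrix of z-scores
#' @export
setGeneric("zscoreByFeature", function(x) standardGeneric("zscoreByFeature"))

#' @rdname zscoreByFeature
#' @export
setMethod("zscoreByFeature", "numeric", function(x) {
    if (length(x) < 2) stop("need at least 2 values to z-score")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
        stop("zero spread: cannot z-score a constant set")
    (x - mean(x)) / s
})

#' @rdname zscoreByFeature
#' @export
setMethod("zscoreByFeature", "FeatureTable", function(x) {
    m <- intensities(x)
    s <- apply(m, 2, stats::sd)
    zero <- which(s == 0 | !is.finite(s))
    if (length(zero))
        stop("zero spread: cannot z-score feature(s): ",
             paste(colnames(m)[zero], collapse = ", "))
    scale(m, center = TRUE, scale = s)[, , drop = FALSE]
})
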