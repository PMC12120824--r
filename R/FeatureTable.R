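#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, observations x features (the orientation
#'   of the wide CSV format). Row names are taken as obs ids and column names
#'   as feature ids when `obs_meta`/`feat_meta` do not provide them.
#' @param obs_meta data.frame with columns `obs_id`, `slide_id`, `day`,
#'   `measurement_order`, `region_type`, `group` and optionally `row_id`.
#' @param feat_meta data.frame with columns `feat_id`, `mz`, `role`; when
#'   omitted, `mz` is parsed from ids of the form `mz123.45` and all roles
#'   default to `tissue_feature`.
#' @param provenance normalization provenance tag: `raw`, `tic` or `is`.
#' @param is_pair optional character(2): analyte and internal-standard feature
#'   ids (recorded for `is`-normalized tables).
#' @return a \linkS4class{FeatureTable}
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("o", 1:3), c("mz100", "mz260")))
#' om <- data.frame(obs_id = rownames(m), slide_id = "S01", day = "d1",
#'                  measurement_order = 1:3, region_type = "qcs", group = "")
#' ft <- FeatureTable(m, om)
#' @export
FeatureTable <- function(intensities, obs_meta, feat_meta = NULL,
                         provenance = c("raw", "tic", "is"), is_pair = NULL) {
    provenance <- match.arg(provenance)
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    if (is.null(rownames(intensities)))
        rownames(intensities) <- obs_meta$obs_id
    obs_meta <- as.data.frame(obs_meta)
    if (!"obs_id" %in% colnames(obs_meta))
        stop("obs_meta must contain an obs_id column")
    if (!"row_id" %in% colnames(obs_meta))
        obs_meta[["row_id"]] <- rep(NA_character_, nrow(obs_meta))
    if (nrow(obs_meta) != nrow(intensities))
        stop("intensities must have exactly one row per obs_meta record")
    if (is.null(feat_meta)) {
        ids <- colnames(intensities)
        if (is.null(ids)) stop("feature ids missing (no colnames, no feat_meta)")
        feat_meta <- data.frame(feat_id = ids, mz = .parseMz(ids),
                                role = "tissue_feature",
                                stringsAsFactors = FALSE)
    }
    feat_meta <- as.data.frame(feat_meta)
    if (!"feat_id" %in% colnames(feat_meta))
        stop("feat_meta must contain a feat_id column")
    if (!"mz" %in% colnames(feat_meta)) feat_meta$mz <- .parseMz(feat_meta$feat_id)
    if (!"role" %in% colnames(feat_meta)) feat_meta$role <- "tissue_feature"
    if (nrow(feat_meta) != ncol(intensities))
        stop("intensities must have exactly one column per feat_meta record")
    if (anyDuplicated(obs_meta$obs_id))
        stop("duplicate obs_id: ",
             paste(unique(obs_meta$obs_id[duplicated(obs_meta$obs_id)]),
                   collapse = ", "))
    if (anyDuplicated(feat_meta$feat_id))
        stop("duplicate feat_id: ",
             paste(unique(feat_meta$feat_id[duplicated(feat_meta$feat_id)]),
                   collapse = ", "))
    ns <- sum(feat_meta$role == "internal_standard")
    if (ns > 1)
        stop("at most one internal_standard feature is supported per table")
    a <- t(intensities)
    rownames(a) <- feat_meta$feat_id
    colnames(a) <- obs_meta$obs_id
    cd <- DataFrame(obs_meta[setdiff(colnames(obs_meta), "obs_id")],
                    row.names = obs_meta$obs_id)
    cd$measurement_order <- as.integer(cd$measurement_order)
    rd <- DataFrame(feat_meta[setdiff(colnames(feat_meta), "feat_id")],
                    row.names = feat_meta$feat_id)
    md <- list(provenance = provenance, is_pair = is_pair)
    se <- SummarizedExperiment(assays = list(intensities = a),
                               colData = cd, rowData = rd, metadata = md)
    new("FeatureTable", se)
}

.parseMz <- function(ids) {
    mz <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", ids)))
    mz[!is.na(mz) & mz <= 0] <- NA_real_
    mz
}

#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Accessors for FeatureTable
#'
#' `intensities` returns the observations-by-features matrix; `obsMeta` and
#' `featMeta` return the metadata as plain data.frames (with `obs_id` /
#' `feat_id` columns); `provenance` returns the normalization tag.
#'
#' @param x a \linkS4class{FeatureTable}
#' @return matrix or data.frame or character, see above.
#' @aliases intensities obsMeta featMeta provenance
#' @name intensities
#' @export
setMethod("intensities", "FeatureTable", function(x)
    t(assay(x, "intensities")))

#' @rdname intensities
#' @export
setGeneric("obsMeta", function(x) standardGeneric("obsMeta"))

#' @rdname intensities
#' @export
setMethod("obsMeta", "FeatureTable", function(x) {
    d <- as.data.frame(colData(x))
    cbind(data.frame(obs_id = colnames(x), stringsAsFactors = FALSE), d,
          row.names = NULL)
})

#' @rdname intensities
#' @export
setGeneric("featMeta", function(x) standardGeneric("featMeta"))

#' @rdname intensities
#' @export
setMethod("featMeta", "FeatureTable", function(x) {
    d <- as.data.frame(rowData(x))
    cbind(data.frame(feat_id = rownames(x), stringsAsFactors = FALSE), d,
          row.names = NULL)
})

#' @rdname intensities
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname intensities
#' @export
setMethod("provenance", "FeatureTable", function(x)
    metadata(x)$provenance)

# replace the intensity matrix (obs x feat orientation), keeping metadata
.setIntensities <- function(ft, m, provenance = NULL) {
    a <- t(m)
    dimnames(a) <- dimnames(assay(ft, "intensities"))
    assays(ft)[["intensities"]] <- a
    if (!is.null(provenance)) metadata(ft)$provenance <- provenance
    validObject(ft)
    ft
}

#' Subset a FeatureTable to one region type
#'
#' @param x a \linkS4class{FeatureTable}
#' @param region `"qcs"` or `"tissue"`
#' @return the subset \linkS4class{FeatureTable}
#' @export
subsetRegion <- function(x, region = c("qcs", "tissue")) {
    region <- match.arg(region)
    x[, colData(x)$region_type == region]
}

#' @importFrom utils head
setMethod("show", "FeatureTable", function(object) {
    cd <- colData(object)
    cat("FeatureTable:", ncol(object), "observations x", nrow(object),
        "features\n")
    cat("  provenance:", metadata(object)$provenance, "\n")
    cat("  regions:", paste(sprintf("%s (%d)", names(table(cd$region_type)),
                                    table(cd$region_type)), collapse = ", "),
        "\n")
    cat("  slides:", length(unique(cd$slide_id)),
        " days:", length(unique(cd$day)), "\n")
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport for analyte", object@analyte,
        sprintf("[%s]\n", object@method))
    cat("  interday CV%:", round(object@interday, 2), "\n")
    cat("  intraday CV%:",
        paste(sprintf("%s=%.2f", object@intraday$day, object@intraday$cv),
              collapse = ", "), "\n")
    fl <- object@outliers$slide_id[object@outliers$flagged]
    cat("  outlier slides:",
        if (length(fl)) paste(fl, collapse = ", ") else "none", "\n")
})

setMethod("show", "CorrectionResult", function(object) {
    cat("CorrectionResult:", object@label, "\n")
    cat("  method:", object@method, " corrected table:",
        ncol(object@table), "obs x", nrow(object@table), "features\n")
    if (length(object@log))
        cat("  log:", paste(head(object@log, 3), collapse = "; "), "\n")
})

setMethod("show", "CombatModel", function(object) {
    cat("CombatModel:", length(object@batchSizes), "batches,",
        length(object@alpha), "features; converged:",
        object@converged, sprintf("(%d iterations)\n", object@iterations))
})

setMethod("show", "WaveICAModel", function(object) {
    rem <- sum(vapply(object@components, function(l) length(l$removed), 1L))
    cat("WaveICAModel:", object@wavelet, "wavelet,", object@levels,
        "levels + smooth, K =", object@K, "; removed", rem,
        "components (R2 >=", object@tThreshold, ")\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@slideEffects), "slides,",
        length(object@dayEffects), "days,",
        sum(object@driftSlopes != 0), "drifting features,",
        nrow(object@markers), "group markers\n")
})

setMethod("show", "ComparisonReport", function(object) {
    cat("ComparisonReport:", nrow(object@grid), "methods\n")
    print(object@grid, digits = 4)
    cat("robust features:", length(object@robustFeatures),
        " dropped after correction:", length(object@droppedFeatures), "\n")
})
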