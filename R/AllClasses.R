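#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- colData rowData
NULL

.REGION_LEVELS <- c("qcs", "tissue")
.ROLE_LEVELS <- c("analyte", "internal_standard", "tissue_feature")
.OBS_META_COLS <- c("obs_id", "slide_id", "day", "measurement_order",
                    "region_type", "group", "row_id")

#' FeatureTable: observations-by-features intensity table
#'
#' The single data currency of the package: a peak-intensity matrix for a set
#' of measured regions (QCS spots and tissue sections) with observation
#' metadata (slide, day, acquisition order, region type, tissue group) and
#' feature metadata (m/z, role). Implemented as a
#' \linkS4class{SummarizedExperiment} with features as rows and observations
#' as columns; the user-facing accessor \code{\link{intensities}} returns the
#' matrix in the observations-by-features orientation used by the wide CSV
#' interchange format.
#'
#' Invariants enforced by the validity method: all intensities are finite and
#' non-negative (missing values are rejected), observation and feature ids are
#' unique, \code{measurement_order} is a unique positive integer per
#' observation, \code{region_type} is one of \code{qcs}/\code{tissue}, and
#' feature roles are one of \code{analyte}/\code{internal_standard}/
#' \code{tissue_feature}.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!("intensities" %in% names(assays(object))))
        return("assay 'intensities' is missing")
    x <- assay(object, "intensities")
    if (!is.numeric(x))
        msg <- c(msg, "intensities must be numeric")
    if (anyNA(x))
        msg <- c(msg, "intensities contain missing values")
    else if (any(!is.finite(x)))
        msg <- c(msg, "intensities contain non-finite values")
    else if (any(x < 0))
        msg <- c(msg, "intensities contain negative values")
    cd <- colData(object)
    need <- setdiff(c("slide_id", "day", "measurement_order", "region_type",
                      "group"), colnames(cd))
    if (length(need))
        msg <- c(msg, paste0("missing observation metadata column(s): ",
                             paste(need, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "obs_id (colnames) must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feat_id (rownames) must be present and unique")
    if ("measurement_order" %in% colnames(cd)) {
        mo <- cd$measurement_order
        if (anyNA(mo) || any(mo < 1) || any(mo != round(mo)))
            msg <- c(msg, "measurement_order must be positive integers")
        if (anyDuplicated(mo))
            msg <- c(msg, "measurement_order must be unique within the table")
    }
    if ("region_type" %in% colnames(cd) &&
        !all(cd$region_type %in% .REGION_LEVELS))
        msg <- c(msg, paste0("region_type must be one of: ",
                             paste(.REGION_LEVELS, collapse = ", ")))
    rd <- rowData(object)
    if ("role" %in% colnames(rd) && !all(rd$role %in% .ROLE_LEVELS))
        msg <- c(msg, paste0("feature role must be one of: ",
                             paste(.ROLE_LEVELS, collapse = ", ")))
    if ("mz" %in% colnames(rd)) {
        mz <- rd$mz
        if (any(!is.na(mz) & mz <= 0))
            msg <- c(msg, "mz must be positive where given")
    }
    if (length(msg)) msg else TRUE
})

#' QC evaluation report for a feature table
#'
#' Machine twin of a per-method QC summary row: pooled intraday and interday
#' CV\% of the monitored QCS analyte, per-slide (and per-row, when a row
#' layout is present) CV\%, Kruskal-Wallis batch-difference tests, robust
#' outlier-slide flags, and an acquisition-drift profile.
#'
#' @slot analyte feature id of the monitored analyte
#' @slot method label of the normalization/correction method evaluated
#' @slot intraday data.frame with day, n and cv columns (cv may be NA with a note)
#' @slot interday pooled interday CV\% (single number)
#' @slot perSlide data.frame with slide_id, day, n, cv
#' @slot perRow data.frame with slide_id, row_id, n, cv (0 rows when no row layout)
#' @slot tests data.frame of Kruskal-Wallis results (scope, statistic, p.value)
#' @slot outliers data.frame from \code{\link{detectOutlierSlides}}
#' @slot drift list from \code{\link{driftProfile}}
#' @export
setClass("QCReport", representation(
    analyte = "character", method = "character",
    intraday = "data.frame", interday = "numeric",
    perSlide = "data.frame", perRow = "data.frame",
    tests = "data.frame", outliers = "data.frame", drift = "list"))

setValidity("QCReport", function(object) {
    msg <- character()
    cv <- c(object@intraday$cv, object@interday, object@perSlide$cv)
    if (any(!is.na(cv) & cv < 0)) msg <- c(msg, "CV% must be >= 0")
    p <- object@tests$p.value
    if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Fitted empirical-Bayes location-scale (ComBat-type) batch model
#'
#' @slot alpha per-feature grand intercept on the log scale
#' @slot gammaHat,gammaStar per-(batch, feature) estimated and EB-shrunk location
#' @slot delta2Hat,delta2Star per-(batch, feature) estimated and EB-shrunk scale
#' @slot sigma2 per-feature pooled variance of the log data
#' @slot priors per-batch hyperparameters (gamma.bar, tau2, lambda.bar, theta.bar)
#' @slot batchSizes observations per batch
#' @slot converged,iterations EB iteration diagnostics
#' @slot skipped ids of zero-variance features passed through unchanged
#' @slot logOffset offset used in the log transform
#' @export
setClass("CombatModel", representation(
    alpha = "numeric", gammaHat = "matrix", gammaStar = "matrix",
    delta2Hat = "matrix", delta2Star = "matrix", sigma2 = "numeric",
    priors = "data.frame", batchSizes = "integer", converged = "logical",
    iterations = "integer", skipped = "character", logOffset = "numeric"))

setValidity("CombatModel", function(object) {
    if (length(object@delta2Star) && any(object@delta2Star <= 0))
        "EB-shrunk scale parameters must be positive" else TRUE
})

#' Fitted wavelet/ICA (WaveICA-type) drift and batch model
#'
#' @slot wavelet wavelet filter name
#' @slot levels number of decomposition levels J
#' @slot K independent components extracted per level
#' @slot tThreshold batch-association R-squared removal threshold
#' @slot components per-level list: component scores, mixing matrix,
#'   per-component batch R-squared, removed component indices
#' @slot seed RNG seed used for ICA initialisation
#' @slot logOffset offset used in the log transform
#' @export
setClass("WaveICAModel", representation(
    wavelet = "character", levels = "integer", K = "integer",
    tThreshold = "numeric", components = "list", seed = "integer",
    logOffset = "numeric"))

setValidity("WaveICAModel", function(object) {
    r2 <- unlist(lapply(object@components, `[[`, "r2"))
    if (length(r2) && any(r2 < -1e-8 | r2 > 1 + 1e-8))
        "component batch R-squared must lie in [0, 1]" else TRUE
})

#' Result of one batch-correction run
#'
#' @slot table corrected \linkS4class{FeatureTable} (same shape and ids as input)
#' @slot model fitted model object (\linkS4class{CombatModel},
#'   \linkS4class{WaveICAModel}, or NULL for pass-through methods)
#' @slot method registered method name
#' @slot label display label (e.g. "TIC + Combat")
#' @slot parameters method parameters used
#' @slot log character vector of decisions (skipped features, removed components)
#' @export
setClass("CorrectionResult", representation(
    table = "FeatureTable", model = "ANY", method = "character",
    label = "character", parameters = "list", log = "character"))

#' Ground truth of a simulated batch experiment
#'
#' @slot slideEffects realized per-slide log-scale effects b_s
#' @slot dayEffects realized per-day log-scale effects c_d
#' @slot sprayFactors realized per-observation log-scale spray/suppression
#'   factors v_o (shared by all features of an observation)
#' @slot driftSlopes per-feature log-scale drift slopes (per order unit)
#' @slot outlierOffsets per-slide log-scale attenuation of designated outliers
#' @slot markers data.frame of group-marker features and log effect sizes
#' @slot config the \code{\link{simulationConfig}} used
#' @slot seed RNG seed
#' @export
setClass("SyntheticTruth", representation(
    slideEffects = "numeric", dayEffects = "numeric",
    sprayFactors = "numeric",
    driftSlopes = "numeric", outlierOffsets = "numeric",
    markers = "data.frame", config = "list", seed = "integer"))

#' Principal component analysis result
#'
#' @slot scores n_obs x A score matrix
#' @slot loadings feature loading matrix with a deterministic sign convention
#' @slot explained per-component explained-variance fractions (non-increasing)
#' @slot center,scale centering/scaling vectors applied to the features
#' @slot dropped ids of zero-variance features dropped before scaling
#' @export
setClass("PCAResult", representation(
    scores = "matrix", loadings = "matrix", explained = "numeric",
    center = "numeric", scale = "numeric", dropped = "character"))

setValidity("PCAResult", function(object) {
    e <- object@explained
    if (length(e) > 1 && any(diff(e) > 1e-10))
        "explained variance must be non-increasing" else TRUE
})

#' PLS-DA variable-importance-in-projection result
#'
#' @slot vip per-feature VIP scores (mean of squared scores is 1)
#' @slot ncomp number of PLS components used
#' @slot threshold selection threshold (default 1.2)
#' @slot selected feature ids with VIP above the threshold
#' @slot explainedY per-component explained response variance
#' @export
setClass("VIPResult", representation(
    vip = "numeric", ncomp = "integer", threshold = "numeric",
    selected = "character", explainedY = "numeric"))

setValidity("VIPResult", function(object) {
    if (length(object@vip) &&
        abs(mean(object@vip^2) - 1) > 1e-6)
        "mean squared VIP must equal 1" else TRUE
})

#' Method-by-metric comparison report for a correction grid
#'
#' @slot grid data.frame with one row per method: intraday CV\% per day,
#'   interday CV\%, QCS PCA distance, tissue intragroup/intergroup distances,
#'   median tissue-feature CV\%
#' @slot vipGrid feature x method VIP selection grid
#' @slot robustFeatures features selected under every method
#' @slot droppedFeatures features selected only without correction
#' @slot failures per-method error messages for grid cells that failed
#' @slot metadata run metadata (config, seed, package version)
#' @export
setClass("ComparisonReport", representation(
    grid = "data.frame", vipGrid = "data.frame",
    robustFeatures = "character", droppedFeatures = "character",
    failures = "character", metadata = "list"))
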