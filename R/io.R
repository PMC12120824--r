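#' Read a feature table from wide CSV/TSV
#'
#' Canonical interchange format: RFC-4180 CSV (or TSV by extension), UTF-8,
#' "." decimal separator. The first column must be `obs_id`; the reserved
#' metadata headers are `slide_id`, `day`, `measurement_order`, `region_type`,
#' `group` and (optionally) `row_id`; every other column is a numeric feature
#' named by its feat_id. Validation is strict: duplicate ids, missing or
#' negative intensities, and unknown region labels are hard errors that name
#' the offending row/column; nothing is silently coerced.
#'
#' Exported abundances may be per-region means or sums depending on the
#' upstream peak-picking software; the reader is agnostic and accepts any
#' non-negative abundance.
#'
#' @param path file path (".tsv"/".txt" read as tab-separated, else comma)
#' @param roles optional named character vector feat_id -> role
#'   (`analyte`, `internal_standard`, `tissue_feature`)
#' @return a \linkS4class{FeatureTable}
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, roles = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             na.strings = character(), quote = "\"",
                             comment.char = "", fileEncoding = "UTF-8")
    if (!ncol(raw) || colnames(raw)[1] != "obs_id")
        stop("first column must be obs_id")
    meta_cols <- intersect(.OBS_META_COLS, colnames(raw))
    need <- setdiff(setdiff(.OBS_META_COLS, "row_id"), meta_cols)
    if (length(need))
        stop("missing required metadata column(s): ",
             paste(need, collapse = ", "))
    feat_cols <- setdiff(colnames(raw), .OBS_META_COLS)
    if (!length(feat_cols)) stop("no feature columns found")
    n <- nrow(raw)
    m <- matrix(NA_real_, n, length(feat_cols),
                dimnames = list(raw$obs_id, feat_cols))
    for (j in seq_along(feat_cols)) {
        v <- suppressWarnings(as.numeric(raw[[feat_cols[j]]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf(
                "missing or non-numeric intensity at row %d (obs_id '%s'), column '%s'",
                bad[1], raw$obs_id[bad[1]], feat_cols[j]))
        neg <- which(v < 0)
        if (length(neg))
            stop(sprintf(
                "negative intensity at row %d (obs_id '%s'), column '%s'",
                neg[1], raw$obs_id[neg[1]], feat_cols[j]))
        m[, j] <- v
    }
    mo <- suppressWarnings(as.integer(raw$measurement_order))
    if (anyNA(mo)) stop("measurement_order must be integer")
    bad_region <- setdiff(unique(raw$region_type), .REGION_LEVELS)
    if (length(bad_region))
        stop("unknown region label(s): ", paste(bad_region, collapse = ", "))
    obs_meta <- data.frame(obs_id = raw$obs_id, slide_id = raw$slide_id,
                           day = raw$day, measurement_order = mo,
                           region_type = raw$region_type, group = raw$group,
                           stringsAsFactors = FALSE)
    if ("row_id" %in% colnames(raw)) obs_meta$row_id <- raw$row_id
    feat_meta <- data.frame(feat_id = feat_cols, mz = .parseMz(feat_cols),
                            role = "tissue_feature", stringsAsFactors = FALSE)
    if (!is.null(roles)) {
        unknown <- setdiff(names(roles), feat_cols)
        if (length(unknown))
            stop("role assigned to unknown feature(s): ",
                 paste(unknown, collapse = ", "))
        feat_meta$role[match(names(roles), feat_meta$feat_id)] <-
            unname(roles)
    }
    FeatureTable(m, obs_meta, feat_meta)
}

#' Write a feature table to wide CSV/TSV
#'
#' Deterministic layout (metadata columns first, then features in their
#' declared order) with full-precision decimal representation (17 significant
#' digits), so that `readFeatureTable(writeFeatureTable(x))` reproduces the
#' table exactly, values and metadata alike.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path output path (".tsv"/".txt" written tab-separated, else comma)
#' @return `path`, invisibly
#' @export
writeFeatureTable <- function(table, path) {
    stopifnot(is(table, "FeatureTable"))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    om <- obsMeta(table)
    keep <- intersect(.OBS_META_COLS, colnames(om))
    if (all(is.na(om$row_id))) keep <- setdiff(keep, "row_id")
    m <- intensities(table)
    num <- matrix("", nrow(m), ncol(m), dimnames = list(NULL, colnames(m)))
    for (j in seq_len(ncol(m))) num[, j] <- .formatFull(m[, j])
    out <- cbind(as.data.frame(lapply(om[keep], as.character),
                               check.names = FALSE, optional = TRUE),
                 as.data.frame(num, check.names = FALSE, optional = TRUE))
    colnames(out) <- c(keep, colnames(m))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = sep, quote = FALSE, na = "",
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    invisible(path)
}

# shortest decimal representation that round-trips an IEEE double
.formatFull <- function(x) {
    out <- formatC(x, digits = 15, format = "g", width = 1)
    bad <- suppressWarnings(as.numeric(out)) != x
    if (any(bad)) out[bad] <- formatC(x[bad], digits = 17, format = "g",
                                      width = 1)
    out
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to package defaults; `vip_threshold` must be
#' positive.
#'
#' @param path YAML file, or NULL for all defaults
#' @return named list of configuration values
#' @export
readPipelineConfig <- function(path = NULL) {
    cfg <- defaultPipelineConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        for (k in names(user)) cfg[[k]] <- user[[k]]
    }
    if (!is.numeric(cfg$vip_threshold) || cfg$vip_threshold <= 0)
        stop("vip_threshold must be > 0")
    cfg
}

#' Default pipeline configuration
#'
#' @return named list: analyte/IS feature ids (NULL = take from feature
#'   roles), batch and order keys, correction method grid, VIP threshold
#'   (1.2), outlier rule constant (3.5), seed.
#' @export
defaultPipelineConfig <- function() {
    list(analyte_feat_id = NULL, is_feat_id = NULL,
         qcs_region = "qcs", batch_key = "day",
         order_key = "measurement_order",
         methods = list(list(pre = "raw", method = "none"),
                        list(pre = "tic", method = "none"),
                        list(pre = "tic", method = "combat"),
                        list(pre = "tic", method = "waveica"),
                        list(pre = "raw", method = "combat"),
                        list(pre = "raw", method = "waveica")),
         cv_grouping = c("day", "slide_id"),
         vip_threshold = 1.2, outlier_k = 3.5, seed = 1L)
}
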