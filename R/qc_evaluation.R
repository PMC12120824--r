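#' Coefficient of variation, in percent
#'
#' 100 * sd / mean with the sample standard deviation (n - 1 denominator).
#' Scale-invariant: `cvPercent(c * x) == cvPercent(x)` for c > 0.
#'
#' @param values numeric vector, length >= 2, nonzero mean
#' @return CV as a percentage
#' @examples
#' cvPercent(c(1, 2, 3))  # 50
#' @export
cvPercent <- function(values) {
    if (length(values) < 2) stop("need at least 2 values for CV%")
    m <- mean(values)
    if (m == 0) stop("CV% undefined for zero mean")
    100 * stats::sd(values) / m
}

#' Kruskal-Wallis batch-difference test
#'
#' Rank-based H statistic with tie correction and a chi-square approximation
#' on k - 1 degrees of freedom, as implemented by [stats::kruskal.test()].
#' The fully degenerate case (every value identical, where the tie correction
#' is 0/0) is defined by policy as H = 0, p = 1: total ties carry no evidence
#' of batch differences.
#'
#' @param values numeric vector
#' @param labels batch labels, one per value; >= 2 distinct labels required
#' @return list with `statistic` (H), `p.value`, `df`
#' @export
kruskalWallisBatchTest <- function(values, labels) {
    labels <- as.factor(as.character(labels))
    if (nlevels(labels) < 2)
        stop("need at least 2 batches for a Kruskal-Wallis test")
    if (length(values) != length(labels))
        stop("values and labels differ in length")
    if (length(unique(values)) == 1L)
        return(list(statistic = 0, p.value = 1,
                    df = nlevels(labels) - 1L))
    kt <- stats::kruskal.test(values, labels)
    list(statistic = unname(kt$statistic), p.value = kt$p.value,
         df = unname(kt$parameter))
}

#' Robust outlier-slide detection
#'
#' Flags slides whose QCS analyte level departs from the cohort: for each
#' slide the median analyte intensity over its QCS spots is taken (on the
#' log scale by default, since slide effects are multiplicative), and slide s
#' is flagged when
#' `|median_s - median(all slide medians)| / (1.4826 * MAD) > k`
#' with the 1.4826 factor making the denominator a consistent sd estimate.
#' Two refinements suit the small slide cohorts of a batch experiment:
#' the center and MAD for slide s are computed from the \emph{other} slides
#' (leave-one-out), so a strong outlier does not dilute its own score; and
#' by default the slide medians are first centered on their day's median
#' (`within_day = TRUE`), so that between-day batch shifts do not inflate
#' the MAD and mask a within-batch anomaly such as a sprayer failure. When
#' the MAD is exactly zero (all reference slides identical), the rule falls
#' back to flagging any slide whose median differs at all from the common
#' value.
#'
#' @param table a \linkS4class{FeatureTable} containing QCS observations
#' @param analyte_feat analyte feature id (default: role `analyte`)
#' @param k rule constant (default 3.5)
#' @param log_scale apply the rule to log-scale medians (default TRUE)
#' @param within_day center slide medians on their day median first
#' @return data.frame with slide_id, median, score, flagged
#' @export
detectOutlierSlides <- function(table, analyte_feat = NULL, k = 3.5,
                                log_scale = TRUE, within_day = TRUE) {
    qcs <- subsetRegion(table, "qcs")
    analyte_feat <- .resolveAnalyte(qcs, analyte_feat)
    om <- obsMeta(qcs)
    v <- intensities(qcs)[, analyte_feat]
    slides <- unique(om$slide_id)
    if (length(slides) < 3)
        stop("outlier rule undefined for fewer than 3 slides")
    if (log_scale) {
        if (any(v <= 0)) stop("log-scale rule requires positive intensities")
        v <- log(v)
    }
    med <- vapply(slides, function(s) stats::median(v[om$slide_id == s]), 0)
    slide_day <- vapply(slides, function(s) om$day[om$slide_id == s][1], "")
    n_s <- length(slides)
    score <- numeric(n_s)
    for (i in seq_len(n_s)) {
        oth <- setdiff(seq_len(n_s), i)
        dc <- if (within_day) {
            day_med <- tapply(med[oth], slide_day[oth], stats::median)
            miss <- setdiff(unique(slide_day), names(day_med))
            if (length(miss))           # day represented by slide i only
                day_med[miss] <- stats::median(med[oth])
            med - day_med[slide_day]
        } else med
        ctr <- stats::median(dc[oth])
        s_mad <- stats::mad(dc[oth], center = ctr, constant = 1.4826)
        score[i] <- if (s_mad > 0) abs(dc[i] - ctr) / s_mad
                    else if (dc[i] == ctr) 0 else Inf
    }
    data.frame(slide_id = slides, median = unname(med),
               score = score, flagged = score > k,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Acquisition-drift profile of the QCS analyte
#'
#' Describes intensity drift along the global measurement order: the analyte
#' value of every QCS spot versus its acquisition order, the least-squares
#' slope of that series (log scale by default, i.e. multiplicative drift per
#' order unit), and a per-slide paired contrast of QCS acquired after versus
#' before the slide's tissue regions (mean after - mean before, NA when the
#' layout does not provide both sides). The slope is descriptive; no p-value
#' is attached.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param analyte_feat analyte feature id (default: role `analyte`)
#' @param log_scale fit the slope on log intensities (default TRUE)
#' @return list with `series` (data.frame order, slide_id, value),
#'   `slope`, `contrast` (data.frame slide_id, before, after, delta)
#' @export
driftProfile <- function(table, analyte_feat = NULL, log_scale = TRUE) {
    qcs <- subsetRegion(table, "qcs")
    analyte_feat <- .resolveAnalyte(qcs, analyte_feat)
    om <- obsMeta(qcs)
    if (anyNA(om$measurement_order))
        stop("measurement_order is required for a drift profile")
    v <- intensities(qcs)[, analyte_feat]
    y <- if (log_scale) {
        if (any(v <= 0)) stop("log-scale drift requires positive intensities")
        log(v)
    } else v
    ord <- order(om$measurement_order)
    series <- data.frame(order = om$measurement_order[ord],
                         slide_id = om$slide_id[ord], value = v[ord],
                         stringsAsFactors = FALSE)
    slope <- if (length(unique(om$measurement_order)) > 1)
        unname(stats::coef(stats::lm(y ~ om$measurement_order))[2]) else 0
    tis <- obsMeta(subsetRegion(table, "tissue"))
    contrast <- do.call(rbind, lapply(unique(om$slide_id), function(s) {
        t_ord <- tis$measurement_order[tis$slide_id == s]
        sel <- om$slide_id == s
        if (!length(t_ord) || sum(sel) < 2)
            return(data.frame(slide_id = s, before = NA_real_,
                              after = NA_real_, delta = NA_real_))
        before <- y[sel & om$measurement_order < min(t_ord)]
        after <- y[sel & om$measurement_order > max(t_ord)]
        if (!length(before) || !length(after))
            return(data.frame(slide_id = s, before = NA_real_,
                              after = NA_real_, delta = NA_real_))
        data.frame(slide_id = s, before = mean(before), after = mean(after),
                   delta = mean(after) - mean(before))
    }))
    list(series = series, slope = slope, contrast = contrast,
         log_scale = log_scale)
}

#' QCS variation report
#'
#' Part 1 of the pipeline: pooled intraday CV\% of the monitored analyte per
#' day (all of that day's QCS spots together), the pooled interday CV\% over
#' the whole experiment, per-slide and (when a row layout is present)
#' per-row CV\%, Kruskal-Wallis tests for slide differences within each day
#' and for day differences overall, robust outlier-slide flags, and the
#' acquisition-drift profile. Grouping levels with fewer than 2 observations
#' are reported as NA, never silently dropped, so every cell of the
#' day-by-method grid is either a number or an explicit not-available marker.
#'
#' @param table a \linkS4class{FeatureTable} with QCS observations
#' @param analyte_feat analyte feature id (default: role `analyte`)
#' @param method label recorded in the report (e.g. "raw", "TIC")
#' @param outlier_k constant for [detectOutlierSlides()]
#' @return a \linkS4class{QCReport}
#' @export
qcsCVReport <- function(table, analyte_feat = NULL, method = "raw",
                        outlier_k = 3.5) {
    qcs <- subsetRegion(table, "qcs")
    if (!ncol(qcs)) stop("table contains no QCS observations")
    analyte_feat <- .resolveAnalyte(qcs, analyte_feat)
    om <- obsMeta(qcs)
    v <- intensities(qcs)[, analyte_feat]
    cv_or_na <- function(x) if (length(x) >= 2 && mean(x) != 0)
        cvPercent(x) else NA_real_
    days <- unique(om$day)
    intraday <- data.frame(
        day = days,
        n = vapply(days, function(d) sum(om$day == d), 0L),
        cv = vapply(days, function(d) cv_or_na(v[om$day == d]), 0),
        row.names = NULL, stringsAsFactors = FALSE)
    interday <- cv_or_na(v)
    slides <- unique(om$slide_id)
    perSlide <- data.frame(
        slide_id = slides,
        day = vapply(slides, function(s) om$day[om$slide_id == s][1], ""),
        n = vapply(slides, function(s) sum(om$slide_id == s), 0L),
        cv = vapply(slides, function(s) cv_or_na(v[om$slide_id == s]), 0),
        row.names = NULL, stringsAsFactors = FALSE)
    perRow <- data.frame(slide_id = character(), row_id = character(),
                         n = integer(), cv = numeric(),
                         stringsAsFactors = FALSE)
    if (!all(is.na(om$row_id))) {
        key <- unique(om[c("slide_id", "row_id")])
        perRow <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
            sel <- om$slide_id == key$slide_id[i] & om$row_id == key$row_id[i]
            data.frame(slide_id = key$slide_id[i], row_id = key$row_id[i],
                       n = sum(sel), cv = cv_or_na(v[sel]),
                       stringsAsFactors = FALSE)
        }))
    }
    tests <- do.call(rbind, c(
        lapply(days, function(d) {
            sel <- om$day == d
            res <- if (length(unique(om$slide_id[sel])) >= 2)
                kruskalWallisBatchTest(v[sel], om$slide_id[sel])
            else list(statistic = NA_real_, p.value = NA_real_)
            data.frame(scope = paste0("intraday_", d),
                       statistic = res$statistic, p.value = res$p.value,
                       stringsAsFactors = FALSE)
        }),
        list({
            res <- if (length(days) >= 2) kruskalWallisBatchTest(v, om$day)
                   else list(statistic = NA_real_, p.value = NA_real_)
            data.frame(scope = "interday", statistic = res$statistic,
                       p.value = res$p.value, stringsAsFactors = FALSE)
        })))
    outliers <- if (length(slides) >= 3 && all(v > 0))
        detectOutlierSlides(table, analyte_feat, k = outlier_k)
    else data.frame(slide_id = slides, median = NA_real_, score = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
    drift <- if (all(v > 0)) driftProfile(table, analyte_feat)
             else driftProfile(table, analyte_feat, log_scale = FALSE)
    new("QCReport", analyte = analyte_feat, method = method,
        intraday = intraday, interday = interday, perSlide = perSlide,
        perRow = perRow, tests = tests, outliers = outliers, drift = drift)
}

.resolveAnalyte <- function(table, analyte_feat) {
    fm <- featMeta(table)
    if (is.null(analyte_feat)) {
        analyte_feat <- fm$feat_id[fm$role == "analyte"][1]
        if (is.na(analyte_feat))
            stop("no feature with role 'analyte'; pass analyte_feat")
    }
    if (!analyte_feat %in% fm$feat_id)
        stop("analyte feature not found: ", analyte_feat)
    analyte_feat
}
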