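#' Simulation configuration for a batch MSI experiment
#'
#' Defines the study design the generator emulates: serial acquisition over
#' `n_days` days with `slides_per_day` slides per day, each slide carrying
#' `qcs_per_slide` QCS spots surrounding `tissue_per_slide` tissue sections;
#' three tissue groups with six replicate slides each by default. Intensity
#' structure is multiplicative (log-normal): per-slide and per-day log-scale
#' effects shared by all features of an observation, feature-specific
#' acquisition-order drift for a "lipid-like" high-m/z subset, one designated
#' low-intensity outlier slide emulating a matrix-sprayer failure, and
#' independent log-normal residual noise. An analyte/internal-standard pair
#' (propranolol / propranolol-d7) is spotted on the QCS regions; the pair
#' shares every observation-level factor but has independent residuals, so
#' the IS ratio cancels slide, day and outlier effects exactly and retains
#' only residual noise.
#'
#' Default magnitudes (log-scale sd: 0.3 per spot, 0.2 per slide, 0.25 per
#' day, 0.08 residual; one slide attenuated by -1.5) are calibrated so that
#' the raw interday CV of the analyte falls in the ~40-65\% regime while the
#' IS-ratio CV stays near 11\% (below the 15\% bioanalytical ceiling), the
#' qualitative regime a QCS-monitored batch experiment exhibits. These are
#' calibrated magnitudes, not estimates of any particular instrument.
#'
#' @param n_days number of acquisition days (batches)
#' @param slides_per_day slides measured per day
#' @param qcs_per_slide QCS spots per slide (half before, half after tissue)
#' @param tissue_per_slide tissue sections per slide
#' @param groups tissue group labels
#' @param slides_per_group replicate slides per group
#' @param n_tissue_features endogenous tissue features
#' @param lipid_fraction fraction of drift-prone lipid-like features
#'   (assigned m/z > 700)
#' @param sigma_spot,sigma_slide,sigma_day,sigma_resid log-scale standard
#'   deviations of per-observation spray/suppression factors, slide effects,
#'   day effects and residual noise
#' @param drift_range range of log-scale drift slopes per order unit for
#'   lipid-like features (drawn uniformly)
#' @param outlier_slides slide ids designated as outliers
#' @param outlier_offset log-scale attenuation of outlier slides
#' @param markers_per_group group-marker features per group
#' @param marker_effect log-scale group-marker effect size
#' @param analyte_qcs_log,is_qcs_log log baseline of analyte and IS on QCS
#' @param analyte_tissue_log log baseline of the analyte pair on tissue
#' @param qcs_background_log log baseline of tissue features on QCS regions
#' @param tissue_base_log_mean,tissue_base_log_sd distribution of per-feature
#'   tissue baselines
#' @return a validated configuration list (class `SimulationConfig`)
#' @export
simulationConfig <- function(n_days = 3L, slides_per_day = 6L,
                             qcs_per_slide = 6L, tissue_per_slide = 2L,
                             groups = c("goat_liver", "chicken_liver",
                                        "chicken_heart"),
                             slides_per_group = 6L,
                             n_tissue_features = 200L,
                             lipid_fraction = 0.3,
                             sigma_spot = 0.3, sigma_slide = 0.2,
                             sigma_day = 0.25, sigma_resid = 0.08,
                             drift_range = c(-0.004, -0.002),
                             outlier_slides = "S04", outlier_offset = -1.5,
                             markers_per_group = 10L, marker_effect = 1.0,
                             analyte_qcs_log = log(1e4),
                             is_qcs_log = log(1e4),
                             analyte_tissue_log = log(50),
                             qcs_background_log = log(5),
                             tissue_base_log_mean = log(500),
                             tissue_base_log_sd = 1.0) {
    cfg <- list(n_days = as.integer(n_days),
                slides_per_day = as.integer(slides_per_day),
                qcs_per_slide = as.integer(qcs_per_slide),
                tissue_per_slide = as.integer(tissue_per_slide),
                groups = groups,
                slides_per_group = as.integer(slides_per_group),
                n_tissue_features = as.integer(n_tissue_features),
                lipid_fraction = lipid_fraction, sigma_spot = sigma_spot,
                sigma_slide = sigma_slide, sigma_day = sigma_day,
                sigma_resid = sigma_resid, drift_range = drift_range,
                outlier_slides = outlier_slides,
                outlier_offset = outlier_offset,
                markers_per_group = as.integer(markers_per_group),
                marker_effect = marker_effect,
                analyte_qcs_log = analyte_qcs_log,
                is_qcs_log = is_qcs_log,
                analyte_tissue_log = analyte_tissue_log,
                qcs_background_log = qcs_background_log,
                tissue_base_log_mean = tissue_base_log_mean,
                tissue_base_log_sd = tissue_base_log_sd)
    if (any(c(cfg$sigma_spot, cfg$sigma_slide, cfg$sigma_day,
              cfg$sigma_resid) < 0))
        stop("noise standard deviations must be >= 0")
    if (cfg$n_days * cfg$slides_per_day !=
        length(cfg$groups) * cfg$slides_per_group)
        stop("inconsistent design: n_days * slides_per_day must equal ",
             "n_groups * slides_per_group")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Generate a synthetic batch experiment with ground truth
#'
#' Draws a full feature table from the model
#' `log x_of = mu_(g(o), f) + b_s(o) + c_d(o) + v_o + beta_f * order(o) +
#'  u_s(o) + eps_of`, `eps ~ N(0, sigma_resid^2)`,
#' where `b`, `c`, `v` and `u` are slide, day, spray-spot and outlier effects
#' shared by all features of an observation (QCS spots share `b`, `c`, `u`
#' with their slide; the analyte and its internal standard additionally share
#' the spot factor `v`, so their ratio retains only residual noise), and
#' `beta_f` is nonzero only for lipid-like features. Slide measurement order
#' is randomized within each day; within a slide, half of the QCS spots are
#' acquired before and half after the tissue sections, so before/after drift
#' contrasts are defined. Intensities are returned on the linear scale
#' (exponentiated). Fully deterministic given `(config, seed)`.
#'
#' @param config a [simulationConfig()]
#' @param seed integer RNG seed
#' @return list with `table` (\linkS4class{FeatureTable}) and `truth`
#'   (\linkS4class{SyntheticTruth})
#' @export
generateBatchExperiment <- function(config = simulationConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(seed, .generate(config, as.integer(seed)))
}

.generate <- function(cfg, seed) {
    n_slides <- cfg$n_days * cfg$slides_per_day
    slide_ids <- sprintf("S%02d", seq_len(n_slides))
    day_ids <- sprintf("day%d", seq_len(cfg$n_days))
    slide_day <- rep(day_ids, each = cfg$slides_per_day)
    # groups balanced across days: cycle group labels within each day
    slide_group <- rep(rep(cfg$groups, length.out = cfg$slides_per_day),
                       cfg$n_days)
    names(slide_day) <- names(slide_group) <- slide_ids

    bad <- setdiff(cfg$outlier_slides, slide_ids)
    if (length(bad)) stop("unknown outlier slide id(s): ",
                          paste(bad, collapse = ", "))
    b <- stats::setNames(stats::rnorm(n_slides, 0, cfg$sigma_slide), slide_ids)
    # day effects: systematic between-day shifts (instrument/cleaning state),
    # a fixed zero-sum contrast of magnitude sigma_day, ascending from day 1
    # (the first day is the low-response day, the one that also carries the
    # default sprayer-failure slide)
    contrast <- seq(-1, 1, length.out = cfg$n_days)
    if (cfg$n_days > 1) contrast <- contrast / stats::sd(contrast)
    c_d <- stats::setNames(cfg$sigma_day * contrast, day_ids)
    u <- stats::setNames(rep(0, n_slides), slide_ids)
    u[cfg$outlier_slides] <- cfg$outlier_offset

    # features: analyte pair + tissue panel with lipid-like drift subset
    nf <- cfg$n_tissue_features
    n_lipid <- round(cfg$lipid_fraction * nf)
    mz <- c(stats::runif(nf - n_lipid, 100, 700),
            stats::runif(n_lipid, 700.1, 900))
    mz <- round(mz, 4)
    repeat {
        clash <- duplicated(mz) | mz %in% c(260.16, 267.21)
        if (!any(clash)) break
        lo <- ifelse(seq_along(mz) > nf - n_lipid, 700.1, 100)
        hi <- ifelse(seq_along(mz) > nf - n_lipid, 900, 700)
        mz[clash] <- round(stats::runif(sum(clash), lo[clash], hi[clash]), 4)
    }
    tissue_ids <- sprintf("mz%.4f", mz)
    feat_ids <- c("mz260.1600", "mz267.2100", tissue_ids)
    roles <- c("analyte", "internal_standard",
               rep("tissue_feature", nf))
    is_lipid <- c(FALSE, FALSE, mz > 700)
    beta <- stats::setNames(rep(0, length(feat_ids)), feat_ids)
    beta[is_lipid] <- stats::runif(sum(is_lipid), min(cfg$drift_range),
                                   max(cfg$drift_range))
    mu_tissue <- stats::rnorm(nf, cfg$tissue_base_log_mean,
                              cfg$tissue_base_log_sd)
    # group markers: disjoint feature sets, shifted up in their group
    marker_pool <- sample(seq_len(nf),
                          min(nf, cfg$markers_per_group * length(cfg$groups)))
    markers <- data.frame(group = rep(cfg$groups,
                                      each = cfg$markers_per_group)[
                              seq_along(marker_pool)],
                          feat_id = tissue_ids[marker_pool],
                          effect = cfg$marker_effect,
                          stringsAsFactors = FALSE)

    # acquisition plan: slides randomized within day, measured sequentially;
    # per slide: first half QCS, tissue sections, second half QCS
    qcs_before <- ceiling(cfg$qcs_per_slide / 2)
    per_slide <- cfg$qcs_per_slide + cfg$tissue_per_slide
    obs <- NULL
    for (d in seq_len(cfg$n_days)) {
        day_slides <- slide_ids[slide_day == day_ids[d]]
        day_slides <- day_slides[sample.int(length(day_slides))]
        for (s in day_slides) {
            region <- c(rep("qcs", qcs_before),
                        rep("tissue", cfg$tissue_per_slide),
                        rep("qcs", cfg$qcs_per_slide - qcs_before))
            obs <- rbind(obs, data.frame(slide_id = s, day = slide_day[[s]],
                                         region_type = region,
                                         stringsAsFactors = FALSE))
        }
    }
    obs$measurement_order <- seq_len(nrow(obs))
    obs$group <- ifelse(obs$region_type == "tissue",
                        slide_group[obs$slide_id], "")
    obs$obs_id <- sprintf("%s_%s%02d", obs$slide_id,
                          ifelse(obs$region_type == "qcs", "q", "t"),
                          stats::ave(seq_len(nrow(obs)),
                                     paste(obs$slide_id, obs$region_type),
                                     FUN = seq_along))
    n_obs <- nrow(obs)

    # expected log intensity mu_(g(o), f)
    mu <- matrix(0, n_obs, length(feat_ids),
                 dimnames = list(obs$obs_id, feat_ids))
    qcs <- obs$region_type == "qcs"
    mu[qcs, 1] <- cfg$analyte_qcs_log
    mu[qcs, 2] <- cfg$is_qcs_log
    mu[!qcs, 1:2] <- cfg$analyte_tissue_log
    shift <- cfg$qcs_background_log - cfg$tissue_base_log_mean
    mu[qcs, -(1:2)] <- rep(mu_tissue + shift, each = sum(qcs))
    mu[!qcs, -(1:2)] <- rep(mu_tissue, each = sum(!qcs))
    for (i in seq_len(nrow(markers))) {
        sel <- !qcs & obs$group == markers$group[i]
        mu[sel, markers$feat_id[i]] <- mu[sel, markers$feat_id[i]] +
            markers$effect[i]
    }
    v <- stats::setNames(stats::rnorm(n_obs, 0, cfg$sigma_spot), obs$obs_id)
    obs_eff <- b[obs$slide_id] + c_d[obs$day] + u[obs$slide_id] + v
    drift <- outer(obs$measurement_order, beta)
    eps <- matrix(stats::rnorm(n_obs * length(feat_ids), 0, cfg$sigma_resid),
                  n_obs, length(feat_ids))
    x <- exp(mu + obs_eff + drift + eps)

    obs_meta <- obs[c("obs_id", "slide_id", "day", "measurement_order",
                      "region_type", "group")]
    feat_meta <- data.frame(feat_id = feat_ids, mz = c(260.16, 267.21, mz),
                            role = roles, stringsAsFactors = FALSE)
    table <- FeatureTable(x, obs_meta, feat_meta)
    truth <- new("SyntheticTruth", slideEffects = b, dayEffects = c_d,
                 sprayFactors = v, driftSlopes = beta, outlierOffsets = u[u != 0],
                 markers = markers, config = unclass(cfg), seed = seed)
    list(table = table, truth = truth)
}

#' Inject a known batch effect into a feature table
#'
#' Applies a controlled additive or multiplicative perturbation to a named
#' slide, day or measurement-order window (optionally restricted to a region
#' type and/or feature subset) and returns the perturbed table together with
#' an exact record of what was injected. Used to give correction methods a
#' known target.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param effect_spec list with fields `type` (`"multiplicative"` or
#'   `"additive"`), `value` (factor or offset), and at least one of `slide`,
#'   `day`, `order_window` (length-2 inclusive range); optional `region`
#'   (`"qcs"`/`"tissue"`) and `features` (feat ids)
#' @return list with `table` (perturbed copy) and `truth` (the realized
#'   spec, including the affected obs ids)
#' @export
injectKnownEffect <- function(table, effect_spec) {
    stopifnot(is(table, "FeatureTable"), is.list(effect_spec))
    type <- match.arg(effect_spec$type, c("multiplicative", "additive"))
    value <- effect_spec$value
    if (!is.numeric(value) || length(value) != 1)
        stop("effect_spec$value must be a single number")
    om <- obsMeta(table)
    sel <- rep(TRUE, nrow(om))
    if (!is.null(effect_spec$slide)) {
        bad <- setdiff(effect_spec$slide, om$slide_id)
        if (length(bad)) stop("unknown slide id(s): ",
                              paste(bad, collapse = ", "))
        sel <- sel & om$slide_id %in% effect_spec$slide
    }
    if (!is.null(effect_spec$day)) {
        bad <- setdiff(effect_spec$day, om$day)
        if (length(bad)) stop("unknown day id(s): ",
                              paste(bad, collapse = ", "))
        sel <- sel & om$day %in% effect_spec$day
    }
    if (!is.null(effect_spec$order_window)) {
        w <- effect_spec$order_window
        sel <- sel & om$measurement_order >= w[1] &
            om$measurement_order <= w[2]
    }
    if (!is.null(effect_spec$region))
        sel <- sel & om$region_type %in% effect_spec$region
    m <- intensities(table)
    feats <- if (is.null(effect_spec$features)) colnames(m)
             else effect_spec$features
    bad <- setdiff(feats, colnames(m))
    if (length(bad)) stop("unknown feature id(s): ",
                          paste(bad, collapse = ", "))
    if (type == "multiplicative") {
        if (value < 0) stop("multiplicative factor must be >= 0")
        m[sel, feats] <- m[sel, feats] * value
    } else {
        m[sel, feats] <- pmax(m[sel, feats] + value, 0)
    }
    truth <- effect_spec
    truth$obs_ids <- om$obs_id[sel]
    truth$features <- feats
    list(table = .setIntensities(table, m), truth = truth)
}

#' Parameter recovery from a simulated experiment
#'
#' Validation utilities for the generator: given a simulated table and its
#' ground truth, re-estimate the effects the generator injected, adjusting
#' for the other (known) truth components so each estimate isolates one
#' effect against residual noise.
#'
#' `recoverSlideEffects` adjusts the log intensities of the QCS observations
#' by the known day, outlier, spray-spot and drift terms, centers each
#' feature, averages per slide, and regresses the per-slide QCS log-means on
#' the true slide effects b_s; an unbiased generator yields slope 1.
#'
#' `recoverDriftSlopes` adjusts the log intensities of all observations by
#' the known slide/day/outlier/spray terms and fits, per drifting feature, a
#' least-squares slope against measurement order, returning fitted versus
#' true slopes.
#'
#' @param table a simulated \linkS4class{FeatureTable}
#' @param truth the matching \linkS4class{SyntheticTruth}
#' @return `recoverSlideEffects`: list with `slope`, `intercept` and
#'   `estimates` (per-slide adjusted means beside true effects).
#'   `recoverDriftSlopes`: data.frame with feat_id, true and fitted slope.
#' @export
recoverSlideEffects <- function(table, truth) {
    om <- obsMeta(table)
    qcs <- om$region_type == "qcs"
    y <- log(intensities(table)[qcs, , drop = FALSE])
    u <- .outlierVector(truth)
    adj <- truth@dayEffects[om$day[qcs]] + u[om$slide_id[qcs]] +
        truth@sprayFactors[om$obs_id[qcs]]
    y <- y - adj                          # recycles down columns (per row)
    ord_c <- om$measurement_order[qcs] - mean(om$measurement_order[qcs])
    y <- y - outer(ord_c, truth@driftSlopes[colnames(y)])
    y <- y - outer(rep(1, nrow(y)), colMeans(y))  # feature-center
    sm <- tapply(rowMeans(y), om$slide_id[qcs], mean)
    b <- truth@slideEffects[names(sm)]
    fit <- stats::lm(sm ~ b)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         estimates = data.frame(slide_id = names(sm), mean = as.numeric(sm),
                                b = as.numeric(b)))
}

#' @rdname recoverSlideEffects
#' @export
recoverDriftSlopes <- function(table, truth) {
    om <- obsMeta(table)
    u <- .outlierVector(truth)
    adj <- truth@slideEffects[om$slide_id] + truth@dayEffects[om$day] +
        u[om$slide_id] + truth@sprayFactors[om$obs_id]
    drifting <- names(truth@driftSlopes)[truth@driftSlopes != 0]
    m <- log(intensities(table)[, drifting, drop = FALSE]) - adj
    ord <- om$measurement_order
    fitted <- vapply(seq_along(drifting), function(j)
        unname(stats::coef(stats::lm(m[, j] ~ ord))[2]), 0)
    data.frame(feat_id = drifting, true = unname(truth@driftSlopes[drifting]),
               fitted = fitted, stringsAsFactors = FALSE)
}

.outlierVector <- function(truth) {
    u <- stats::setNames(rep(0, length(truth@slideEffects)),
                         names(truth@slideEffects))
    u[names(truth@outlierOffsets)] <- truth@outlierOffsets
    u
}
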