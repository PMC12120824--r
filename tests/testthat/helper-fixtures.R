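# shared fixture builders (all data generated in code; nothing on disk)

# minimal wide table: n_obs x features, one slide per `slides` entry
makeToyTable <- function(values, slides = NULL, days = NULL, region = "qcs",
                         groups = NULL, feat_ids = NULL, roles = NULL) {
    m <- as.matrix(values)
    n <- nrow(m)
    if (is.null(feat_ids)) feat_ids <- sprintf("mz%d", 100 + seq_len(ncol(m)))
    colnames(m) <- feat_ids
    if (is.null(slides)) slides <- rep("S01", n)
    if (is.null(days)) days <- rep("day1", n)
    if (is.null(groups)) groups <- rep("", n)
    om <- data.frame(obs_id = sprintf("o%02d", seq_len(n)),
                     slide_id = slides, day = days,
                     measurement_order = seq_len(n),
                     region_type = rep(region, length.out = n),
                     group = groups, stringsAsFactors = FALSE)
    fm <- data.frame(feat_id = feat_ids, mz = 100 + seq_along(feat_ids),
                     role = if (is.null(roles)) "tissue_feature" else roles,
                     stringsAsFactors = FALSE)
    FeatureTable(m, om, fm)
}

# homogeneous single-region series with a day-aligned step on the log scale
makeStepTable <- function(n = 48, p = 40, step = 0.8, sigma = 0.1, seed = 1) {
    set.seed(seed)
    day <- rep(c("day1", "day2"), each = n / 2)
    m <- exp(matrix(rnorm(n * p, 5, sigma), n, p) +
             ifelse(day == "day2", step, 0))
    colnames(m) <- paste0("mz", 100 + seq_len(p))
    om <- data.frame(obs_id = sprintf("o%02d", seq_len(n)),
                     slide_id = rep(sprintf("S%02d", seq_len(n / 6)), each = 6),
                     day = day, measurement_order = seq_len(n),
                     region_type = "qcs", group = "", stringsAsFactors = FALSE)
    FeatureTable(m, om)
}

# per-feature R^2 against the day factor, log scale
featureDayR2 <- function(tb) {
    om <- obsMeta(tb)
    y <- log(intensities(tb))
    vapply(seq_len(ncol(y)), function(j)
        summary(stats::lm(y[, j] ~ factor(om$day)))$r.squared, 0)
}

qcsAnalyteCV <- function(tb, feat = "mz260.1600") {
    om <- obsMeta(tb)
    cvPercent(intensities(tb)[om$region_type == "qcs", feat])
}
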