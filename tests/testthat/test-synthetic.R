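test_that("generation is bit-reproducible from (config, seed)", {
    a <- generateBatchExperiment(seed = 3)
    b <- generateBatchExperiment(seed = 3)
    expect_identical(intensities(a$table), intensities(b$table))
    expect_identical(a$truth@slideEffects, b$truth@slideEffects)
    c_ <- generateBatchExperiment(seed = 4)
    expect_false(identical(intensities(a$table), intensities(c_$table)))
})

test_that("the default design matches the declared layout", {
    sim <- generateBatchExperiment(seed = 1)
    om <- obsMeta(sim$table)
    expect_equal(ncol(intensities(sim$table)), 202L)  # analyte + IS + 200
    expect_equal(length(unique(om$slide_id)), 18L)
    expect_equal(length(unique(om$day)), 3L)
    expect_equal(sum(om$region_type == "qcs"), 108L)
    expect_equal(sum(om$region_type == "tissue"), 36L)
    expect_identical(sort(om$measurement_order), 1:144)
    # groups balanced: 6 slides per group, tissue obs labelled, qcs blank
    tis <- om[om$region_type == "tissue", ]
    expect_equal(as.integer(table(unique(tis[c("slide_id", "group")])$group)),
                 rep(6L, 3))
    expect_true(all(om$group[om$region_type == "qcs"] == ""))
    # each slide has QCS both before and after its tissue sections
    for (s in unique(om$slide_id)) {
        t_ord <- om$measurement_order[om$slide_id == s &
                                      om$region_type == "tissue"]
        q_ord <- om$measurement_order[om$slide_id == s &
                                      om$region_type == "qcs"]
        expect_true(any(q_ord < min(t_ord)) && any(q_ord > max(t_ord)))
    }
    # lipid-like drifting features sit above m/z 700
    fm <- featMeta(sim$table)
    drifting <- names(sim$truth@driftSlopes)[sim$truth@driftSlopes != 0]
    expect_true(all(fm$mz[match(drifting, fm$feat_id)] > 700))
})

test_that("with batch terms off the interday CV follows the log-normal form", {
    cfg <- simulationConfig(sigma_spot = 0, sigma_slide = 0, sigma_day = 0,
                            drift_range = c(0, 0),
                            outlier_slides = character(0))
    sim <- generateBatchExperiment(cfg, seed = 6)
    cv <- qcsAnalyteCV(sim$table)
    closed <- 100 * sqrt(exp(cfg$sigma_resid^2) - 1)
    expect_lt(abs(cv - closed) / closed, 0.15)
})

test_that("IS-ratio variation reflects residual noise only", {
    sim <- generateBatchExperiment(seed = 8)
    om <- obsMeta(sim$table)
    qcs <- om$region_type == "qcs"
    m <- intensities(sim$table)
    ratio <- m[qcs, "mz260.1600"] / m[qcs, "mz267.2100"]
    sigma <- sim$truth@config$sigma_resid
    closed <- 100 * sqrt(exp(2 * sigma^2) - 1)    # two independent residuals
    expect_lt(abs(cvPercent(ratio) - closed) / closed, 0.25)
    # slide/day/outlier structure is gone from the ratio
    expect_gt(kruskalWallisBatchTest(ratio, om$day[qcs])$p.value, 1e-3)
})

test_that("slide effects and drift slopes are recoverable from the data", {
    sim <- generateBatchExperiment(seed = 2)
    rec <- recoverSlideEffects(sim$table, sim$truth)
    expect_lt(abs(rec$slope - 1), 0.1)
    dr <- recoverDriftSlopes(sim$table, sim$truth)
    agg <- unname(coef(lm(dr$fitted ~ dr$true))[2])
    expect_lt(abs(agg - 1), 0.2)
    expect_lt(median(abs(dr$fitted - dr$true) / abs(dr$true)), 0.2)
})

test_that("injected effects are applied exactly where declared", {
    sim <- generateBatchExperiment(seed = 9)
    # zero-magnitude effect: identity
    z <- injectKnownEffect(sim$table,
                           list(type = "additive", value = 0, slide = "S03"))
    expect_identical(intensities(z$table), intensities(sim$table))
    # multiplicative effect confined to one slide's QCS spots
    inj <- injectKnownEffect(sim$table,
                             list(type = "multiplicative", value = 0.25,
                                  slide = "S07", region = "qcs"))
    om <- obsMeta(sim$table)
    sel <- om$slide_id == "S07" & om$region_type == "qcs"
    expect_equal(intensities(inj$table)[sel, ],
                 intensities(sim$table)[sel, ] * 0.25)
    expect_identical(intensities(inj$table)[!sel, ],
                     intensities(sim$table)[!sel, ])
    expect_setequal(inj$truth$obs_ids, om$obs_id[sel])
    expect_error(injectKnownEffect(sim$table,
                                   list(type = "multiplicative", value = 2,
                                        slide = "S99")), "unknown slide")
})

test_that("an injected attenuated slide is flagged by the outlier rule", {
    cfg <- simulationConfig(outlier_slides = character(0))
    sim <- generateBatchExperiment(cfg, seed = 5)
    inj <- injectKnownEffect(sim$table,
                             list(type = "multiplicative", value = 0.2,
                                  slide = "S10", region = "qcs"))
    out <- detectOutlierSlides(inj$table)
    expect_true(out$flagged[out$slide_id == "S10"])
    expect_equal(out$slide_id[which.max(out$score)], "S10")
})

test_that("a day-level offset is almost fully removed by ComBat", {
    cfg <- simulationConfig(sigma_spot = 0, sigma_slide = 0, sigma_day = 0,
                            drift_range = c(0, 0),
                            outlier_slides = character(0))
    sim <- generateBatchExperiment(cfg, seed = 7)
    delta <- 0.5
    inj <- injectKnownEffect(sim$table,
                             list(type = "multiplicative",
                                  value = exp(delta), day = "day2"))
    gap <- function(tb) {
        om <- obsMeta(tb)
        y <- rowMeans(log(intensities(tb)))
        mean(y[om$day == "day2"]) - mean(y[om$day != "day2"])
    }
    expect_equal(gap(inj$table), delta, tolerance = 0.05)
    corrected <- combatCorrect(inj$table)
    expect_lt(abs(gap(corrected@table)), 0.1 * delta)
})

test_that("invalid simulation configurations are rejected", {
    expect_error(simulationConfig(sigma_slide = -1), "standard deviations")
    expect_error(simulationConfig(slides_per_group = 5), "inconsistent")
    expect_error(generateBatchExperiment(
        simulationConfig(outlier_slides = "S99"), seed = 1), "unknown")
})
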