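test_that("CV percent follows the sd/mean definition with sample sd", {
    expect_identical(cvPercent(c(5, 5, 5)), 0)
    expect_identical(cvPercent(c(1, 2, 3)), 50)
    # independent arithmetic oracle: sd = sqrt(sum((x - xbar)^2)/(n-1))
    x <- c(2, 4, 6, 8)
    oracle <- 100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
    expect_equal(cvPercent(x), oracle)
    expect_equal(cvPercent(x), 51.6398, tolerance = 1e-5)
    expect_error(cvPercent(3), "at least 2")
    expect_error(cvPercent(c(-1, 1)), "zero mean")
})

test_that("CV percent is scale-invariant", {
    set.seed(5)
    for (i in 1:10) {
        x <- exp(rnorm(8, 2, 0.5))
        cc <- runif(1, 1e-3, 1e3)
        expect_equal(cvPercent(cc * x), cvPercent(x))
    }
})

test_that("Kruskal-Wallis wrapper matches the rank-sum formula", {
    # hand oracle (no ties): H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)
    a <- c(1, 2, 3); b <- c(100, 101, 102)
    r <- rank(c(a, b))
    H_oracle <- 12 / (6 * 7) * (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * 7
    res <- kruskalWallisBatchTest(c(a, b), rep(c("g1", "g2"), each = 3))
    expect_equal(res$statistic, H_oracle)
    expect_equal(res$p.value, 1 - pchisq(H_oracle, 1))
    # identically distributed groups: small H, p far from significance
    res2 <- kruskalWallisBatchTest(c(1, 2, 3, 1, 2, 3),
                                   rep(c("g1", "g2"), 3))
    expect_lt(res2$statistic, 1)
    expect_gt(res2$p.value, 0.5)
})

test_that("total ties yield H = 0 with p = 1 by policy", {
    res <- kruskalWallisBatchTest(rep(7, 8), rep(c("a", "b"), 4))
    expect_identical(res$statistic, 0)
    expect_identical(res$p.value, 1)
    expect_error(kruskalWallisBatchTest(1:4, rep("a", 4)), "at least 2")
})

test_that("QCS report pools intraday and interday CVs as defined", {
    # two days of constants: all CVs zero
    ft <- makeToyTable(matrix(10, 12, 1),
                       slides = rep(c("S01", "S02", "S03", "S04"), each = 3),
                       days = rep(c("day1", "day2"), each = 6),
                       roles = "analyte")
    rep0 <- qcsCVReport(ft)
    expect_equal(rep0@intraday$cv, c(0, 0))
    expect_equal(rep0@interday, 0)
    # day-level shift: intraday CVs zero, interday equals the pooled formula
    v <- c(rep(10, 6), rep(20, 6))
    ft2 <- makeToyTable(matrix(v, 12, 1),
                        slides = rep(c("S01", "S02", "S03", "S04"), each = 3),
                        days = rep(c("day1", "day2"), each = 6),
                        roles = "analyte")
    rep2 <- qcsCVReport(ft2)
    expect_equal(rep2@intraday$cv, c(0, 0))
    expect_equal(rep2@interday, cvPercent(v))
    # a single-slide day: the slide CV equals that day's CV
    expect_equal(rep2@perSlide$cv[rep2@perSlide$slide_id == "S01"],
                 cvPercent(v[1:3]))
})

test_that("report marks under-populated cells as NA instead of dropping", {
    ft <- makeToyTable(matrix(c(5, 6, 7), 3, 1),
                       slides = c("S01", "S01", "S02"),
                       days = c("day1", "day1", "day2"), roles = "analyte")
    rep1 <- qcsCVReport(ft)
    expect_true(is.na(rep1@intraday$cv[rep1@intraday$day == "day2"]))
    expect_equal(nrow(rep1@intraday), 2L)       # day2 cell present, marked NA
    expect_true(is.na(rep1@perSlide$cv[rep1@perSlide$slide_id == "S02"]))
})

test_that("outlier rule flags a clearly attenuated slide and only it", {
    med <- c(100, 98, 103, 101, 99, 15)
    m <- matrix(rep(med, each = 4) * rep(c(0.98, 1, 1.01, 1.02), 6), 24, 1,
                byrow = FALSE)
    ft <- makeToyTable(m, slides = rep(sprintf("S%02d", 1:6), each = 4),
                       roles = "analyte")
    out <- detectOutlierSlides(ft)
    expect_identical(out$slide_id[out$flagged], "S06")
    # equal medians: nothing flagged
    ft_eq <- makeToyTable(matrix(rep(c(9, 10, 11), 6), 18, 1),
                          slides = rep(sprintf("S%02d", 1:6), each = 3),
                          roles = "analyte")
    expect_false(any(detectOutlierSlides(ft_eq)$flagged))
    expect_error(detectOutlierSlides(
        makeToyTable(matrix(1:4, 4, 1), slides = rep(c("S01", "S02"), 2),
                     roles = "analyte")), "3 slides")
})

test_that("zero MAD falls back to exact-inequality flagging", {
    ft <- makeToyTable(matrix(c(rep(10, 12), rep(2, 3)), 15, 1),
                       slides = rep(sprintf("S%02d", 1:5), each = 3),
                       roles = "analyte")
    out <- detectOutlierSlides(ft)
    expect_identical(out$slide_id[out$flagged], "S05")
    expect_true(is.infinite(out$score[out$slide_id == "S05"]))
})

test_that("drift profile recovers an injected log-linear slope", {
    n <- 30
    slope <- -0.5
    m <- matrix(exp(8 + slope * seq_len(n)), n, 1)
    ft <- makeToyTable(m, slides = rep(sprintf("S%02d", 1:5), each = 6),
                       roles = "analyte")
    prof <- driftProfile(ft)
    expect_equal(prof$slope, slope, tolerance = 1e-10)
    # constant series: zero slope
    flat <- makeToyTable(matrix(5, n, 1),
                         slides = rep(sprintf("S%02d", 1:5), each = 6),
                         roles = "analyte")
    expect_equal(driftProfile(flat)$slope, 0, tolerance = 1e-12)
})

test_that("before/after tissue contrast is paired per slide", {
    # slide: 2 QCS, 1 tissue, 2 QCS; after-values lower by 1 on log scale
    vals <- exp(c(5, 5, 9, 4, 4,   5, 5, 9, 5, 5))
    region <- rep(c("qcs", "qcs", "tissue", "qcs", "qcs"), 2)
    ft <- makeToyTable(matrix(vals, 10, 1),
                       slides = rep(c("S01", "S02"), each = 5),
                       region = region, roles = "analyte")
    prof <- driftProfile(ft)
    d <- prof$contrast
    expect_equal(d$delta[d$slide_id == "S01"], -1)
    expect_equal(d$delta[d$slide_id == "S02"], 0)
    # no tissue on the slide: contrast not available
    ft2 <- makeToyTable(matrix(exp(c(5, 6)), 2, 1), roles = "analyte")
    expect_true(is.na(driftProfile(ft2)$contrast$delta))
})
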