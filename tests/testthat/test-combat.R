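# fixture: two batches with a known additive offset and scale change on the
# log scale, lognormal data
makeBatchTable <- function(n_per_batch = 40, p = 10, offset = 0, scale2 = 1,
                           seed = 1, sigma = 0.3) {
    set.seed(seed)
    n <- 2 * n_per_batch
    day <- rep(c("day1", "day2"), each = n_per_batch)
    mu <- rnorm(p, 5, 1)
    y <- matrix(rnorm(n * p, 0, sigma), n, p)
    y[day == "day2", ] <- y[day == "day2", ] * scale2 + offset
    m <- exp(sweep(y, 2, mu, "+"))
    colnames(m) <- paste0("mz", seq_len(p) + 100)
    om <- data.frame(obs_id = sprintf("o%03d", seq_len(n)),
                     slide_id = rep(sprintf("S%02d", seq_len(ceiling(n / 4))),
                                    each = 4, length.out = n),
                     day = day, measurement_order = seq_len(n),
                     region_type = "qcs", group = "", stringsAsFactors = FALSE)
    FeatureTable(m, om)
}

test_that("single batch reduces to a standardize/restore round trip", {
    ft <- makeBatchTable(20, 5)
    one <- ft[, obsMeta(ft)$day == "day1"]
    res <- combatCorrect(one)
    expect_lt(max(abs(intensities(res@table) - intensities(one))), 1e-8)
    expect_match(paste(res@log, collapse = " "), "single batch")
})

test_that("an injected additive log offset is removed at large n", {
    delta <- 1.2
    ft <- makeBatchTable(200, 10, offset = delta, seed = 3)
    res <- combatCorrect(ft)
    y <- log(intensities(res@table))
    day <- obsMeta(ft)$day
    gaps <- abs(colMeans(y[day == "day2", ]) - colMeans(y[day == "day1", ]))
    expect_lt(max(gaps), 0.05 * delta)
})

test_that("an injected 4:1 variance ratio is equalized at large n", {
    ft <- makeBatchTable(200, 10, scale2 = 2, seed = 4)   # var ratio 4
    res <- combatCorrect(ft)
    y <- log(intensities(res@table))
    day <- obsMeta(ft)$day
    v1 <- apply(y[day == "day1", ], 2, var)
    v2 <- apply(y[day == "day2", ], 2, var)
    expect_true(all(pmax(v1, v2) / pmin(v1, v2) < 1.2))
})

test_that("grand mean per feature is preserved on balanced designs", {
    # modest batch shift: the log-scale adjustment is mean-neutral and the
    # residual linear-scale (Jensen) deviation stays below 1%
    ft <- makeBatchTable(50, 8, offset = 0.15, seed = 5)
    res <- combatCorrect(ft)
    pre <- colMeans(intensities(ft))
    post <- colMeans(intensities(res@table))
    expect_true(all(abs(post - pre) / pre < 0.01))
})

test_that("EB shrinkage interpolates between batch and pooled estimates", {
    g_hat <- 0.8; g_bar <- 0.1; d2 <- 1.3; n <- 12
    wide <- msibatch:::.combatShrinkGamma(g_hat, d2, n, g_bar, tau2 = 1e8)
    narrow <- msibatch:::.combatShrinkGamma(g_hat, d2, n, g_bar, tau2 = 1e-12)
    expect_equal(wide, g_hat, tolerance = 1e-6)
    expect_equal(narrow, g_bar, tolerance = 1e-6)
    # monotone path between the limits
    taus <- 10^seq(-6, 4, length.out = 30)
    path <- sapply(taus, function(t2)
        msibatch:::.combatShrinkGamma(g_hat, d2, n, g_bar, t2))
    expect_true(all(diff(path) > 0))
    expect_true(all(path >= g_bar & path <= g_hat))
})

test_that("native EB fit agrees with the reference implementation", {
    ft <- makeBatchTable(30, 25, offset = 0.5, scale2 = 1.5, seed = 8)
    eps <- 0.5 * min(intensities(ft))
    res <- combatCorrect(ft, eps = eps)
    ref <- suppressMessages(sva::ComBat(
        dat = t(log(intensities(ft) + eps)),
        batch = obsMeta(ft)$day, mod = NULL, par.prior = TRUE,
        prior.plots = FALSE))
    own <- t(log(intensities(res@table) + eps))
    expect_lt(max(abs(own - ref)), 1e-5)
})

test_that("degenerate batches and features are handled explicitly", {
    ft <- makeBatchTable(10, 4)
    om <- obsMeta(ft)
    lone <- ft[, c(which(om$day == "day1"), which(om$day == "day2")[1])]
    expect_error(combatCorrect(lone), ">= 2 observations")
    # constant feature: passed through unchanged, with a log entry
    m <- intensities(ft)
    m[, 2] <- 7
    ft2 <- makeToyTable(m, slides = om$slide_id, days = om$day)
    res <- combatCorrect(ft2)
    expect_match(paste(res@log, collapse = " "), "zero-variance")
    expect_equal(unname(intensities(res@table)[, 2]), rep(7, nrow(m)))
})

test_that("the fitted model satisfies its structural constraints", {
    ft <- makeBatchTable(25, 12, offset = 0.4, seed = 10)
    res <- combatCorrect(ft)
    mod <- res@model
    expect_true(mod@converged)
    expect_true(all(mod@delta2Star > 0))
    # weighted constraint sum_i n_i gamma_hat = 0 per feature
    w <- as.numeric(mod@batchSizes)
    expect_lt(max(abs(mod@gammaHat %*% w)), 1e-8)
})
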