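# brute-force geometry oracles used against the score-space metrics
bruteIntragroup <- function(pts, g) {
    per <- tapply(seq_len(nrow(pts)), g, function(i) {
        ctr <- colMeans(pts[i, , drop = FALSE])
        mean(apply(pts[i, , drop = FALSE], 1,
                   function(p) sqrt(sum((p - ctr)^2))))
    })
    mean(per)
}
bruteIntergroup <- function(pts, g) {
    ctrs <- do.call(rbind, tapply(seq_len(nrow(pts)), g, function(i)
        colMeans(pts[i, , drop = FALSE])))
    d <- as.matrix(dist(ctrs))
    mean(d[upper.tri(d)])
}

test_that("PCA of collinear data loads a single component", {
    t_ <- seq(-2, 2, length.out = 12)
    x <- cbind(3 * t_, -1 * t_, 0.5 * t_) + 10
    pc <- pcaScores(x, n_components = 2, scale = FALSE)
    expect_gt(pc@explained[1], 1 - 1e-10)
})

test_that("orthogonal rotation leaves the variance spectrum unchanged", {
    set.seed(12)
    x <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
    q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    p1 <- pcaScores(x, scale = FALSE)
    p2 <- pcaScores(x %*% q, scale = FALSE)
    expect_equal(p1@explained, p2@explained, tolerance = 1e-10)
})

test_that("PCA handles duplicates, sign convention and bad inputs", {
    set.seed(13)
    x <- matrix(rnorm(30), 10, 3)
    x[2, ] <- x[1, ]
    pc <- pcaScores(x, n_components = 2, scale = FALSE)
    expect_equal(pc@scores[1, ], pc@scores[2, ])
    # deterministic sign: dominant loading positive
    for (a in 1:2) {
        expect_gt(pc@loadings[which.max(abs(pc@loadings[, a])), a], 0)
    }
    expect_error(pcaScores(x, n_components = 5), "exceeds")
    x0 <- cbind(x, 7)   # zero-variance column dropped when scaling
    expect_message(pcaScores(x0), "zero-variance")
})

test_that("intragroup distance matches the geometry oracle", {
    three <- rbind(c(1, 2), c(1, 2), c(1, 2))
    expect_equal(intragroupDistance(three, rep("a", 3))$average, 0)
    two <- rbind(c(0, 0), c(2, 0))
    expect_equal(intragroupDistance(two, rep("a", 2))$average, 1)
    square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    expect_equal(intragroupDistance(square, rep("a", 4))$average,
                 bruteIntragroup(square, rep("a", 4)), tolerance = 1e-12)
    expect_equal(intragroupDistance(square, rep("a", 4))$average, sqrt(2) / 2)
    expect_error(intragroupDistance(matrix(1:3, 3, 1), rep("a", 3)),
                 "2 score components")
})

test_that("intergroup distance averages pairwise centroid distances", {
    pts <- rbind(c(0, 0), c(3, 4))
    expect_equal(intergroupDistance(pts, c("a", "b"))$average, 5)
    co <- rbind(c(1, 1), c(1, 1))
    expect_equal(intergroupDistance(co, c("a", "b"))$average, 0)
    tri <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
    expect_equal(intergroupDistance(tri, c("a", "b", "c"))$average,
                 bruteIntergroup(tri, c("a", "b", "c")), tolerance = 1e-12)
    expect_equal(intergroupDistance(tri, c("a", "b", "c"))$average, 2)
    expect_error(intergroupDistance(pts, c("a", "a")), "2 groups")
})

test_that("distances are invariant to observation order and rotation", {
    set.seed(14)
    pts <- matrix(rnorm(24), 12, 2)
    g <- rep(c("a", "b", "c"), 4)
    perm <- sample(12)
    expect_equal(intragroupDistance(pts, g)$average,
                 intragroupDistance(pts[perm, ], g[perm])$average)
    th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(intergroupDistance(pts, g)$average,
                 intergroupDistance(pts %*% R, g)$average)
})

test_that("QCS proximity separates corrected from uncorrected tables", {
    # identical QCS spots: distance exactly 0
    set.seed(15)
    tis <- exp(matrix(rnorm(6 * 5, 5, 1), 6, 5))
    qcs <- matrix(rep(exp(c(4, 5, 6, 4.5, 5.5)), each = 6), 6, 5)
    m <- rbind(qcs, tis)
    ft <- makeToyTable(m, region = rep(c("qcs", "tissue"), each = 6),
                       groups = rep(c("", "g1"), each = 6),
                       slides = rep(sprintf("S%02d", 1:6), 2))
    expect_lt(suppressMessages(qcsProximity(list(perfect = ft)))[[1]], 1e-10)
    # known multiplicative slide effect: removing it shrinks the distance
    eff <- rep(exp(c(-0.6, 0, 0.6)), each = 2)
    m2 <- rbind(qcs * eff, tis)
    ft2 <- makeToyTable(m2, region = rep(c("qcs", "tissue"), each = 6),
                        groups = rep(c("", "g1"), each = 6),
                        slides = rep(sprintf("S%02d", 1:6), 2))
    d <- suppressMessages(qcsProximity(list(raw = ft2, fixed = ft)))
    expect_gt(d[["raw"]], d[["fixed"]])
})

test_that("mean squared VIP equals one for any fit", {
    set.seed(16)
    for (i in 1:5) {
        x <- matrix(rnorm(40 * 15), 40, 15)
        g <- sample(rep(c("a", "b", "c"), length.out = 40))
        v <- plsdaVIP(x, g)
        expect_equal(mean(v@vip^2), 1, tolerance = 1e-8)
    }
})

test_that("a strongly informative feature is selected in every replicate", {
    hits <- 0L
    for (seed in 1:20) {
        set.seed(seed)
        n <- 40
        g <- rep(c("a", "b"), each = n / 2)
        x <- matrix(rnorm(n * 50), n, 50)
        x[g == "b", 1] <- x[g == "b", 1] + 3     # 3-sigma group shift
        colnames(x) <- paste0("f", 1:50)
        v <- plsdaVIP(x, g, n_components = 1)
        hits <- hits + (names(which.max(v@vip)) == "f1" && v@vip["f1"] > 1.2)
    }
    expect_identical(hits, 20L)
})

test_that("permuted labels rarely promote the informative feature", {
    set.seed(17)
    n <- 40
    g <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 50), n, 50)
    x[g == "b", 1] <- x[g == "b", 1] + 3
    colnames(x) <- paste0("f", 1:50)
    hits <- sum(vapply(1:50, function(i) {
        v <- plsdaVIP(x, sample(g), n_components = 1)
        v@vip["f1"] > 1.2
    }, TRUE))
    expect_lte(hits, 10L)   # <= 20% of 50 permutations
})

test_that("native VIP ranking agrees with an independent PLS-DA fit", {
    set.seed(18)
    n <- 36
    g <- rep(c("a", "b", "c"), each = n / 3)
    x <- matrix(rnorm(n * 30), n, 30)
    x[g == "b", 2] <- x[g == "b", 2] + 2.5
    x[g == "c", 5] <- x[g == "c", 5] + 2.5
    colnames(x) <- paste0("f", 1:30)
    own <- plsdaVIP(x, g, n_components = 2)
    ref <- suppressMessages(mixOmics::plsda(x, factor(g), ncomp = 2))
    ref_vip <- mixOmics::vip(ref)[, 2]
    expect_gt(cor(own@vip, ref_vip, method = "spearman"), 0.85)
    expect_setequal(names(sort(own@vip, decreasing = TRUE))[1:2],
                    names(sort(ref_vip, decreasing = TRUE))[1:2])
})

test_that("robustness grid crosses selections into robust and dropped sets", {
    v <- function(scores) {
        vip <- scores / sqrt(mean(scores^2))
        new("VIPResult", vip = vip, ncomp = 1L, threshold = 1.2,
            selected = names(vip)[vip > 1.2], explainedY = 1)
    }
    base <- c(f1 = 3, f2 = 2, f3 = 0.5, f4 = 0.4, f5 = 0.3)
    raw <- v(base)
    same <- v(base)
    cmp <- robustFeatureComparison(list(raw = raw, combat = same))
    expect_setequal(cmp$robust, raw@selected)
    expect_length(cmp$dropped, 0L)
    # a raw-only hit lands in the dropped set
    corr <- v(c(f1 = 3, f2 = 0.1, f3 = 0.5, f4 = 0.4, f5 = 2))
    cmp2 <- robustFeatureComparison(list(raw = raw, combat = corr))
    expect_identical(cmp2$dropped, "f2")
    expect_identical(cmp2$robust, "f1")
    bad <- v(c(g1 = 1, g2 = 1, g3 = 1, g4 = 1, g5 = 1))
    expect_error(robustFeatureComparison(list(raw = raw, x = bad)),
                 "mismatched")
})
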