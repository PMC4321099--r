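test_that("probe tables round-trip through write and read", {
    set.seed(42)
    for (twoChannel in c(FALSE, TRUE)) {
        tab <- randomProbeTable(25, twoChannel)
        s <- ArraySample(tab, arm = if (twoChannel) "mrna_total"
                                    else "mirna")
        path <- tempfile(fileext = ".tsv")
        writeProbeTable(s, path)
        back <- readProbeTable(path, arm = arm(s))
        expect_equal(probes(back)$cy5, tab$cy5)
        expect_equal(probes(back)$cy3, tab$cy3)
        expect_identical(probes(back)$flag, tab$flag)
        expect_identical(probes(back)$feature_id, tab$feature_id)
        unlink(path)
    }
})

test_that("probe table reader reports format problems precisely", {
    tab <- randomProbeTable(5)
    path <- tempfile(fileext = ".tsv")
    utils::write.table(tab[setdiff(names(tab), "flag")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readProbeTable(path), "flag")

    tab$cy5[3] <- -4
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readProbeTable(path), "negative intensity.*4")
    unlink(path)
})

test_that("flag filtering keeps exactly the nonnegative flags", {
    s <- ArraySample(data.frame(probe_id = c("a", "b", "c"),
                                feature_id = c("x", "y", "z"),
                                cy5 = c(1, 2, 3), cy3 = NA_real_,
                                flag = c(0L, -50L, 100L)))
    f <- suppressMessages(filterFlags(s))
    expect_identical(probes(f)$probe_id, c("a", "c"))

    set.seed(7)
    tab <- randomProbeTable(200)
    s <- ArraySample(tab)
    f <- suppressMessages(filterFlags(s))
    # brute-force oracle
    expect_identical(probes(f)$probe_id, tab$probe_id[tab$flag >= 0])

    allGood <- ArraySample(within(tab, flag <- abs(flag)))
    expect_identical(probes(suppressMessages(filterFlags(allGood))),
                     probes(allGood))
})

test_that("percentile scaling matches the stated rule", {
    mk <- function(vals) ArraySample(data.frame(
        probe_id = sprintf("p%d", seq_along(vals)),
        feature_id = sprintf("f%d", seq_along(vals)),
        cy5 = vals, cy3 = NA_real_, flag = 0L))
    # samples whose 75th percentiles are exactly 100 and 400: the
    # cohort reference is their geometric mean 200, factors 2.0 and 0.5
    s1 <- mk(c(10, 20, 100, 100))
    s2 <- mk(c(40, 80, 400, 400))
    expect_equal(unname(quantile(probes(s1)$cy5, 0.75)), 100)
    expect_equal(unname(quantile(probes(s2)$cy5, 0.75)), 400)
    out <- suppressMessages(percentileScaleNormalize(list(s1, s2)))
    expect_equal(attr(out, "scaleFactors"), c(2, 0.5))
    expect_equal(unname(quantile(probes(out[[1]])$cy5, 0.75)), 200)
    expect_equal(unname(quantile(probes(out[[2]])$cy5, 0.75)), 200)

    # single sample: reference is itself, factor 1
    single <- suppressMessages(percentileScaleNormalize(list(s2)))
    expect_equal(attr(single, "scaleFactors"), 1)

    # scaling preserves within-sample ratios
    r0 <- probes(s2)$cy5 / probes(s2)$cy5[1]
    r1 <- probes(out[[2]])$cy5 / probes(out[[2]])$cy5[1]
    expect_equal(r0, r1)

    # idempotence: a second application is the identity
    out2 <- suppressMessages(percentileScaleNormalize(out))
    expect_true(all(abs(attr(out2, "scaleFactors") - 1) < 1e-12))

    # all-zero sample is an error
    expect_error(suppressMessages(
        percentileScaleNormalize(list(mk(c(0, 0, 0, 0))))),
        "non-positive")
})

test_that("stage order is pinned: filtering before scaling matters", {
    set.seed(11)
    tab <- randomProbeTable(100)
    tab$flag <- 0L
    bright <- order(tab$cy5, decreasing = TRUE)[1:20]
    tab$flag[bright] <- -50L        # flagged spots are the brightest
    s <- ArraySample(tab)
    filteredFirst <- suppressMessages(
        percentileScaleNormalize(list(filterFlags(s)),
                                 reference = "constant"))
    unfiltered <- suppressMessages(
        percentileScaleNormalize(list(s), reference = "constant"))
    expect_false(isTRUE(all.equal(attr(filteredFirst, "scaleFactors"),
                                  attr(unfiltered, "scaleFactors"))))
})

.mkTwoColour <- function(n, M, A, probeIds = sprintf("p%03d", seq_len(n))) {
    ArraySample(data.frame(
        probe_id = probeIds, feature_id = sprintf("g%03d", seq_len(n)),
        cy5 = 2^(A + M / 2), cy3 = 2^(A - M / 2), flag = 0L),
        arm = "mrna_total")
}

test_that("LOWESS leaves a flat null untouched", {
    set.seed(1)
    A <- runif(200, 4, 14)
    s <- .mkTwoColour(200, M = rep(0, 200), A = A)
    out <- lowessNormalize(s)
    M <- log2(probes(out)$cy5 / probes(out)$cy3)
    expect_true(all(abs(M) < 1e-9))
})

test_that("LOWESS removes planted intensity-dependent curvature", {
    set.seed(2)
    A <- runif(500, 4, 14)
    M <- 0.5 * A + rnorm(500, 0, 0.05)
    s <- .mkTwoColour(500, M = M, A = A)
    out <- lowessNormalize(s, rankTolerance = 0.1)
    fitset <- attr(out, "fitSet")
    Mc <- log2(probes(out)$cy5 / probes(out)$cy3)
    expect_lt(median(abs(Mc[fitset])), 0.05)
})

test_that("a genuine 4-fold differential probe survives LOWESS", {
    set.seed(3)
    n <- 400
    A <- runif(n, 4, 14)
    M <- rnorm(n, 0, 0.05)
    M[1] <- 2                      # 4-fold up, rank-inconsistent
    A[1] <- 9
    s <- .mkTwoColour(n, M = M, A = A)
    out <- lowessNormalize(s)
    Mc <- log2(probes(out)$cy5 / probes(out)$cy3)
    expect_gte(abs(Mc[1]), 1.8)
})

test_that("LOWESS demands enough rank-consistent probes", {
    set.seed(4)
    n <- 40
    # anti-rank construction: cy5 ascending, cy3 descending
    s <- ArraySample(data.frame(
        probe_id = sprintf("p%02d", 1:n), feature_id = sprintf("g%02d", 1:n),
        cy5 = sort(runif(n, 10, 1000)),
        cy3 = sort(runif(n, 10, 1000), decreasing = TRUE),
        flag = 0L), arm = "mrna_total")
    expect_error(lowessNormalize(s, rankTolerance = 0.01),
                 "rank-consistent")
    expect_error(lowessNormalize(
        ArraySample(randomProbeTable(10), arm = "mirna")), "two-channel")
})

test_that("log2 ratios match elementwise division", {
    mk <- function(vals, feat = sprintf("f%d", seq_along(vals)))
        ArraySample(data.frame(probe_id = sprintf("p%d", seq_along(vals)),
                               feature_id = feat, cy5 = vals,
                               cy3 = NA_real_, flag = 0L))
    expect_equal(computeLog2Ratio(mk(400), mk(100))$log2_ratio, 2)
    expect_equal(computeLog2Ratio(mk(123), mk(123))$log2_ratio, 0)

    set.seed(5)
    a <- runif(50, 1, 1e4); b <- runif(50, 1, 1e4)
    r <- computeLog2Ratio(mk(a), mk(b))
    feat <- sprintf("f%d", 1:50)
    expect_equal(r$log2_ratio[match(feat, r$feature_id)], log2(a / b))

    # within-array two-colour convention
    s <- .mkTwoColour(30, M = log2(a[1:30] / b[1:30]),
                      A = rep(10, 30))
    r2 <- computeLog2Ratio(s)
    expect_equal(r2$log2_ratio[match(sprintf("g%03d", 1:30),
                                     r2$feature_id)],
                 log2(a[1:30] / b[1:30]))
    expect_error(computeLog2Ratio(mk(1)), "control")
})

test_that("duplicate probes for a feature collapse by median", {
    s <- ArraySample(data.frame(
        probe_id = c("p1", "p2", "p3"), feature_id = c("f1", "f1", "f1"),
        cy5 = c(100, 200, 800), cy3 = NA_real_, flag = 0L))
    ctrl <- ArraySample(data.frame(
        probe_id = "q1", feature_id = "f1", cy5 = 100, cy3 = NA_real_,
        flag = 0L))
    expect_equal(computeLog2Ratio(s, ctrl)$log2_ratio, 1)  # median 200
})

test_that("ratio matrix drops features missing anywhere and keeps metadata", {
    d <- smallStudy(31, flagFraction = 0.1)
    sim <- simulateMirnaArrays(d)
    suppressMessages({
        filtered <- lapply(sim$samples, filterFlags)
        re <- ratioMatrix(filtered, "mirna")
    })
    mat <- SummarizedExperiment::assay(re, "log2ratio")
    expect_true(all(is.finite(mat)))
    cd <- SummarizedExperiment::colData(re)
    expect_setequal(unique(cd$genotype),
                    c("wildtype", "tlr4_ko", "nfkb_ko"))
    # features flagged out somewhere are gone
    flaggedSomewhere <- unique(unlist(lapply(sim$samples, function(s) {
        p <- probes(s); p$feature_id[p$flag < 0]
    })))
    expect_length(intersect(rownames(mat), flaggedSomewhere), 0)
})
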