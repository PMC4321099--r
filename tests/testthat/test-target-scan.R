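test_that("a perfect embedded duplex scores maximally with a matched seed", {
    set.seed(91)
    m <- randomRna(22)
    site <- chartr("U", "T", rnaRevComp(m))
    utr <- paste0(randomDna(40), site, randomDna(40))
    hits <- alignDuplex(m, utr)
    expect_gte(nrow(hits), 1)
    top <- hits[1, ]
    p <- scanParams()
    # 22 WC pairs, 7 of them (positions 2-8) doubled
    expect_equal(top$score, (22 - 7) * p$match + 7 * p$match * 2)
    expect_true(top$seed_matched)
    expect_equal(top$start, 40)
    expect_equal(top$end, 40 + 22)
    expect_identical(top$trace, strrep("M", 22))
})

test_that("unpairable sequences yield no sites", {
    hits <- alignDuplex(strrep("A", 22), strrep("A", 60))
    expect_equal(nrow(hits), 0)
    expect_error(alignDuplex("ACGUXCGUACGUACGUACGUAC", strrep("A", 30)),
                 "non-canonical")
    expect_error(alignDuplex("ACGU", strrep("A", 30)), "18-26")
})

test_that("a threshold above the attainable score empties the result", {
    m <- randomRna(22)
    utr <- paste0("AAAA", chartr("U", "T", rnaRevComp(m)), "AAAA")
    p <- scanParams(minScore = 1000)
    expect_equal(nrow(alignDuplex(m, utr, p)), 0)
})

test_that("reported scores equal their re-scored traces", {
    set.seed(92)
    p <- scanParams(minScore = 40)
    for (i in 1:25) {
        m <- randomRna(sample(18:26, 1))
        utr <- paste0(randomDna(30), chartr("U", "T", rnaRevComp(m)),
                      randomDna(30))
        hits <- alignDuplex(m, utr, p)
        for (k in seq_len(nrow(hits)))
            expect_equal(rescoreAlignment(hits[k, ], m, utr, p),
                         hits$score[k])
    }
})

test_that("production aligner equals the exhaustive DP oracle", {
    set.seed(93)
    p <- scanParams(minScore = 0)
    for (i in 1:40) {
        m <- randomRna(sample(18:26, 1))
        utr <- randomDna(sample(40:120, 1))
        hits <- alignDuplex(m, utr, p)
        got <- if (nrow(hits)) max(hits$score) else 0
        expect_equal(got, oracleDuplexScore(m, utr, p))
    }
})

test_that("score is symmetric under joint sequence-and-weight reversal", {
    set.seed(94)
    p <- scanParams()
    Lm <- 22
    w <- ifelse(seq_len(Lm) >= p$seedStart & seq_len(Lm) <= p$seedEnd,
                p$seedMultiplier, 1)
    for (i in 1:10) {
        m <- randomRna(Lm)
        utr <- randomDna(90)
        rev1 <- paste(rev(strsplit(m, "")[[1]]), collapse = "")
        rev2 <- paste(rev(strsplit(utr, "")[[1]]), collapse = "")
        expect_equal(oracleDuplexScore(m, utr, p, weights = w),
                     oracleDuplexScore(rev1, rev2, p, weights = rev(w)))
    }
})

test_that("flanking background never lowers the best site score", {
    set.seed(95)
    p <- scanParams(minScore = 0)
    best <- function(m, u) {
        h <- alignDuplex(m, u, p)
        if (nrow(h)) max(h$score) else 0
    }
    for (i in 1:10) {
        m <- randomRna(22)
        core <- randomDna(60)
        extended <- paste0(randomDna(25), core, randomDna(25))
        expect_gte(best(m, extended), best(m, core))
    }
})

test_that("overlapping sites are suppressed greedily, best first", {
    set.seed(96)
    m <- randomRna(22)
    site <- chartr("U", "T", rnaRevComp(m))
    utr <- paste0(randomDna(20), site, randomDna(15), site, randomDna(20))
    hits <- alignDuplex(m, utr)
    expect_gte(nrow(hits), 2)
    expect_true(all(diff(hits$score) <= 0))        # best-first
    # reported intervals are pairwise disjoint
    if (nrow(hits) > 1) {
        ord <- order(hits$start)
        expect_true(all(hits$start[ord][-1] >=
                        hits$end[ord][-length(ord)]))
    }
})

test_that("seed scan finds exact seed complements", {
    # planted site: exactly one 7mer-m8 hit at the recorded offset
    d <- smallStudy(97)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    sq <- simulateSequences(d, mr$ledger)
    ps <- plantedSites(sq$ledger)
    row <- ps[1, ]
    hits <- seedMatchScan(as.character(sq$mirna[[row$mirna]]),
                          as.character(sq$utr[[row$gene]]))
    m8 <- hits[hits$type == "7mer-m8", ]
    expect_true(row$seed_offset %in% m8$offset)

    # a let-7-like seed: GAGGUAG at positions 2-8 pairs CUACCUC
    mirna <- paste0("U", "GAGGUAG", randomRna(14))
    utr <- paste0("GGGG", "CTACCTC", "GGGG")
    hits <- seedMatchScan(mirna, utr)
    expect_equal(hits$offset[hits$type == "7mer-m8"], 4)

    # 7mer-A1: positions 2-7 complemented with an A opposite position 1
    utrA1 <- paste0("GGGG", "TACCTC", "A", "GGGG")
    hitsA1 <- seedMatchScan(mirna, utrA1)
    expect_equal(hitsA1$offset[hitsA1$type == "7mer-A1"], 4)
})

test_that("chance seed-match counts follow the closed form", {
    set.seed(98)
    m <- randomRna(22)
    L <- 300
    n <- 400
    counts <- vapply(seq_len(n), function(i)
        sum(seedMatchScan(m, randomDna(L))$type == "7mer-m8"),
        numeric(1))
    expected <- (L - 6) / 4^7
    expect_lt(abs(mean(counts) - expected), 4 * sqrt(expected / n))
})

test_that("predicted target sets honour threshold, seed and ordering", {
    d <- smallStudy(99)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    sq <- simulateSequences(d, mr$ledger)
    pred <- predictTargets(sq$mirna, sq$utr)
    planted <- split(plantedSites(sq$ledger)$gene,
                     plantedSites(sq$ledger)$mirna)
    for (m in names(planted))
        expect_true(all(planted[[m]] %in% pred[[m]]))
    # genes without any planted or chance site stay absent
    sites <- attr(pred, "sites")
    for (m in names(pred))
        expect_true(all(pred[[m]] %in% sites$gene[sites$mirna == m]))
    # impossible threshold empties every set
    predNone <- predictTargets(sq$mirna, sq$utr,
                               scanParams(minScore = 1e6))
    expect_true(all(lengths(predNone) == 0))
})
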