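test_that("design validity rejects impossible layouts", {
    expect_error(SimDesign(nMirnaProbes = 2, nResponsive = 3,
                           nUpregulated = 0),
                 "exceeds")
    expect_error(SimDesign(flagFraction = 1), "flagFraction")
    expect_error(SimDesign(noiseSd = 0), "noiseSd")
    expect_error(SimDesign(genotypes = "mutant"), "genotypes")
})

test_that("ledger lists exactly the designed responsive miRNAs", {
    sim <- simulateMirnaArrays(smallStudy(1, nResponsive = 3))
    expect_length(responsiveMirnas(sim$ledger), 3)
    up <- upregulatedByTimepoint(sim$ledger)
    expect_true(all(responsiveMirnas(sim$ledger) %in% up[["rep1d"]]))
})

test_that("planted miRNA effects land where designed", {
    d <- smallStudy(5, nMirnaProbes = 60, noiseSd = 0.1)
    sim <- simulateMirnaArrays(d)
    suppressMessages({
        re <- ratioMatrix(sim$samples, "mirna")
    })
    fold <- genotypeFoldTable(re)
    resp <- responsiveMirnas(sim$ledger)
    rows <- fold[fold$feature_id %in% resp, ]
    expect_true(all(rows$wildtype > 1.5))
    expect_true(all(rows$tlr4_ko < -1.5))
    expect_true(all(rows$nfkb_ko < -1.5))
    upOnly <- setdiff(up <- upregulatedByTimepoint(sim$ledger)[["rep1d"]],
                      resp)
    expect_true(all(fold[fold$feature_id %in% upOnly, "tlr4_ko"] > 1.5))
})

test_that("flagged-spot count stays inside the binomial 99% interval", {
    d <- SimDesign(nMirnaProbes = 1000, flagFraction = 0.1, seed = 7,
                   genotypes = "wildtype", timepoints = "rep1d",
                   nResponsive = 0, nUpregulated = 0)
    sim <- simulateMirnaArrays(d)
    bounds <- qbinom(c(0.005, 0.995), 1000, 0.1)
    for (s in sim$samples) {
        nflag <- sum(probes(s)$flag < 0)
        expect_gte(nflag, bounds[1])
        expect_lte(nflag, bounds[2])
    }
})

test_that("planted target genes carry the designed expression signature", {
    d <- smallStudy(3, noiseSd = 0.2)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    suppressMessages({
        tot <- ratioMatrix(mr$samples, "mrna_total")
        ip <- ratioMatrix(mr$samples, "mrna_ago2ip")
    })
    targets <- unique(targetPairs(mr$ledger)$gene)
    mTot <- rowMeans(SummarizedExperiment::assay(tot, "log2ratio"))
    mIp <- rowMeans(SummarizedExperiment::assay(ip, "log2ratio"))
    # planted -2 / +2 realized within noise
    expect_true(all(abs(mTot[targets] + 2) < 1))
    expect_true(all(abs(mIp[targets] - 2) < 1))
    dc <- decoys(mr$ledger)
    downOnly <- dc$gene[dc$class == "down_only"]
    ipOnly <- dc$gene[dc$class == "ip_only"]
    siteOnly <- dc$gene[dc$class == "site_only"]
    expect_true(all(mTot[downOnly] < -1))
    expect_true(all(abs(mIp[downOnly]) < 1))
    expect_true(all(mIp[ipOnly] > 1))
    expect_true(all(abs(mTot[ipOnly]) < 1))
    expect_true(all(abs(mTot[siteOnly]) < 1))
    expect_true(all(abs(mIp[siteOnly]) < 1))
})

test_that("mRNA simulation requires a ledger", {
    d <- smallStudy(1)
    expect_error(simulateMrnaArrays(d), "TruthLedger")
})

test_that("planted sites are the reverse complement of the miRNA 5' end", {
    d <- smallStudy(9)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    sq <- simulateSequences(d, mr$ledger, siteLength = 14)
    ps <- plantedSites(sq$ledger)
    expect_gt(nrow(ps), 0)
    for (i in seq_len(nrow(ps))) {
        utr <- as.character(sq$utr[[ps$gene[i]]])
        m <- as.character(sq$mirna[[ps$mirna[i]]])
        embedded <- substr(utr, ps$offset[i] + 1, ps$offset[i] + 14)
        expect_identical(embedded, ps$site[i])
        # the recorded seed offset holds the DNA reverse complement of
        # miRNA positions 2-8
        seed7 <- substr(utr, ps$seed_offset[i] + 1, ps$seed_offset[i] + 7)
        expect_identical(chartr("T", "U", seed7),
                         rnaRevComp(substr(m, 2, 8)))
    }
})

test_that("site length beyond the UTR is rejected", {
    d <- smallStudy(2)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    expect_error(simulateSequences(d, mr$ledger, siteLength = 9999),
                 "utrLength")
})

test_that("background seed-match frequency matches the closed form", {
    # over background-only UTRs of length 300 a 7-mer has L-6 start
    # positions, each matching with probability 4^-7
    d <- SimDesign(nMirnaProbes = 10, nGenes = 400, nResponsive = 1,
                   nUpregulated = 0, nTargetsPerMirna = 0, utrLength = 300,
                   genotypes = "wildtype", timepoints = "rep1d", seed = 21)
    sim <- simulateMirnaArrays(d)
    led <- sim$ledger
    led@targetPairs <- data.frame(mirna = character(),
                                  gene = character())
    sq <- simulateSequences(d, led)
    m <- as.character(sq$mirna[[1]])
    hits <- vapply(as.character(sq$utr), function(u)
        sum(seedMatchScan(m, u)$type == "7mer-m8"), numeric(1))
    expected <- (300 - 6) / 4^7
    # 400 UTRs: mean count within 4 sigma of the Poisson-binomial mean
    tol <- 4 * sqrt(expected / 400)
    expect_lt(abs(mean(hits) - expected), tol)
})

test_that("identical designs give byte-identical outputs", {
    d <- smallStudy(17, flagFraction = 0.05)
    out1 <- tempfile(); out2 <- tempfile()
    for (out in c(out1, out2)) {
        sim <- simulateMirnaArrays(d)
        mr <- simulateMrnaArrays(d, sim$ledger)
        sq <- simulateSequences(d, mr$ledger)
        writeArraySet(c(sim$samples, mr$samples), out)
        writeTruthLedger(sq$ledger, file.path(out, "ledger.tsv"))
        Biostrings::writeXStringSet(sq$utr, file.path(out, "utr.fa"))
        Biostrings::writeXStringSet(sq$mirna, file.path(out, "mirna.fa"))
    }
    f1 <- list.files(out1); f2 <- list.files(out2)
    expect_identical(f1, f2)
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(out1, f))),
                         unname(tools::md5sum(file.path(out2, f))))
    unlink(c(out1, out2), recursive = TRUE)
})

test_that("truth ledger round-trips through its tab-delimited form", {
    d <- smallStudy(13)
    sim <- simulateMirnaArrays(d)
    mr <- simulateMrnaArrays(d, sim$ledger)
    sq <- simulateSequences(d, mr$ledger)
    path <- tempfile(fileext = ".tsv")
    writeTruthLedger(sq$ledger, path)
    back <- readTruthLedger(path)
    expect_identical(sort(responsiveMirnas(back)),
                     sort(responsiveMirnas(sq$ledger)))
    expect_equal(
        targetPairs(back)[order(targetPairs(back)$mirna,
                                targetPairs(back)$gene), ],
        targetPairs(sq$ledger)[order(targetPairs(sq$ledger)$mirna,
                                     targetPairs(sq$ledger)$gene), ],
        ignore_attr = TRUE)
    expect_setequal(plantedSites(back)$site, plantedSites(sq$ledger)$site)
    unlink(path)
})
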