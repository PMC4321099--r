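# Independent oracles, deliberately written without reference to the
# package internals.

# Plain-R affine-gap Smith-Waterman best-score oracle for the duplex
# scoring scheme: reversed miRNA vs UTR, WC/wobble/mismatch pair scores,
# pair scores at miRNA seed positions multiplied by seedMultiplier,
# first gap residue gapOpen, later residues gapExtend. Optionally takes
# an explicit per-position weight vector (miRNA 5'->3').
oracleDuplexScore <- function(mirna, utr, p = scanParams(),
                              weights = NULL) {
    q <- rev(strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]])
    tt <- strsplit(chartr("Tt", "Uu", toupper(utr)), "")[[1]]
    n <- length(q)
    m <- length(tt)
    if (is.null(weights)) {
        pos <- n - seq_len(n) + 1L     # miRNA position of reversed index
        w <- ifelse(pos >= p$seedStart & pos <= p$seedEnd,
                    p$seedMultiplier, 1)
    } else w <- rev(weights)
    pairS <- function(a, b) {
        if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
            (a == "C" && b == "G") || (a == "G" && b == "C"))
            p$match
        else if ((a == "G" && b == "U") || (a == "U" && b == "G"))
            p$wobble
        else p$mismatch
    }
    S <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m))
        S[i, j] <- w[i] * pairS(q[i], tt[j])
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)
    F <- matrix(-Inf, n + 1, m + 1)
    best <- 0
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            E[i, j] <- max(H[i, j - 1] + p$gapOpen,
                           E[i, j - 1] + p$gapExtend)
            F[i, j] <- max(H[i - 1, j] + p$gapOpen,
                           F[i - 1, j] + p$gapExtend)
            H[i, j] <- max(0, H[i - 1, j - 1] + S[i - 1, j - 1],
                           E[i, j], F[i, j])
            if (H[i, j] > best) best <- H[i, j]
        }
    }
    best
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

rnaRevComp <- function(x) {
    ch <- rev(strsplit(chartr("T", "U", x), "")[[1]])
    paste(c(A = "U", C = "G", G = "C", U = "A")[ch], collapse = "")
}

# random probe table for round-trip / filtering properties
randomProbeTable <- function(n, twoChannel = FALSE) {
    data.frame(
        probe_id = sprintf("p%03d", seq_len(n)),
        feature_id = sprintf("f%03d", sample(n)),
        cy5 = round(stats::runif(n, 1, 1e4), 3),
        cy3 = if (twoChannel) round(stats::runif(n, 1, 1e4), 3)
              else NA_real_,
        flag = sample(c(-100L, -50L, 0L, 50L, 100L), n, replace = TRUE),
        stringsAsFactors = FALSE)
}

# small simulated study used by several tests (flagging disabled so the
# statistical stages see every feature; QC filtering has its own tests)
smallStudy <- function(seed, nMirnaProbes = 40, nGenes = 60,
                       nResponsive = 3, nUpregulated = 4,
                       nTargetsPerMirna = 4, effectLog2 = 2,
                       noiseSd = 0.2, flagFraction = 0,
                       timepoints = "rep1d",
                       genotypes = c("wildtype", "tlr4_ko", "nfkb_ko")) {
    SimDesign(nMirnaProbes = nMirnaProbes, nGenes = nGenes,
              genotypes = genotypes, timepoints = timepoints,
              nResponsive = nResponsive, nUpregulated = nUpregulated,
              nTargetsPerMirna = nTargetsPerMirna,
              effectLog2 = effectLog2, noiseSd = noiseSd,
              flagFraction = flagFraction, seed = seed)
}
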