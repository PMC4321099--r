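## Synthetic study generator. Intensities are log-normal: log2 intensity =
## feature baseline + planted condition effect + N(0, noiseSd). Bad spots
## get flag -50 (so the "flag < 0" QC filter removes them), good spots 0.
## Sham arrays are simulated explicitly so ratio computation is exercised.
## A single master seed drives everything; each sample draws from its own
## deterministically derived stream.

.sampleSeed <- function(seed, idx)
    as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483629)

.mirnaIds <- function(n) sprintf("sim-miR-%04d", seq_len(n))
.geneIds <- function(n) sprintf("simgene%04d", seq_len(n))

## baseline log2 intensities, fixed per feature by the master seed
.baselines <- function(n, seed, stream) {
    set.seed(.sampleSeed(seed, stream))
    stats::rnorm(n, mean = 8, sd = 1.5)
}

#' Simulate probe-level miRNA arrays with planted responsive miRNAs
#'
#' Generates one single-channel probe table per (genotype, timepoint,
#' replicate, condition in {iri, sham}) and a \linkS4class{TruthLedger}.
#' The first \code{nResponsive} miRNAs are TLR4/NF-kB-responsive: their
#' mean log2(IRI/sham) is \code{+effectLog2} in wild-type and
#' \code{-effectLog2} in both knockouts at 1 d of reperfusion. The next
#' \code{nUpregulated} miRNAs are upregulated by \code{+effectLog2} in
#' every genotype at every timepoint. A \code{flagFraction} of spots is
#' flagged bad (flag -50) at random per array.
#'
#' @param design a \linkS4class{SimDesign}
#' @return list with elements \code{samples} (named list of
#'   \linkS4class{ArraySample}) and \code{ledger}
#'   (\linkS4class{TruthLedger})
#' @examples
#' sim <- simulateMirnaArrays(SimDesign(nMirnaProbes = 40, seed = 1))
#' length(responsiveMirnas(sim$ledger))
#' @export
simulateMirnaArrays <- function(design) {
    stopifnot(is(design, "SimDesign"))
    validObject(design)
    n <- design@nMirnaProbes
    ids <- .mirnaIds(n)
    responsive <- ids[seq_len(design@nResponsive)]
    upregulated <- ids[design@nResponsive + seq_len(design@nUpregulated)]
    base <- .baselines(n, design@seed, stream = 1L)

    upByTp <- lapply(design@timepoints, function(tp) {
        out <- upregulated
        if (tp == "rep1d") out <- c(responsive, out)
        out
    })
    names(upByTp) <- design@timepoints

    samples <- list()
    idx <- 0L
    for (g in design@genotypes) for (tp in design@timepoints)
        for (r in seq_len(design@nReplicatesMirna))
            for (cond in c("iri", "sham")) {
        idx <- idx + 1L
        set.seed(.sampleSeed(design@seed, 100L + idx))
        effect <- numeric(n)
        if (cond == "iri") {
            effect[ids %in% upregulated] <- design@effectLog2
            if (tp == "rep1d")
                effect[ids %in% responsive] <-
                    if (g == "wildtype") design@effectLog2
                    else -design@effectLog2
        }
        log2int <- base + effect + stats::rnorm(n, 0, design@noiseSd)
        flag <- ifelse(stats::runif(n) < design@flagFraction, -50L, 0L)
        s <- ArraySample(
            data.frame(probe_id = sprintf("mp%04d", seq_len(n)),
                       feature_id = ids, cy5 = 2^log2int, cy3 = NA_real_,
                       flag = flag, stringsAsFactors = FALSE),
            genotype = g, timepoint = tp, replicate = r, arm = "mirna",
            condition = cond)
        samples[[sampleId(s)]] <- s
    }

    ledger <- new("TruthLedger",
        responsiveMirnas = responsive,
        upregulatedByTimepoint = upByTp,
        targetPairs = data.frame(mirna = character(), gene = character(),
                                 stringsAsFactors = FALSE),
        plantedSites = data.frame(mirna = character(), gene = character(),
                                  offset = integer(), seed_offset = integer(),
                                  site = character(), stringsAsFactors = FALSE),
        decoys = data.frame(gene = character(), class = character(),
                            stringsAsFactors = FALSE))
    list(samples = samples, ledger = ledger)
}

## Allocate target pairs and decoy classes onto the gene panel and extend
## the ledger. Target genes are drawn from a shared pool (80% the size of
## nResponsive * nTargetsPerMirna) so some genes are hit by several
## miRNAs, which exercises the multiplicity summary.
.planTargets <- function(design, ledger) {
    if (!length(responsiveMirnas(ledger)))
        stop("ledger carries no responsive miRNAs; ",
             "run simulateMirnaArrays first")
    set.seed(.sampleSeed(design@seed, 2L))
    genes <- .geneIds(design@nGenes)
    resp <- responsiveMirnas(ledger)
    nPool <- max(design@nTargetsPerMirna,
                 ceiling(length(resp) * design@nTargetsPerMirna * 0.8))
    nDecoy <- min(design@nTargetsPerMirna,
                  max(0L, (design@nGenes - nPool) %/% 6L))
    if (nPool + 3L * nDecoy > design@nGenes)
        stop("nGenes too small for the requested target/decoy layout")
    pool <- genes[seq_len(nPool)]
    pairs <- do.call(rbind, lapply(resp, function(m)
        data.frame(mirna = m,
                   gene = sort(sample(pool, design@nTargetsPerMirna)),
                   stringsAsFactors = FALSE)))
    decoyGenes <- genes[nPool + seq_len(3L * nDecoy)]
    decoys <- data.frame(
        gene = decoyGenes,
        class = rep(c("down_only", "ip_only", "site_only"), each = nDecoy),
        stringsAsFactors = FALSE)
    ledger@targetPairs <- pairs
    ledger@decoys <- decoys
    ledger
}

#' Simulate two-colour whole-genome arrays (total mRNA and Ago2-IP arms)
#'
#' Each array carries the ischemia-reperfusion sample on Cy5 and the sham
#' control on Cy3. Genes in the ledger's target pairs are planted with
#' mean log2(IRI/sham) of \code{-effectLog2} on the total-mRNA arm and
#' \code{+effectLog2} on the Ago2-IP arm. Decoy genes satisfy only one of
#' the two expression criteria (\code{down_only}, \code{ip_only}) or none
#' (\code{site_only}); all remaining genes are null background. On the
#' first call with a ledger lacking target pairs, pairs and decoys are
#' allocated deterministically from the design seed.
#'
#' @param design a \linkS4class{SimDesign}
#' @param ledger the \linkS4class{TruthLedger} from
#'   \code{\link{simulateMirnaArrays}}
#' @param dyeBias optional intensity-dependent dye-bias coefficient: the
#'   per-probe log-ratio M gains \code{dyeBias * (A - mean(A))}, giving
#'   the curved MA trend that LOWESS normalization is meant to remove
#' @return list with elements \code{samples} and the extended
#'   \code{ledger}
#' @export
simulateMrnaArrays <- function(design, ledger, dyeBias = 0) {
    stopifnot(is(design, "SimDesign"))
    if (missing(ledger) || !is(ledger, "TruthLedger"))
        stop("a TruthLedger from simulateMirnaArrays is required")
    if (!nrow(targetPairs(ledger)))
        ledger <- .planTargets(design, ledger)
    n <- design@nGenes
    genes <- .geneIds(n)
    base <- .baselines(n, design@seed, stream = 3L)
    targets <- unique(targetPairs(ledger)$gene)
    dc <- decoys(ledger)
    downG <- c(targets, dc$gene[dc$class == "down_only"])
    upG <- c(targets, dc$gene[dc$class == "ip_only"])

    samples <- list()
    idx <- 0L
    for (a in c("mrna_total", "mrna_ago2ip"))
        for (r in seq_len(design@nReplicatesMrna)) {
        idx <- idx + 1L
        set.seed(.sampleSeed(design@seed, 500L + idx))
        effect <- numeric(n)
        if (a == "mrna_total") effect[genes %in% downG] <- -design@effectLog2
        else effect[genes %in% upG] <- design@effectLog2
        l3 <- base + stats::rnorm(n, 0, design@noiseSd)           # sham, Cy3
        l5 <- base + effect + stats::rnorm(n, 0, design@noiseSd)  # IRI, Cy5
        if (dyeBias != 0) {
            A <- (l5 + l3) / 2
            M <- (l5 - l3) + dyeBias * (A - mean(A))
            l5 <- A + M / 2
            l3 <- A - M / 2
        }
        flag <- ifelse(stats::runif(n) < design@flagFraction, -50L, 0L)
        s <- ArraySample(
            data.frame(probe_id = sprintf("gp%04d", seq_len(n)),
                       feature_id = genes, cy5 = 2^l5, cy3 = 2^l3,
                       flag = flag, stringsAsFactors = FALSE),
            genotype = "wildtype", timepoint = "rep1d", replicate = r,
            arm = a, condition = "iri")
        samples[[sampleId(s)]] <- s
    }
    list(samples = samples, ledger = ledger)
}

.RC <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

.revcompDNA <- function(x) {
    ch <- rev(strsplit(x, "")[[1]])
    paste(.RC[ch], collapse = "")
}

#' Simulate miRNA and 3'UTR sequences with planted binding sites
#'
#' miRNAs are random 22-nt RNA sequences; 3'UTRs are i.i.d. uniform DNA of
#' length \code{utrLength}. For every (miRNA, gene) pair with a planted
#' site (target pairs plus sequence-carrying decoys), the reverse
#' complement of miRNA positions 1..\code{siteLength} is embedded at a
#' random non-overlapping offset, so the site contains the exact reverse
#' complement of the seed (positions 2-8) at a recorded offset.
#'
#' @param design a \linkS4class{SimDesign}
#' @param ledger ledger holding target pairs (see
#'   \code{\link{simulateMrnaArrays}})
#' @param siteLength length of the planted complementary stretch
#'   (>= 8 so the full seed complement is contained)
#' @return list with \code{mirna} (\code{RNAStringSet}), \code{utr}
#'   (\code{DNAStringSet}) and the extended \code{ledger} whose
#'   \code{plantedSites} records offsets and site sequences
#' @export
simulateSequences <- function(design, ledger, siteLength = 14L) {
    stopifnot(is(design, "SimDesign"))
    if (missing(ledger) || !is(ledger, "TruthLedger"))
        stop("a TruthLedger is required")
    siteLength <- as.integer(siteLength)
    if (siteLength < 8L || siteLength > design@utrLength)
        stop("siteLength must lie in [8, utrLength]")
    set.seed(.sampleSeed(design@seed, 4L))
    resp <- responsiveMirnas(ledger)
    mirnaSeq <- vapply(resp, function(i)
        paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
              collapse = ""), character(1))

    genes <- .geneIds(design@nGenes)
    L <- design@utrLength
    utrSeq <- vapply(genes, function(g)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))

    ## sites to plant: every target pair, plus one site per expression
    ## decoy and per site-only decoy (assigned round-robin to miRNAs)
    dc <- decoys(ledger)
    extra <- dc$gene
    plan <- targetPairs(ledger)
    if (length(extra))
        plan <- rbind(plan, data.frame(
            mirna = resp[(seq_along(extra) - 1L) %% length(resp) + 1L],
            gene = extra, stringsAsFactors = FALSE))

    occupied <- lapply(stats::setNames(nm = genes), function(g) integer())
    sites <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
        m <- plan$mirna[i]; g <- plan$gene[i]
        site <- .revcompDNA(substr(mirnaSeq[[m]], 1L, siteLength))
        repeat {
            off <- sample.int(L - siteLength + 1L, 1L) - 1L
            span <- off:(off + siteLength - 1L)
            if (!any(span %in% occupied[[g]])) break
        }
        if (off + siteLength > L)
            stop("planted site exceeds UTR length for gene ", g)
        occupied[[g]] <- c(occupied[[g]], span)
        substr(utrSeq[[g]], off + 1L, off + siteLength) <- site
        sites[[i]] <- data.frame(
            mirna = m, gene = g, offset = off,
            seed_offset = off + siteLength - 8L,
            site = site, stringsAsFactors = FALSE)
    }
    ledger@plantedSites <- if (length(sites)) do.call(rbind, sites) else
        ledger@plantedSites
    validObject(ledger)
    list(mirna = Biostrings::RNAStringSet(mirnaSeq),
         utr = Biostrings::DNAStringSet(utrSeq),
         ledger = ledger)
}
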