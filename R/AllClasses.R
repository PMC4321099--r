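#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.ARMS <- c("mirna", "mrna_total", "mrna_ago2ip")
.CONDITIONS <- c("iri", "sham")
.GENOTYPES <- c("wildtype", "tlr4_ko", "nfkb_ko")
.TIMEPOINTS <- c("isc2h_rep0h", "rep4h", "rep1d", "rep7d")

#' Simulation design for the synthetic ischemia-reperfusion study
#'
#' A \code{SimDesign} captures the layout of the emulated experiment: how
#' many miRNA probes and genes are on the arrays, which genotypes and
#' reperfusion timepoints are sampled, replicate counts per arm, and the
#' planted truth (number of TLR4/NF-kB-responsive miRNAs, number of
#' generically upregulated miRNAs, targets per responsive miRNA, the
#' planted log2 effect size, intensity noise, bad-spot fraction and the
#' master RNG seed).
#'
#' Genotype and timepoint labels follow the study layout: wild-type plus
#' Tlr4 and NF-kB knockouts; ischemia 2 h followed by 0 h, 4 h, 1 d or 7 d
#' of reperfusion.
#'
#' @slot nMirnaProbes number of miRNA probes per array
#' @slot nGenes number of gene probes on the whole-genome arrays
#' @slot genotypes character subset of
#'   \code{c("wildtype", "tlr4_ko", "nfkb_ko")}
#' @slot timepoints character subset of
#'   \code{c("isc2h_rep0h", "rep4h", "rep1d", "rep7d")}
#' @slot nReplicatesMirna replicate arrays per miRNA-arm condition
#' @slot nReplicatesMrna replicate arrays per whole-genome-arm condition
#' @slot nResponsive planted TLR4/NF-kB-responsive miRNAs (up in wild-type,
#'   down in both knockouts at 1 d of reperfusion)
#' @slot nUpregulated planted genotype-independent upregulated miRNAs
#' @slot nTargetsPerMirna planted target genes per responsive miRNA
#' @slot effectLog2 planted effect size in log2 units
#' @slot noiseSd standard deviation of log2-scale intensity noise
#' @slot flagFraction fraction of spots flagged as bad quality
#' @slot utrLength length of simulated 3'UTR sequences (nt)
#' @slot seed master integer seed; all per-sample streams derive from it
#' @export
setClass("SimDesign", representation(
    nMirnaProbes = "integer",
    nGenes = "integer",
    genotypes = "character",
    timepoints = "character",
    nReplicatesMirna = "integer",
    nReplicatesMrna = "integer",
    nResponsive = "integer",
    nUpregulated = "integer",
    nTargetsPerMirna = "integer",
    effectLog2 = "numeric",
    noiseSd = "numeric",
    flagFraction = "numeric",
    utrLength = "integer",
    seed = "integer"
))

setValidity("SimDesign", function(object) {
    msg <- character()
    counts <- c(nMirnaProbes = object@nMirnaProbes, nGenes = object@nGenes,
                nReplicatesMirna = object@nReplicatesMirna,
                nReplicatesMrna = object@nReplicatesMrna,
                nResponsive = object@nResponsive,
                nUpregulated = object@nUpregulated,
                nTargetsPerMirna = object@nTargetsPerMirna)
    if (any(is.na(counts)) || any(counts < 0L))
        msg <- c(msg, "all counts must be nonnegative")
    if (object@nResponsive + object@nUpregulated > object@nMirnaProbes)
        msg <- c(msg, "nResponsive + nUpregulated exceeds nMirnaProbes")
    if (!all(object@genotypes %in% .GENOTYPES))
        msg <- c(msg, sprintf("genotypes must be a subset of {%s}",
                              paste(.GENOTYPES, collapse = ", ")))
    if (!all(object@timepoints %in% .TIMEPOINTS))
        msg <- c(msg, sprintf("timepoints must be a subset of {%s}",
                              paste(.TIMEPOINTS, collapse = ", ")))
    if (is.na(object@flagFraction) || object@flagFraction < 0 ||
        object@flagFraction >= 1)
        msg <- c(msg, "flagFraction must lie in [0, 1)")
    if (is.na(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (object@utrLength < 30L)
        msg <- c(msg, "utrLength must be at least 30")
    if (length(msg)) msg else TRUE
})

#' Construct a SimDesign
#'
#' Defaults mirror the emulated study design at desk scale: three
#' genotypes, four reperfusion timepoints, 3 replicate miRNA arrays and 2
#' replicate whole-genome arrays per condition, a 4-fold (log2 = 2)
#' planted effect and log2 intensity noise of 0.2.
#'
#' @param nMirnaProbes,nGenes array sizes
#' @param genotypes,timepoints condition labels (see \linkS4class{SimDesign})
#' @param nReplicatesMirna,nReplicatesMrna replicate counts
#' @param nResponsive,nUpregulated,nTargetsPerMirna planted truth sizes
#' @param effectLog2 planted log2 effect
#' @param noiseSd log2 intensity noise SD
#' @param flagFraction fraction of spots flagged bad
#' @param utrLength simulated 3'UTR length in nt
#' @param seed master RNG seed
#' @return a validated \linkS4class{SimDesign}
#' @examples
#' SimDesign(nMirnaProbes = 50, nResponsive = 3, seed = 1)
#' @export
SimDesign <- function(nMirnaProbes = 200L, nGenes = 100L,
                      genotypes = .GENOTYPES, timepoints = .TIMEPOINTS,
                      nReplicatesMirna = 3L, nReplicatesMrna = 2L,
                      nResponsive = 3L, nUpregulated = 5L,
                      nTargetsPerMirna = 4L, effectLog2 = 2,
                      noiseSd = 0.2, flagFraction = 0.02,
                      utrLength = 500L, seed = 1L) {
    new("SimDesign",
        nMirnaProbes = as.integer(nMirnaProbes), nGenes = as.integer(nGenes),
        genotypes = genotypes, timepoints = timepoints,
        nReplicatesMirna = as.integer(nReplicatesMirna),
        nReplicatesMrna = as.integer(nReplicatesMrna),
        nResponsive = as.integer(nResponsive),
        nUpregulated = as.integer(nUpregulated),
        nTargetsPerMirna = as.integer(nTargetsPerMirna),
        effectLog2 = as.numeric(effectLog2), noiseSd = as.numeric(noiseSd),
        flagFraction = as.numeric(flagFraction),
        utrLength = as.integer(utrLength), seed = as.integer(seed))
}

setMethod("show", "SimDesign", function(object) {
    cat("SimDesign:", object@nMirnaProbes, "miRNA probes,",
        object@nGenes, "genes\n")
    cat("  genotypes:", paste(object@genotypes, collapse = ", "), "\n")
    cat("  timepoints:", paste(object@timepoints, collapse = ", "), "\n")
    cat("  replicates: miRNA", object@nReplicatesMirna,
        "| whole-genome", object@nReplicatesMrna, "\n")
    cat("  planted:", object@nResponsive, "responsive +",
        object@nUpregulated, "upregulated miRNAs;",
        object@nTargetsPerMirna, "targets each; effect",
        object@effectLog2, "log2\n")
    cat("  noiseSd", object@noiseSd, "| flagFraction", object@flagFraction,
        "| seed", object@seed, "\n")
})

#' One hybridized array: sample metadata plus its probe-level records
#'
#' Each probe row carries \code{probe_id}, \code{feature_id} (miRNA or
#' gene accession), \code{cy5} and \code{cy3} intensities and an integer
#' QC \code{flag}. miRNA arrays are single-channel: only Cy5 is measured
#' and \code{cy3} is \code{NA}. Whole-genome arrays (total mRNA and
#' Ago2-IP arms) are two-colour within-array designs with the
#' ischemia-reperfusion sample on Cy5 and the sham control on Cy3.
#'
#' @slot sampleId unique sample identifier
#' @slot genotype one of wildtype / tlr4_ko / nfkb_ko
#' @slot timepoint reperfusion timepoint label
#' @slot replicate replicate index (1-based)
#' @slot arm one of \code{"mirna"}, \code{"mrna_total"}, \code{"mrna_ago2ip"}
#' @slot condition \code{"iri"} or \code{"sham"}; two-colour arrays carry
#'   both conditions on one slide and are labelled \code{"iri"} (Cy5)
#' @slot probes data.frame of probe-level records
#' @export
setClass("ArraySample", representation(
    sampleId = "character",
    genotype = "character",
    timepoint = "character",
    replicate = "integer",
    arm = "character",
    condition = "character",
    probes = "data.frame"
))

.PROBE_COLS <- c("probe_id", "feature_id", "cy5", "cy3", "flag")

setValidity("ArraySample", function(object) {
    msg <- character()
    p <- object@probes
    if (!all(.PROBE_COLS %in% names(p)))
        msg <- c(msg, sprintf("probes must have columns: %s",
                              paste(.PROBE_COLS, collapse = ", ")))
    else {
        if (any(!nzchar(p$feature_id)))
            msg <- c(msg, "feature_id must be nonempty")
        if (any(is.na(p$cy5)) || any(p$cy5 < 0))
            msg <- c(msg, "cy5 intensities must be nonnegative and non-NA")
        if (any(p$cy3 < 0, na.rm = TRUE))
            msg <- c(msg, "cy3 intensities must be nonnegative")
        if (object@arm == "mirna" && any(!is.na(p$cy3)))
            msg <- c(msg, "miRNA arrays are single-channel: cy3 must be NA")
        if (object@arm != "mirna" && nrow(p) && any(is.na(p$cy3)))
            msg <- c(msg, "whole-genome arrays require both channels")
    }
    if (!object@arm %in% .ARMS)
        msg <- c(msg, sprintf("arm must be one of {%s}",
                              paste(.ARMS, collapse = ", ")))
    if (!object@condition %in% .CONDITIONS)
        msg <- c(msg, "condition must be 'iri' or 'sham'")
    if (length(msg)) msg else TRUE
})

#' Construct an ArraySample
#'
#' @param probes data.frame with columns \code{probe_id}, \code{feature_id},
#'   \code{cy5}, \code{cy3}, \code{flag}
#' @param sampleId sample identifier; built from the metadata if missing
#' @param genotype,timepoint,replicate,arm,condition sample metadata
#' @return a validated \linkS4class{ArraySample}
#' @export
ArraySample <- function(probes, sampleId = NULL, genotype = "wildtype",
                        timepoint = "rep1d", replicate = 1L, arm = "mirna",
                        condition = "iri") {
    if (is.null(sampleId))
        sampleId <- paste(arm, genotype, timepoint, condition,
                          paste0("r", replicate), sep = "_")
    probes <- as.data.frame(probes)
    probes$probe_id <- as.character(probes$probe_id)
    probes$feature_id <- as.character(probes$feature_id)
    new("ArraySample", sampleId = sampleId, genotype = genotype,
        timepoint = timepoint, replicate = as.integer(replicate),
        arm = arm, condition = condition, probes = probes)
}

setMethod("show", "ArraySample", function(object) {
    cat("ArraySample", object@sampleId, "\n")
    cat(" ", object@arm, "arm |", object@genotype, "|", object@timepoint,
        "| replicate", object@replicate, "|", object@condition, "\n")
    cat(" ", nrow(object@probes), "probes (",
        sum(object@probes$flag < 0), "flagged bad )\n")
})

#' Ground-truth ledger of a synthetic study
#'
#' Records what was planted by the simulator so recovery can be measured:
#' the responsive miRNA ids, upregulated miRNAs per timepoint, the
#' (miRNA, gene) target pairs, planted UTR binding sites, and the decoy
#' genes (each satisfying only a subset of the three evidence arms).
#'
#' @slot responsiveMirnas character vector of responsive miRNA ids
#' @slot upregulatedByTimepoint named list, timepoint -> miRNA ids
#' @slot targetPairs data.frame with columns \code{mirna}, \code{gene}
#' @slot plantedSites data.frame with columns \code{gene}, \code{mirna},
#'   \code{offset} (0-based start of the full complementary site),
#'   \code{seed_offset} (0-based start of the seed-complement 7-mer),
#'   \code{site} (site sequence, DNA alphabet)
#' @slot decoys data.frame with columns \code{gene}, \code{class}
#'   (\code{"down_only"}, \code{"ip_only"} or \code{"site_only"})
#' @export
setClass("TruthLedger", representation(
    responsiveMirnas = "character",
    upregulatedByTimepoint = "list",
    targetPairs = "data.frame",
    plantedSites = "data.frame",
    decoys = "data.frame"
))

setValidity("TruthLedger", function(object) {
    msg <- character()
    planted <- unique(c(object@responsiveMirnas,
                        unlist(object@upregulatedByTimepoint)))
    if (nrow(object@targetPairs) &&
        !all(object@targetPairs$mirna %in% planted))
        msg <- c(msg, "every target pair's miRNA must be planted")
    if (nrow(object@targetPairs)) {
        key <- paste(object@plantedSites$mirna, object@plantedSites$gene)
        need <- paste(object@targetPairs$mirna, object@targetPairs$gene)
        if (!all(need %in% key) && nrow(object@plantedSites))
            msg <- c(msg, "every target pair needs >=1 planted site")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TruthLedger", function(object) {
    cat("TruthLedger:", length(object@responsiveMirnas),
        "responsive miRNAs,", nrow(object@targetPairs), "target pairs,",
        nrow(object@decoys), "decoy genes\n")
})

#' Log2-ratio expression matrix
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding one assay,
#' \code{"log2ratio"}: normalized log2(IRI/sham) values, features in rows
#' and samples in columns, with genotype / timepoint / replicate / arm in
#' \code{colData}. Features that could not be quantified in every retained
#' sample (flagged out or non-positive intensity) are dropped before
#' construction and reported by the builders, so validity requires all
#' values finite.
#'
#' @export
setClass("RatioExperiment", contains = "SummarizedExperiment")

setValidity("RatioExperiment", function(object) {
    if (!"log2ratio" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2ratio' is required")
    if (!all(is.finite(assay(object, "log2ratio"))))
        return("log2ratio values must all be finite")
    TRUE
})

#' Construct a RatioExperiment
#'
#' @param log2ratio numeric matrix, features x samples
#' @param colData data.frame of per-sample metadata (genotype, timepoint,
#'   replicate, arm)
#' @return a \linkS4class{RatioExperiment}
#' @export
RatioExperiment <- function(log2ratio, colData) {
    se <- SummarizedExperiment(
        assays = list(log2ratio = as.matrix(log2ratio)),
        colData = DataFrame(colData))
    new("RatioExperiment", se)
}
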