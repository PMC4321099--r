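#' Read a probe-level array table
#'
#' Probe tables are tab-delimited with a header line and columns
#' \code{probe_id}, \code{feature_id}, \code{cy5}, \code{cy3}, \code{flag}.
#' Single-channel miRNA arrays leave \code{cy3} as \code{NA}. Rows that do
#' not parse are reported with their line numbers.
#'
#' @param path path to the tab-delimited probe table
#' @param genotype,timepoint,replicate,arm,condition sample metadata (the
#'   manifest carries these; see \code{\link{readArraySet}})
#' @param sampleId optional explicit sample id
#' @return an \linkS4class{ArraySample}
#' @export
readProbeTable <- function(path, genotype = "wildtype", timepoint = "rep1d",
                           replicate = 1L, arm = "mirna", condition = "iri",
                           sampleId = NULL) {
    if (!file.exists(path))
        stop("probe table not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE, quote = "")
    missing <- setdiff(.PROBE_COLS, names(tab))
    if (length(missing))
        stop("format error in ", basename(path), ": missing column(s) ",
             paste(missing, collapse = ", "))
    tab <- tab[.PROBE_COLS]
    suppressWarnings({
        cy5 <- as.numeric(tab$cy5)
        cy3 <- as.numeric(ifelse(tab$cy3 %in% c("", "NA"), NA, tab$cy3))
        flag <- as.integer(tab$flag)
    })
    bad <- which(is.na(cy5) | is.na(flag) | !nzchar(tab$feature_id))
    if (length(bad))
        stop("malformed row(s) in ", basename(path), " at line(s) ",
             paste(bad + 1L, collapse = ", "),
             " (line numbers include the header)")
    neg <- which(cy5 < 0 | (!is.na(cy3) & cy3 < 0))
    if (length(neg))
        stop("validation error in ", basename(path),
             ": negative intensity at line(s) ",
             paste(neg + 1L, collapse = ", "))
    ArraySample(data.frame(probe_id = tab$probe_id,
                           feature_id = tab$feature_id,
                           cy5 = cy5, cy3 = cy3, flag = flag,
                           stringsAsFactors = FALSE),
                sampleId = sampleId, genotype = genotype,
                timepoint = timepoint, replicate = replicate,
                arm = arm, condition = condition)
}

#' Write a probe-level array table
#'
#' @param sample an \linkS4class{ArraySample}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeProbeTable <- function(sample, path) {
    p <- probes(sample)
    utils::write.table(p[.PROBE_COLS], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write or read a set of arrays with a manifest
#'
#' \code{writeArraySet} writes one probe table per sample plus a
#' \code{manifest.tsv} mapping filename to (genotype, timepoint,
#' replicate, arm, condition). \code{readArraySet} reads the manifest and
#' returns the samples.
#'
#' @param samples list of \linkS4class{ArraySample}
#' @param dir output directory (created if needed)
#' @return \code{writeArraySet}: the manifest path, invisibly;
#'   \code{readArraySet}: a named list of \linkS4class{ArraySample}
#' @export
writeArraySet <- function(samples, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(samples, function(s) {
        fn <- paste0(sampleId(s), ".tsv")
        writeProbeTable(s, file.path(dir, fn))
        data.frame(file = fn, sample_id = sampleId(s),
                   genotype = genotype(s), timepoint = timepoint(s),
                   replicate = replicateIndex(s), arm = arm(s),
                   condition = condition(s), stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    mpath <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(mpath)
}

#' @rdname writeArraySet
#' @param manifest path to a \code{manifest.tsv} written by
#'   \code{writeArraySet}
#' @export
readArraySet <- function(manifest) {
    man <- utils::read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
    dir <- dirname(manifest)
    samples <- lapply(seq_len(nrow(man)), function(i) {
        readProbeTable(file.path(dir, man$file[i]),
                       genotype = man$genotype[i],
                       timepoint = man$timepoint[i],
                       replicate = man$replicate[i],
                       arm = man$arm[i], condition = man$condition[i],
                       sampleId = man$sample_id[i])
    })
    names(samples) <- man$sample_id
    samples
}

#' Read miRNA or 3'UTR sequences from FASTA
#'
#' Accepts DNA or RNA alphabets and canonicalizes: miRNAs to RNA
#' (T -> U), UTRs to DNA (U -> T). Non-canonical characters are an error.
#'
#' @param path FASTA file
#' @param as \code{"rna"} (miRNAs) or \code{"dna"} (3'UTRs)
#' @return an \code{RNAStringSet} or \code{DNAStringSet}
#' @export
readSequences <- function(path, as = c("rna", "dna")) {
    as <- match.arg(as)
    raw <- Biostrings::readBStringSet(path)
    chr <- toupper(as.character(raw))
    if (as == "rna") {
        chr <- chartr("T", "U", chr)
        if (any(grepl("[^ACGU]", chr)))
            stop("non-canonical characters in ", basename(path))
        out <- Biostrings::RNAStringSet(chr)
    } else {
        chr <- chartr("U", "T", chr)
        if (any(grepl("[^ACGT]", chr)))
            stop("non-canonical characters in ", basename(path))
        out <- Biostrings::DNAStringSet(chr)
    }
    names(out) <- names(raw)
    out
}

#' Serialize / load a TruthLedger as a tab-delimited file
#'
#' One long-format table with a \code{record} discriminator column so the
#' whole ground truth travels as a single text file.
#'
#' @param ledger a \linkS4class{TruthLedger}
#' @param path output (input) path
#' @return \code{writeTruthLedger}: \code{path} invisibly;
#'   \code{readTruthLedger}: a \linkS4class{TruthLedger}
#' @export
writeTruthLedger <- function(ledger, path) {
    blank <- function(n) rep(NA, n)
    rows <- list()
    if (length(responsiveMirnas(ledger)))
        rows$resp <- data.frame(record = "responsive",
                                mirna = responsiveMirnas(ledger),
                                gene = NA, timepoint = NA, offset = NA,
                                seed_offset = NA, site = NA, class = NA)
    up <- upregulatedByTimepoint(ledger)
    for (tp in names(up)) if (length(up[[tp]]))
        rows[[paste0("up_", tp)]] <- data.frame(
            record = "upregulated", mirna = up[[tp]], gene = NA,
            timepoint = tp, offset = NA, seed_offset = NA, site = NA,
            class = NA)
    tp2 <- targetPairs(ledger)
    if (nrow(tp2))
        rows$pairs <- data.frame(record = "target_pair", mirna = tp2$mirna,
                                 gene = tp2$gene, timepoint = NA,
                                 offset = NA, seed_offset = NA, site = NA,
                                 class = NA)
    ps <- plantedSites(ledger)
    if (nrow(ps))
        rows$sites <- data.frame(record = "planted_site", mirna = ps$mirna,
                                 gene = ps$gene, timepoint = NA,
                                 offset = ps$offset,
                                 seed_offset = ps$seed_offset,
                                 site = ps$site, class = NA)
    dc <- decoys(ledger)
    if (nrow(dc))
        rows$decoys <- data.frame(record = "decoy", mirna = NA,
                                  gene = dc$gene, timepoint = NA,
                                  offset = NA, seed_offset = NA, site = NA,
                                  class = dc$class)
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthLedger
#' @export
readTruthLedger <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    pick <- function(rec) tab[tab$record == rec, , drop = FALSE]
    up <- pick("upregulated")
    upl <- split(up$mirna, up$timepoint)
    pairs <- pick("target_pair")
    sites <- pick("planted_site")
    dc <- pick("decoy")
    new("TruthLedger",
        responsiveMirnas = pick("responsive")$mirna,
        upregulatedByTimepoint = upl,
        targetPairs = data.frame(mirna = pairs$mirna, gene = pairs$gene,
                                 stringsAsFactors = FALSE),
        plantedSites = data.frame(mirna = sites$mirna, gene = sites$gene,
                                  offset = as.integer(sites$offset),
                                  seed_offset = as.integer(sites$seed_offset),
                                  site = sites$site,
                                  stringsAsFactors = FALSE),
        decoys = data.frame(gene = dc$gene, class = dc$class,
                            stringsAsFactors = FALSE))
}
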