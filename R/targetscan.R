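#' @useDynLib ago2seed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Duplex alignment scoring parameters
#'
#' The scoring scheme of the site aligner: Watson-Crick pair +5, G:U
#' wobble +1, mismatch -3; affine gaps (first gap residue -8, each
#' further residue -2); all pair scores at miRNA seed positions
#' (2-8 by default, 1-based from the 5' end) are multiplied by
#' \code{seedMultiplier}. Sites scoring below \code{minScore} are not
#' reported. Defaults are chosen to mimic published miRanda-like
#' behaviour on this dimensionless scale.
#'
#' @param match,wobble,mismatch pair scores
#' @param gapOpen,gapExtend affine gap costs (negative)
#' @param seedMultiplier weight applied to pair scores in the seed
#' @param seedStart,seedEnd seed bounds, 1-based miRNA positions
#' @param minScore site score threshold (default 80)
#' @param maxSites cap on reported sites per (miRNA, UTR) pair
#' @return a named list of class \code{"ScanParams"}
#' @export
scanParams <- function(match = 5, wobble = 1, mismatch = -3,
                       gapOpen = -8, gapExtend = -2, seedMultiplier = 2,
                       seedStart = 2L, seedEnd = 8L, minScore = 80,
                       maxSites = 100L) {
    stopifnot(match > 0, gapOpen < 0, gapExtend < 0,
              seedMultiplier >= 1, seedStart >= 1, seedEnd >= seedStart)
    structure(list(match = match, wobble = wobble, mismatch = mismatch,
                   gapOpen = gapOpen, gapExtend = gapExtend,
                   seedMultiplier = seedMultiplier,
                   seedStart = as.integer(seedStart),
                   seedEnd = as.integer(seedEnd), minScore = minScore,
                   maxSites = as.integer(maxSites)),
              class = "ScanParams")
}

.asRnaChar <- function(x, what) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    x <- chartr("Tt", "Uu", toupper(x))
    if (any(grepl("[^ACGU]", x)))
        stop("non-canonical characters in ", what, " sequence")
    x
}

#' Align a miRNA against a 3'UTR and report candidate binding sites
#'
#' Local alignment of the reversed miRNA along the UTR (both 5'->3')
#' under the complementarity scoring of \code{\link{scanParams}}. All
#' non-overlapping sites with score >= \code{minScore} are returned
#' best-first; overlapping lower-scoring sites are suppressed greedily
#' (ties broken by leftmost start). Coordinates are 0-based half-open on
#' the UTR. The trace string runs 5'->3' along the UTR with symbols
#' \code{M} (Watson-Crick pair), \code{W} (G:U wobble), \code{X}
#' (mismatch), \code{i} (UTR base bulged out) and \code{d} (miRNA base
#' bulged out). \code{seed_matched} is TRUE when the seed duplex is
#' canonical: every seed position aligned as a Watson-Crick pair, with
#' no bulge on either strand interrupting the seed pairing.
#'
#' @param mirna miRNA sequence 5'->3' (character, \code{RNAString}, or a
#'   length-1 \code{RNAStringSet}); 18-26 nt
#' @param utr UTR sequence 5'->3' (character, \code{DNAString}/
#'   \code{RNAString} or length-1 set); U/T are interchangeable
#' @param params a \code{\link{scanParams}} list
#' @return \code{DataFrame} with columns \code{start}, \code{end},
#'   \code{mirna_start}, \code{mirna_end}, \code{score}, \code{trace},
#'   \code{seed_matched}
#' @examples
#' p <- scanParams()
#' alignDuplex("UAGCAGCACGUAAAUAUUGGCG",
#'             "AAACGCCAATATTTACGTGCTGCTAAA", p)
#' @export
alignDuplex <- function(mirna, utr, params = scanParams()) {
    m <- .asRnaChar(mirna, "miRNA")
    u <- .asRnaChar(utr, "UTR")
    stopifnot(length(m) == 1, length(u) == 1)
    if (nchar(m) < 18 || nchar(m) > 26)
        stop("miRNA length must be 18-26 nt (got ", nchar(m), ")")
    res <- .duplexAlignCpp(m, u, params$match, params$wobble,
                           params$mismatch, params$gapOpen,
                           params$gapExtend, params$seedMultiplier,
                           params$seedStart, params$seedEnd,
                           params$minScore, params$maxSites)
    DataFrame(start = res$start, end = res$end,
              mirna_start = res$mirna_start, mirna_end = res$mirna_end,
              score = res$score, trace = res$trace,
              seed_matched = res$seed_matched)
}

#' Re-score an alignment trace under a parameter set
#'
#' Walks a trace reported by \code{\link{alignDuplex}} and recomputes its
#' score from the sequences; used to assert that reported scores are
#' consistent with their traces.
#'
#' @param site one row of the \code{\link{alignDuplex}} result
#' @param mirna,utr the aligned sequences
#' @param params the parameter set the alignment was computed under
#' @return the recomputed score
#' @export
rescoreAlignment <- function(site, mirna, utr, params = scanParams()) {
    m <- strsplit(.asRnaChar(mirna, "miRNA"), "")[[1]]
    u <- strsplit(.asRnaChar(utr, "UTR"), "")[[1]]
    tr <- strsplit(site$trace, "")[[1]]
    pos <- site$mirna_end          # miRNA position at the UTR 5' edge
    j <- site$start + 1L           # 1-based UTR index
    weight <- function(p)
        if (p >= params$seedStart && p <= params$seedEnd)
            params$seedMultiplier else 1
    pairScore <- function(qb, tb) {
        wc <- (qb == "A" && tb == "U") || (qb == "U" && tb == "A") ||
              (qb == "C" && tb == "G") || (qb == "G" && tb == "C")
        if (wc) return(params$match)
        if ((qb == "G" && tb == "U") || (qb == "U" && tb == "G"))
            return(params$wobble)
        params$mismatch
    }
    score <- 0
    inGap <- FALSE
    for (c in tr) {
        if (c %in% c("M", "W", "X")) {
            score <- score + weight(pos) * pairScore(m[pos], u[j])
            pos <- pos - 1L
            j <- j + 1L
            inGap <- FALSE
        } else {
            score <- score +
                if (inGap) params$gapExtend else params$gapOpen
            if (c == "i") j <- j + 1L else pos <- pos - 1L
            inGap <- TRUE
        }
    }
    score
}

.revcompToRna <- function(x) {
    ch <- rev(strsplit(x, "")[[1]])
    paste(c(A = "U", C = "G", G = "C", U = "A")[ch], collapse = "")
}

#' Exact seed-match scan
#'
#' Reports every offset where the UTR carries an exact reverse complement
#' of the miRNA seed: \code{"7mer-m8"} sites (positions 2-8) and
#' \code{"7mer-A1"} sites (positions 2-7 complemented, with an A in the
#' UTR opposite miRNA position 1). Offsets are 0-based starts of the
#' 7-nt matched region on the UTR. An 8mer site reports both types (at
#' offsets differing by 1).
#'
#' @param mirna miRNA sequence 5'->3'
#' @param utr UTR sequence 5'->3'
#' @return data.frame with columns \code{offset}, \code{type}
#' @export
seedMatchScan <- function(mirna, utr) {
    m <- .asRnaChar(mirna, "miRNA")
    u <- .asRnaChar(utr, "UTR")
    hits7 <- .findAll(u, .revcompToRna(substr(m, 2, 8)))
    hitsA1 <- .findAll(u, paste0(.revcompToRna(substr(m, 2, 7)), "A"))
    out <- rbind(
        if (length(hits7)) data.frame(offset = hits7, type = "7mer-m8"),
        if (length(hitsA1)) data.frame(offset = hitsA1, type = "7mer-A1"))
    if (is.null(out))
        return(data.frame(offset = integer(), type = character()))
    out[order(out$offset, out$type), , drop = FALSE]
}

## all 0-based offsets of pattern in subject (overlapping allowed)
.findAll <- function(subject, pattern) {
    hits <- gregexpr(paste0("(?=", pattern, ")"), subject,
                     perl = TRUE)[[1]]
    if (hits[1] == -1) integer() else as.integer(hits) - 1L
}

#' Predict per-miRNA target gene sets from sequence alone
#'
#' A gene enters a miRNA's predicted set iff its UTR has at least one
#' site with score >= \code{minScore} and a fully Watson-Crick-paired
#' seed. Each set is ordered by best site score (descending), ties by
#' gene id.
#'
#' @param mirnas named \code{RNAStringSet} or named character vector
#' @param utrs named \code{DNAStringSet} or named character vector of
#'   3'UTRs (names = gene ids)
#' @param params a \code{\link{scanParams}} list
#' @return named list: miRNA id -> character vector of predicted gene
#'   ids; the full site table is attached as attribute \code{"sites"}
#' @export
predictTargets <- function(mirnas, utrs, params = scanParams()) {
    mseq <- .asRnaChar(as.character(mirnas), "miRNA")
    useq <- as.character(utrs)
    if (is.null(names(mseq)) || is.null(names(useq)))
        stop("mirnas and utrs must be named")
    siteRows <- list()
    sets <- lapply(names(mseq), function(mid) {
        best <- stats::setNames(numeric(0), character(0))
        for (gid in names(useq)) {
            hits <- alignDuplex(mseq[[mid]], useq[[gid]], params)
            hits <- hits[hits$seed_matched, , drop = FALSE]
            if (nrow(hits)) {
                siteRows[[paste(mid, gid)]] <<- data.frame(
                    mirna = mid, gene = gid, start = hits$start,
                    end = hits$end, score = hits$score,
                    stringsAsFactors = FALSE)
                best[gid] <- max(hits$score)
            }
        }
        if (length(best)) names(best)[order(-best, names(best))]
        else character()
    })
    names(sets) <- names(mseq)
    sets <- lapply(sets, function(s) if (is.null(s)) character() else s)
    attr(sets, "sites") <- if (length(siteRows))
        do.call(rbind, siteRows) else
        data.frame(mirna = character(), gene = character(),
                   start = integer(), end = integer(), score = numeric())
    sets
}
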