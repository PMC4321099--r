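## Gene identifiers are harmonized case-insensitively on the symbol; an
## optional accession map is the secondary key. A symbol that folds onto
## two different accessions is a collision: it is reported and excluded
## from calls rather than silently merged.
.foldId <- function(x) tolower(trimws(x))

#' Evidence intersection: sequence prediction x Ago2-IP x downregulation
#'
#' Builds the full outer evidence table over every (miRNA, gene) pair
#' touched by any arm, with one logical column per evidence bit:
#' \code{predicted} (a sequence site), \code{ago2_up} (>= 2-fold up in
#' the Ago2-IP pool) and \code{mrna_down} (>= 2-fold down on the
#' whole-genome arrays). A pair is \code{called} a target iff all three
#' bits concur.
#'
#' @param predicted named list: miRNA id -> predicted gene ids
#' @param ago2Up character vector of Ago2-IP-upregulated gene ids
#' @param mrnaDown character vector of downregulated gene ids
#' @param accessions optional named character vector mapping gene symbol
#'   to accession; used to detect symbol collisions
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{accession}, \code{predicted}, \code{ago2_up},
#'   \code{mrna_down}, \code{called}; collided symbols (excluded from
#'   calls) are attached as attribute \code{"collisions"}
#' @examples
#' intersectEvidence(list(m1 = c("A", "B", "C")),
#'                   ago2Up = c("B", "C", "D"),
#'                   mrnaDown = c("C", "B", "E"))
#' @export
intersectEvidence <- function(predicted, ago2Up, mrnaDown,
                              accessions = NULL) {
    stopifnot(is.list(predicted), !is.null(names(predicted)))
    collisions <- character()
    if (!is.null(accessions)) {
        key <- .foldId(names(accessions))
        dup <- split(unname(accessions), key)
        collisions <- names(dup)[vapply(dup, function(a)
            length(unique(a)) > 1, logical(1))]
        if (length(collisions))
            warning("symbol(s) mapping to multiple accessions excluded ",
                    "from calls: ", paste(collisions, collapse = ", "))
    }
    upKey <- .foldId(ago2Up)
    downKey <- .foldId(mrnaDown)
    rows <- lapply(names(predicted), function(m) {
        genes <- unique(c(predicted[[m]], ago2Up, mrnaDown))
        if (!length(genes))
            return(NULL)
        key <- .foldId(genes)
        pred <- key %in% .foldId(predicted[[m]])
        up <- key %in% upKey
        down <- key %in% downKey
        acc <- if (is.null(accessions)) NA_character_ else
            as.character(accessions[match(key, .foldId(names(accessions)))])
        data.frame(mirna = m, gene = genes, accession = acc,
                   predicted = pred, ago2_up = up, mrna_down = down,
                   called = pred & up & down & !(key %in% collisions),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(mirna = character(), gene = character(),
                          accession = character(), predicted = logical(),
                          ago2_up = logical(), mrna_down = logical(),
                          called = logical())
    rownames(out) <- NULL
    attr(out, "collisions") <- collisions
    out
}

#' Multiplicity summary: genes called by at least k miRNAs
#'
#' Counts, per gene, the distinct miRNAs that call it a target and
#' reports the genes reaching the threshold, sorted by (count
#' descending, gene id).
#'
#' @param table an evidence table from \code{\link{intersectEvidence}},
#'   or a named list of per-miRNA called gene sets
#' @param k multiplicity threshold (default 2)
#' @return list with \code{counts} (named integer vector over all called
#'   genes), \code{k}, and \code{genes} (those with count >= k)
#' @export
multiplicitySummary <- function(table, k = 2L) {
    if (is.data.frame(table)) {
        called <- table[table$called, c("mirna", "gene")]
    } else {
        stopifnot(is.list(table), !is.null(names(table)))
        called <- do.call(rbind, lapply(names(table), function(m)
            if (length(table[[m]]))
                data.frame(mirna = m, gene = table[[m]],
                           stringsAsFactors = FALSE)))
        if (is.null(called))
            called <- data.frame(mirna = character(), gene = character())
    }
    called <- unique(called)
    counts <- vapply(split(called$mirna, called$gene),
                     function(m) length(unique(m)), integer(1))
    genes <- names(counts)[counts >= k]
    genes <- genes[order(-counts[genes], genes)]
    list(counts = counts, k = as.integer(k), genes = genes)
}

.extdata <- function(file, md5) {
    path <- system.file("extdata", file, package = "ago2seed",
                        mustWork = TRUE)
    if (unname(tools::md5sum(path)) != md5)
        stop("fixture corruption: checksum mismatch for ", file)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
}

#' Bundled study tables
#'
#' Curated result tables from the mouse hindlimb ischemia-reperfusion
#' study the pipeline reproduces, shipped as tab-delimited fixtures with
#' checksum verification.
#'
#' \code{loadTimepointTable}: the significantly upregulated miRNAs per
#' reperfusion timepoint and log2-ratio threshold column, exactly as
#' printed (duplicate listings across columns are retained; each entry
#' keeps its column provenance).
#'
#' \code{loadGenotypeFoldTable}: per-genotype log2 fold of expression for
#' the three TLR4/NF-kB-responsive miRNAs (wild-type up, both knockouts
#' down).
#'
#' \code{loadTargetGeneTable}: the called target genes per responsive
#' miRNA with their RefSeq accessions.
#'
#' @return a data.frame (see Details)
#' @name studyTables
NULL

#' @rdname studyTables
#' @export
loadTimepointTable <- function() {
    tab <- .extdata("mirna_upregulated_by_timepoint.tsv",
                    "8015112c696050faf81e56b6c3cafa5a")
    tab$min_log2 <- as.numeric(tab$min_log2)
    tab$column <- as.integer(tab$column)
    tab$row <- as.integer(tab$row)
    tab
}

#' @rdname studyTables
#' @export
loadGenotypeFoldTable <- function() {
    tab <- .extdata("responsive_mirna_genotype_folds.tsv",
                    "b71fea8deb8a3a8d18dac44280692558")
    for (col in c("wildtype", "tlr4_ko", "nfkb_ko"))
        tab[[col]] <- as.numeric(tab[[col]])
    names(tab)[names(tab) == "mirna"] <- "feature_id"
    tab
}

#' @rdname studyTables
#' @export
loadTargetGeneTable <- function() {
    .extdata("mirna_target_genes.tsv",
             "4f85ea51e67ff9a04a094c5e8cf0a0d6")
}
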