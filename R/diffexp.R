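## Vectorized one-sample two-sided t-test of each row against 0.
.rowTTest <- function(mat) {
    n <- ncol(mat)
    m <- rowMeans(mat)
    s <- apply(mat, 1, stats::sd)
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
    p[s == 0 & m == 0] <- 1        # all-zero replicates: no evidence
    p[s == 0 & m != 0] <- 0        # degenerate exact shift
    data.frame(mean_log2 = m, p_value = p)
}

#' Replicate-level differential statistics
#'
#' For each feature, the mean log2 ratio across the selected replicate
#' columns and a two-sided one-sample location test of the replicate
#' ratios against 0 (Student t by default, Wilcoxon signed-rank as a
#' robustness option). \code{passes} applies the selection rule:
#' |mean log2| >= \code{minAbsLog2} and P < \code{maxP}.
#'
#' @param x a \linkS4class{RatioExperiment} or a numeric matrix whose
#'   columns are replicates of one group
#' @param genotype,timepoint optional column filters when \code{x} is a
#'   \linkS4class{RatioExperiment}
#' @param test \code{"t"} or \code{"wilcoxon"}
#' @param minAbsLog2,maxP selection thresholds
#' @return \code{DataFrame} with \code{feature_id}, \code{mean_log2},
#'   \code{p_value}, \code{n_replicates}, \code{passes}
#' @export
replicateStats <- function(x, genotype = NULL, timepoint = NULL,
                           test = c("t", "wilcoxon"),
                           minAbsLog2 = 1, maxP = 0.05) {
    test <- match.arg(test)
    if (is(x, "RatioExperiment")) {
        keep <- rep(TRUE, ncol(x))
        cd <- colData(x)
        if (!is.null(genotype)) keep <- keep & cd$genotype %in% genotype
        if (!is.null(timepoint)) keep <- keep & cd$timepoint %in% timepoint
        mat <- assay(x, "log2ratio")[, keep, drop = FALSE]
    } else mat <- as.matrix(x)
    if (ncol(mat) < 2)
        stop("at least 2 replicates are required for a location test")
    if (test == "t") {
        st <- .rowTTest(mat)
    } else {
        p <- apply(mat, 1, function(v)
            if (all(v == 0)) 1 else
            suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value))
        st <- data.frame(mean_log2 = rowMeans(mat), p_value = p)
    }
    DataFrame(feature_id = rownames(mat), mean_log2 = st$mean_log2,
              p_value = st$p_value, n_replicates = ncol(mat),
              passes = abs(st$mean_log2) >= minAbsLog2 &
                  st$p_value < maxP)
}

#' Apply the fold-and-P selection rule
#'
#' Features with |mean log2 ratio| >= \code{minAbsLog2} (closed
#' threshold, i.e. log2 ratio <= -1 or >= 1 at the default) and
#' P < \code{maxP}, optionally restricted to one direction.
#'
#' @param results output of \code{\link{replicateStats}}
#' @param minAbsLog2,maxP selection thresholds
#' @param direction \code{"both"}, \code{"up"} or \code{"down"}
#' @return sorted, deduplicated character vector of feature ids
#' @export
selectDifferential <- function(results, minAbsLog2 = 1, maxP = 0.05,
                               direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    m <- results$mean_log2
    ok <- results$p_value < maxP & switch(direction,
        both = abs(m) >= minAbsLog2,
        up = m >= minAbsLog2,
        down = m <= -minAbsLog2)
    sort(unique(results$feature_id[ok]))
}

#' Fold-based transcript lists for the whole-genome arms
#'
#' Mean log2 ratio across the arm's replicate arrays; \code{up} collects
#' features at >= \code{minFold}-fold up (mean log2 >= log2(minFold)),
#' \code{down} those at >= \code{minFold}-fold down. Boundaries are
#' inclusive: a 2-fold change exactly is selected. No P-value clause is
#' applied by default (two replicate arrays); set \code{maxP} to add one.
#'
#' @param x a \linkS4class{RatioExperiment}
#' @param arm expected arm label; must match the samples' arm metadata
#' @param minFold fold threshold on the natural scale (default 2)
#' @param maxP optional P-value clause (requires >= 2 replicates)
#' @return list with character vectors \code{up} and \code{down}
#' @export
foldLists <- function(x, arm = c("mrna_total", "mrna_ago2ip", "mirna"),
                      minFold = 2, maxP = NULL) {
    arm <- match.arg(arm)
    cd <- colData(x)
    if (!all(cd$arm == arm))
        stop("matrix holds arm(s) ", paste(unique(cd$arm), collapse = ", "),
             " but '", arm, "' was requested")
    mat <- assay(x, "log2ratio")
    m <- rowMeans(mat)
    cut <- log2(minFold)
    pok <- rep(TRUE, length(m))
    if (!is.null(maxP)) pok <- .rowTTest(mat)$p_value < maxP
    list(up = sort(rownames(mat)[m >= cut & pok]),
         down = sort(rownames(mat)[m <= -cut & pok]))
}

#' Per-genotype fold table at one timepoint
#'
#' Mean log2(IRI/sham) per genotype, the shape needed by
#' \code{\link{classifyResponsive}}.
#'
#' @param x a miRNA-arm \linkS4class{RatioExperiment}
#' @param timepoint timepoint to tabulate (default \code{"rep1d"})
#' @return data.frame with columns \code{feature_id}, \code{wildtype},
#'   \code{tlr4_ko}, \code{nfkb_ko} (those present in the data)
#' @export
genotypeFoldTable <- function(x, timepoint = "rep1d") {
    cd <- colData(x)
    keep <- cd$timepoint == timepoint
    if (!any(keep)) stop("no samples at timepoint ", timepoint)
    mat <- assay(x, "log2ratio")[, keep, drop = FALSE]
    gt <- cd$genotype[keep]
    out <- data.frame(feature_id = rownames(mat), stringsAsFactors = FALSE)
    for (g in unique(gt))
        out[[g]] <- rowMeans(mat[, gt == g, drop = FALSE])
    out
}

#' Cross-genotype responsiveness classification
#'
#' A miRNA is called TLR4/NF-kB-responsive when it is upregulated in
#' wild-type (log2 fold >= \code{wtMin}, and P < \code{maxP} when
#' wild-type P values are supplied) while showing decreased expression in
#' both the Tlr4 and the NF-kB knockout (log2 fold <= \code{koMax}).
#'
#' @param table data.frame with columns \code{feature_id},
#'   \code{wildtype}, \code{tlr4_ko}, \code{nfkb_ko} of log2 folds
#' @param wtMin wild-type up threshold (log2; default 1)
#' @param koMax knockout down threshold (log2; default -1)
#' @param pValues optional named numeric vector of wild-type P values
#'   (names = feature ids)
#' @param maxP P threshold used when \code{pValues} is given
#' @return sorted character vector of responsive feature ids
#' @examples
#' tab <- data.frame(feature_id = c("miR-a", "miR-b"),
#'                   wildtype = c(2.6, 2.0),
#'                   tlr4_ko = c(-1.1, -1.5), nfkb_ko = c(-1.1, 0.5))
#' classifyResponsive(tab)   # only miR-a: miR-b fails one knockout clause
#' @export
classifyResponsive <- function(table, wtMin = 1, koMax = -1,
                               pValues = NULL, maxP = 0.05) {
    need <- c("feature_id", "wildtype", "tlr4_ko", "nfkb_ko")
    missing <- setdiff(need, names(table))
    if (length(missing))
        stop("fold table is missing column(s): ",
             paste(missing, collapse = ", "))
    ok <- table$wildtype >= wtMin & table$tlr4_ko <= koMax &
        table$nfkb_ko <= koMax
    if (!is.null(pValues)) {
        p <- pValues[table$feature_id]
        ok <- ok & !is.na(p) & p < maxP
    }
    sort(unique(table$feature_id[ok]))
}
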