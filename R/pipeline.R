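#' Run the full target-calling pipeline on array samples and sequences
#'
#' Convenience wrapper chaining the stages in the pinned order
#' (flag filter -> normalize -> ratio -> lists -> scan -> intersect):
#' miRNA arrays are percentile-scaled, whole-genome arrays
#' LOWESS-normalized; the responsive miRNAs are classified from the
#' cross-genotype fold table; fold lists are built from the total and
#' Ago2-IP arms; sequence targets are predicted for the responsive
#' miRNAs; and the three evidence arms are intersected.
#'
#' @param mirnaSamples named list of miRNA-arm \linkS4class{ArraySample}
#' @param mrnaSamples named list of whole-genome-arm samples (both arms)
#' @param mirnaSeqs named RNA sequences of the miRNAs to scan (ids must
#'   match the array feature ids for responsive classification to line
#'   up)
#' @param utrSeqs named DNA 3'UTR sequences (names = gene ids)
#' @param params \code{\link{scanParams}} for the sequence arm
#' @param minFold fold threshold for the expression arms (default 2)
#' @param quiet suppress per-stage messages
#' @return list with \code{responsive}, \code{foldTable},
#'   \code{predicted}, \code{ago2Up}, \code{mrnaDown}, \code{evidence}
#'   (the evidence table) and \code{multiplicity} (at k = 2)
#' @export
runTargetPipeline <- function(mirnaSamples, mrnaSamples, mirnaSeqs,
                              utrSeqs, params = scanParams(),
                              minFold = 2, quiet = TRUE) {
    run <- if (quiet) suppressMessages else identity
    run({
        mir <- lapply(mirnaSamples, filterFlags)
        mir <- percentileScaleNormalize(mir)
        mirRe <- ratioMatrix(mir, "mirna")

        mrna <- lapply(mrnaSamples, filterFlags)
        mrna <- lapply(mrna, lowessNormalize)
        totalRe <- ratioMatrix(
            Filter(function(s) arm(s) == "mrna_total", mrna), "mrna_total")
        ipRe <- ratioMatrix(
            Filter(function(s) arm(s) == "mrna_ago2ip", mrna),
            "mrna_ago2ip")
    })
    fold <- genotypeFoldTable(mirRe)
    wtStats <- replicateStats(mirRe, genotype = "wildtype",
                              timepoint = "rep1d")
    pv <- stats::setNames(wtStats$p_value, wtStats$feature_id)
    responsive <- classifyResponsive(fold, pValues = pv)

    down <- foldLists(totalRe, "mrna_total", minFold = minFold)$down
    up <- foldLists(ipRe, "mrna_ago2ip", minFold = minFold)$up

    predicted <- predictTargets(mirnaSeqs, utrSeqs, params)
    ev <- intersectEvidence(predicted, ago2Up = up, mrnaDown = down)
    list(responsive = responsive, foldTable = fold, predicted = predicted,
         ago2Up = up, mrnaDown = down, evidence = ev,
         multiplicity = multiplicitySummary(ev, k = 2L))
}
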