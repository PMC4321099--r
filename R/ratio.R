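## Duplicate probes for one feature are collapsed by the median of their
## normalized intensities before any ratio is taken.
.collapseByFeature <- function(p, channel) {
    v <- p[[channel]]
    tapply(v, p$feature_id, stats::median)
}

#' Per-feature log2 ratio of treated over control
#'
#' Two conventions, matching the two array arms. Single-channel miRNA
#' arrays are ratioed between arrays: \code{treated} (IRI) against
#' \code{control} (sham), matched on feature id. Two-colour whole-genome
#' arrays are ratioed within the array: Cy5 (IRI) over Cy3 (sham) of the
#' same slide, with \code{control} omitted. Features with a non-positive
#' normalized intensity on either side are dropped and reported.
#'
#' @param treated an \linkS4class{ArraySample} (normalized, flag-filtered)
#' @param control matching sham \linkS4class{ArraySample}, or \code{NULL}
#'   for within-array two-colour ratios
#' @return data.frame with columns \code{feature_id}, \code{log2_ratio}
#' @export
computeLog2Ratio <- function(treated, control = NULL) {
    stopifnot(is(treated, "ArraySample"))
    if (is.null(control)) {
        if (arm(treated) == "mirna")
            stop("single-channel miRNA arrays need an explicit control")
        num <- .collapseByFeature(probes(treated), "cy5")
        den <- .collapseByFeature(probes(treated), "cy3")
    } else {
        stopifnot(is(control, "ArraySample"))
        num <- .collapseByFeature(probes(treated), "cy5")
        den <- .collapseByFeature(probes(control), "cy5")
        common <- intersect(names(num), names(den))
        num <- num[common]
        den <- den[common]
    }
    ok <- is.finite(num) & is.finite(den) & num > 0 & den > 0
    if (any(!ok))
        message("dropped ", sum(!ok),
                " feature(s) with non-positive or missing intensity: ",
                paste(utils::head(names(num)[!ok], 5), collapse = ", "),
                if (sum(!ok) > 5) ", ..." else "")
    data.frame(feature_id = names(num)[ok],
               log2_ratio = unname(log2(num[ok] / den[ok])),
               stringsAsFactors = FALSE)
}

#' Assemble a log2-ratio matrix across samples
#'
#' For the miRNA arm, IRI arrays are paired with their sham counterparts
#' by (genotype, timepoint, replicate) and ratioed between arrays; for
#' the whole-genome arms each two-colour slide yields one within-array
#' ratio column. Features that fail (flagged out or non-positive) in any
#' retained sample are dropped so the matrix is complete; the drop count
#' is reported.
#'
#' @param samples named list of normalized, flag-filtered
#'   \linkS4class{ArraySample}
#' @param arm which arm to assemble: \code{"mirna"}, \code{"mrna_total"}
#'   or \code{"mrna_ago2ip"}
#' @return a \linkS4class{RatioExperiment}
#' @export
ratioMatrix <- function(samples, arm = c("mirna", "mrna_total",
                                         "mrna_ago2ip")) {
    arm <- match.arg(arm)
    sel <- Filter(function(s) arm(s) == arm, samples)
    if (!length(sel)) stop("no samples in arm '", arm, "'")
    if (arm == "mirna") {
        iri <- Filter(function(s) condition(s) == "iri", sel)
        sham <- Filter(function(s) condition(s) == "sham", sel)
        keyOf <- function(s) paste(genotype(s), timepoint(s),
                                   replicateIndex(s), sep = "|")
        shamKeys <- vapply(sham, keyOf, character(1))
        cols <- lapply(iri, function(s) {
            j <- match(keyOf(s), shamKeys)
            if (is.na(j))
                stop("no sham array matches ", sampleId(s))
            computeLog2Ratio(s, sham[[j]])
        })
        meta <- data.frame(
            genotype = vapply(iri, genotype, character(1)),
            timepoint = vapply(iri, timepoint, character(1)),
            replicate = vapply(iri, replicateIndex, integer(1)),
            arm = arm, stringsAsFactors = FALSE)
        colIds <- vapply(iri, sampleId, character(1))
    } else {
        cols <- lapply(sel, computeLog2Ratio)
        meta <- data.frame(
            genotype = vapply(sel, genotype, character(1)),
            timepoint = vapply(sel, timepoint, character(1)),
            replicate = vapply(sel, replicateIndex, integer(1)),
            arm = arm, stringsAsFactors = FALSE)
        colIds <- vapply(sel, sampleId, character(1))
    }
    feats <- Reduce(intersect, lapply(cols, `[[`, "feature_id"))
    all <- unique(unlist(lapply(cols, `[[`, "feature_id")))
    if (length(feats) < length(all))
        message("dropped ", length(all) - length(feats),
                " feature(s) not quantified in every sample")
    if (!length(feats)) stop("no feature quantified in every sample")
    mat <- vapply(cols, function(cl)
        cl$log2_ratio[match(feats, cl$feature_id)], numeric(length(feats)))
    dimnames(mat) <- list(feats, colIds)
    rownames(meta) <- colIds
    RatioExperiment(mat, meta)
}
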