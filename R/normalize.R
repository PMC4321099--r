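#' QC flag filtering
#'
#' Drops every spot whose flag is negative (bad-quality spots from image
#' quantification carry negative flags) and keeps exactly the probes with
#' flag >= 0. The retention count is reported via \code{message}.
#'
#' @param sample an \linkS4class{ArraySample}
#' @return the filtered \linkS4class{ArraySample}
#' @export
filterFlags <- function(sample) {
    stopifnot(is(sample, "ArraySample"))
    p <- probes(sample)
    keep <- p$flag >= 0
    message(sampleId(sample), ": retained ", sum(keep), "/", nrow(p),
            " probes after flag filtering")
    if (!any(keep))
        warning("all probes flagged out in ", sampleId(sample))
    sample@probes <- p[keep, , drop = FALSE]
    rownames(sample@probes) <- NULL
    validObject(sample)
    sample
}

## percentile with linear interpolation between order statistics
.pctl <- function(x, p) unname(stats::quantile(x, p, type = 7))

#' Between-array 75th-percentile scaling
#'
#' Each array's intensities are multiplied by a scalar chosen so that its
#' 75th-percentile Cy5 intensity equals a cohort reference. The default
#' reference is the geometric mean of the per-array 75th percentiles,
#' which makes the transform idempotent and leaves a single array
#' unchanged; a fixed-constant reference is available instead. Scale
#' factors are attached as attribute \code{"scaleFactors"}.
#'
#' @param samples list of flag-filtered \linkS4class{ArraySample}
#' @param percentile quantile used for scaling (default 0.75)
#' @param reference \code{"geomean"} (default) or \code{"constant"}
#' @param constant reference intensity when \code{reference="constant"}
#' @return the list of rescaled samples, with attribute
#'   \code{"scaleFactors"}
#' @examples
#' \dontrun{norm <- percentileScaleNormalize(filtered)}
#' @export
percentileScaleNormalize <- function(samples, percentile = 0.75,
                                     reference = c("geomean", "constant"),
                                     constant = 1000) {
    reference <- match.arg(reference)
    if (is(samples, "ArraySample")) samples <- list(samples)
    if (!length(samples)) stop("at least one sample is required")
    q <- vapply(samples, function(s) .pctl(probes(s)$cy5, percentile),
                numeric(1))
    if (any(q <= 0))
        stop("sample(s) with non-positive ", percentile * 100,
             "th percentile intensity: ",
             paste(vapply(samples[q <= 0], sampleId, character(1)),
                   collapse = ", "))
    ref <- if (reference == "geomean") exp(mean(log(q))) else constant
    fac <- ref / q
    out <- mapply(function(s, f) {
        s@probes$cy5 <- s@probes$cy5 * f
        if (any(!is.na(s@probes$cy3))) s@probes$cy3 <- s@probes$cy3 * f
        s
    }, samples, fac, SIMPLIFY = FALSE)
    names(out) <- names(samples)
    message("percentile scaling: reference ", signif(ref, 6),
            "; factors ", paste(signif(fac, 4), collapse = ", "))
    attr(out, "scaleFactors") <- unname(fac)
    out
}

## deterministic ranks: ties broken by probe_id
.rankByProbe <- function(x, probe_id) {
    ord <- order(x, probe_id)
    r <- integer(length(x))
    r[ord] <- seq_along(x)
    r
}

#' Rank-consistency-filtered LOWESS normalization
#'
#' Within-array intensity-dependent normalization for two-colour arrays.
#' Per probe, M = log2(cy5/cy3) and A = mean of the log2 channels. The
#' LOWESS trend of M on A is fitted only on rank-consistent probes --
#' those whose Cy5 and Cy3 ranks differ by at most
#' \code{rankTolerance * N} -- so genuinely differential probes (rank
#' inconsistent by construction) do not drag the fit. The fitted trend is
#' interpolated to all probes and subtracted from M; channels are
#' reconstituted from the corrected M and the unchanged A.
#'
#' @param sample a two-channel \linkS4class{ArraySample}
#' @param span LOWESS smoother span (fraction of fit points)
#' @param rankTolerance rank-difference fraction defining consistency
#' @return the normalized \linkS4class{ArraySample}
#' @export
lowessNormalize <- function(sample, span = 0.3, rankTolerance = 0.05) {
    stopifnot(is(sample, "ArraySample"))
    if (arm(sample) == "mirna")
        stop("lowessNormalize requires a two-channel (whole-genome) array")
    p <- probes(sample)
    if (any(p$cy5 <= 0 | p$cy3 <= 0))
        stop("non-positive intensities; filter or offset before LOWESS")
    N <- nrow(p)
    M <- log2(p$cy5 / p$cy3)
    A <- (log2(p$cy5) + log2(p$cy3)) / 2
    r5 <- .rankByProbe(p$cy5, p$probe_id)
    r3 <- .rankByProbe(p$cy3, p$probe_id)
    fitset <- abs(r5 - r3) / N <= rankTolerance
    if (sum(fitset) < 10)
        stop("only ", sum(fitset), " rank-consistent probes; ",
             "increase rankTolerance")
    fit <- stats::lowess(A[fitset], M[fitset], f = span)
    trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
    Mc <- M - trend
    sample@probes$cy5 <- 2^(A + Mc / 2)
    sample@probes$cy3 <- 2^(A - Mc / 2)
    attr(sample, "fitSet") <- fitset
    sample
}
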