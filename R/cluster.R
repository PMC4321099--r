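#' Pearson correlation distance
#'
#' d(i, j) = 1 - r(i, j) between the selected vectors (rows for
#' \code{axis = "features"}, columns for \code{axis = "samples"}), giving
#' a symmetric matrix with zero diagonal and range [0, 2]. A
#' zero-variance vector has no defined correlation and is an error that
#' names the offender.
#'
#' @param x numeric matrix or \linkS4class{RatioExperiment}
#' @param axis cluster features (rows) or samples (columns)
#' @return symmetric distance matrix
#' @export
pearsonDistance <- function(x, axis = c("features", "samples")) {
    axis <- match.arg(axis)
    if (is(x, "RatioExperiment")) x <- assay(x, "log2ratio")
    m <- if (axis == "features") t(x) else x   # cor() works on columns
    v <- apply(m, 2, stats::var)
    if (any(v == 0))
        stop("zero-variance vector(s): ",
             paste(colnames(m)[v == 0], collapse = ", "))
    d <- 1 - stats::cor(m)
    diag(d) <- 0
    d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' arithmetic mean of all pairwise member distances.
#'
#' @param d symmetric distance matrix (e.g. from
#'   \code{\link{pearsonDistance}}) or a \code{dist}
#' @return an \code{hclust} object (merge list, heights, leaf order)
#' @export
averageLinkage <- function(d) {
    if (is.matrix(d)) {
        if (!isSymmetric(unname(d), tol = 1e-8))
            stop("distance matrix must be symmetric")
        d <- stats::as.dist(d)
    }
    stats::hclust(d, method = "average")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights.
#'
#' @param hc an \code{hclust} from \code{\link{averageLinkage}}
#' @param path optional file to write; when \code{NULL} the Newick string
#'   is returned
#' @return the Newick string (invisibly when written to file)
#' @export
dendrogramNewick <- function(hc, path = NULL) {
    phy <- ape::as.phylo(hc)
    if (is.null(path)) ape::write.tree(phy)
    else invisible(ape::write.tree(phy, file = path))
}
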