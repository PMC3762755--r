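#' Pearson distance between samples
#'
#' d(s, t) = 1 - r(s, t) with r the Pearson correlation over the (signature)
#' features: symmetric, zero diagonal, range [0, 2].
#'
#' @param te a [TissueExperiment-class], typically already restricted to a
#'   signature; features with missing values are dropped pairwise by the
#'   correlation.
#' @param signature optional [GeneSignature-class] (or character vector of
#'   feature ids) to restrict the features first; ids absent from the matrix
#'   are dropped, mirroring platform restriction.
#' @return sample x sample distance matrix.
#' @export
sampleDistance <- function(te, signature = NULL) {
    m <- .restrictMatrix(te, signature)
    if (nrow(m) < 2L) stop("at least 2 features are required")
    v <- apply(m, 2L, stats::var, na.rm = TRUE)
    if (any(v == 0 | is.na(v)))
        stop("zero-variance sample: '",
             colnames(m)[which(v == 0 | is.na(v))[1L]], "'")
    1 - stats::cor(m, use = "pairwise.complete.obs")
}

#' Absolute-Pearson distance between genes
#'
#' d(g, h) = 1 - |r(g, h)|, range [0, 1]: perfectly anti-correlated genes
#' are as close as identical ones, grouping co-regulated modules regardless
#' of sign.
#'
#' @inheritParams sampleDistance
#' @return gene x gene distance matrix.
#' @export
geneDistance <- function(te, signature = NULL) {
    m <- .restrictMatrix(te, signature)
    if (ncol(m) < 2L) stop("at least 2 samples are required")
    v <- apply(m, 1L, stats::var, na.rm = TRUE)
    if (any(v == 0 | is.na(v)))
        stop("zero-variance gene: '",
             rownames(m)[which(v == 0 | is.na(v))[1L]], "'")
    1 - abs(stats::cor(t(m), use = "pairwise.complete.obs"))
}

.restrictMatrix <- function(te, signature) {
    m <- if (methods::is(te, "TissueExperiment")) exprsValues(te)
         else as.matrix(te)
    if (!is.null(signature)) {
        ids <- if (methods::is(signature, "GeneSignature"))
            featureIds(signature) else as.character(signature)
        m <- m[intersect(ids, rownames(m)), , drop = FALSE]
    }
    m
}

#' Ward hierarchical clustering on a dissimilarity matrix
#'
#' Agglomerative Ward linkage via the Lance-Williams recurrence applied
#' directly to the supplied dissimilarities (no Euclidean embedding is
#' required, matching the behavior of the classic hcluster/ward pipeline on
#' correlation distances).  Ties are broken by the merge order of
#' \code{stats::hclust}, which is deterministic given the input.
#'
#' @param d symmetric distance matrix or \code{dist} object.
#' @return an \code{hclust} tree (merge matrix, heights, leaf order).
#' @export
wardCluster <- function(d) {
    if (is.matrix(d)) {
        if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
            stop("distance matrix must be symmetric")
        d <- stats::as.dist(d)
    } else if (!inherits(d, "dist"))
        stop("d must be a matrix or a dist object")
    stats::hclust(d, method = "ward.D")
}

#' Class purity at a k-cluster cut
#'
#' Cuts the dendrogram into k clusters, assigns each cluster the majority
#' tissue label of its samples (ties break toward the label with more
#' samples overall, then lexicographically), and counts a sample as correct
#' when its cluster's label matches its own.
#'
#' @param dend an \code{hclust} tree over samples ([wardCluster()]).
#' @param labels named character vector: sample -> tissue code (names must
#'   cover the tree's leaves; unnamed vectors are taken in leaf order).
#' @param k number of clusters; defaults to the number of distinct labels.
#' @return list with \code{classes} (data.frame: tissue_code, n_samples,
#'   n_correct, accuracy), \code{clusterLabel} (cluster -> assigned label),
#'   \code{misclassified} (sample ids), \code{overall} accuracy.
#' @export
scoreClasses <- function(dend, labels, k = NULL) {
    stopifnot(inherits(dend, "hclust"))
    nLeaves <- length(dend$order)
    if (is.null(names(labels)))
        names(labels) <- dend$labels
    labels <- labels[dend$labels]
    if (anyNA(labels)) stop("labels must cover every leaf of the tree")
    if (is.null(k)) k <- length(unique(labels))
    if (k > nLeaves) stop("k cannot exceed the number of samples")
    cl <- stats::cutree(dend, k = k)
    totals <- table(labels)
    clusterLabel <- vapply(split(labels, cl), function(lab) {
        tt <- table(lab)
        best <- names(tt)[tt == max(tt)]
        if (length(best) > 1L) {
            tb <- totals[best]
            best <- best[tb == max(tb)]
            best <- sort(best)[1L]
        }
        best
    }, character(1L))
    assigned <- clusterLabel[as.character(cl)]
    correct <- assigned == labels
    classes <- do.call(rbind, lapply(sort(unique(labels)), function(tc) {
        sel <- labels == tc
        data.frame(tissue_code = tc, n_samples = sum(sel),
                   n_correct = sum(correct[sel]),
                   accuracy = mean(correct[sel]),
                   stringsAsFactors = FALSE)
    }))
    list(classes = classes, clusterLabel = clusterLabel,
         misclassified = names(labels)[!correct],
         overall = mean(correct))
}
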