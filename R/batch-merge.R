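#' Parametric empirical-Bayes batch adjustment
#'
#' Location/scale batch-effect removal for merging studies measured on
#' different platforms, the standard parametric empirical-Bayes pipeline:
#' per gene, estimate a grand mean and pooled variance and standardize; per
#' batch and gene, estimate a location (gamma) and scale (delta^2); shrink
#' both toward moment-matched hyperpriors (normal for gamma, inverse-gamma
#' for delta^2) by iterating the conditional posterior means to convergence;
#' remove the shrunken effects and back-transform.  No covariates are
#' protected and only the parametric priors are offered.
#'
#' Input studies are merged on the intersection of their feature sets.
#'
#' @param x a [TissueExperiment-class] carrying at least two studies in its
#'   \code{study_id} annotation, or a list of TissueExperiments (one per
#'   study).
#' @param tol,maxIter convergence tolerance and iteration cap of the
#'   posterior iteration.
#' @return the adjusted [TissueExperiment-class] (merged, on the common
#'   feature set).
#' @examples
#' sp <- cohortSpec(nProbes = 300, nPlantedDE = 30, nLiverDecoys = 20,
#'                  nTumorGenes = 30, nStudies = 2, seed = 5)
#' co <- generateCohort(sp)
#' bat <- injectBatches(co$experiment, sp)
#' adj <- ebAdjust(bat$experiment)
#' @export
ebAdjust <- function(x, tol = 1e-6, maxIter = 200L) {
    if (is.list(x) && !methods::is(x, "TissueExperiment"))
        x <- .mergeStudies(x)
    stopifnot(methods::is(x, "TissueExperiment"))
    batch <- as.character(studyId(x))
    batches <- unique(batch)
    if (length(batches) < 2L) stop("at least two studies are required")
    nb <- table(batch)
    if (any(nb < 2L))
        stop("singleton batch: '", names(nb)[which(nb < 2L)[1L]], "'")
    m <- exprsValues(x)
    if (anyNA(m))
        stop("missing values are not supported by the EB adjustment; ",
             "filter or impute first")
    N <- ncol(m)
    # gene-wise grand mean weighted by batch size, and pooled variance
    batchMeans <- vapply(batches, function(b)
        rowMeans(m[, batch == b, drop = FALSE]), numeric(nrow(m)))
    w <- as.numeric(nb[batches]) / N
    grand <- as.numeric(batchMeans %*% w)
    fit <- batchMeans[, match(batch, batches)]
    pooledVar <- rowSums((m - fit)^2) / N
    if (any(pooledVar == 0))
        stop("zero pooled variance for probe '",
             rownames(m)[which(pooledVar == 0)[1L]], "'")
    Z <- (m - grand) / sqrt(pooledVar)
    adj <- Z
    for (b in batches) {
        idx <- which(batch == b)
        n <- length(idx)
        Zb <- Z[, idx, drop = FALSE]
        gammaHat <- rowMeans(Zb)
        delta2Hat <- rowSums((Zb - gammaHat)^2) / (n - 1)
        gBar <- mean(gammaHat)
        t2 <- stats::var(gammaHat)
        dM <- mean(delta2Hat)
        dV <- stats::var(delta2Hat)
        aPrior <- (2 * dV + dM^2) / dV
        bPrior <- (dM * dV + dM^3) / dV
        gStar <- gammaHat
        d2Star <- delta2Hat
        for (it in seq_len(maxIter)) {
            gNew <- (n * t2 * gammaHat + d2Star * gBar) /
                (n * t2 + d2Star)
            ss <- rowSums((Zb - gNew)^2)
            dNew <- (0.5 * ss + bPrior) / (n / 2 + aPrior - 1)
            change <- max(abs(gNew - gStar), abs(dNew - d2Star))
            gStar <- gNew; d2Star <- dNew
            if (change < tol) break
        }
        adj[, idx] <- (Zb - gStar) / sqrt(d2Star)
    }
    out <- adj * sqrt(pooledVar) + grand
    SummarizedExperiment::assay(x, "exprs") <- out
    x
}

# cbind a list of TissueExperiments on their common probes.
.mergeStudies <- function(xs) {
    stopifnot(length(xs) >= 2L,
              all(vapply(xs, methods::is, logical(1L), "TissueExperiment")))
    common <- Reduce(intersect, lapply(xs, rownames))
    if (!length(common))
        stop("studies share no features; nothing to merge")
    values <- do.call(cbind, lapply(xs, function(te)
        exprsValues(te)[common, , drop = FALSE]))
    TissueExperiment(values,
                     unlist(lapply(xs, function(te)
                         as.character(tissueCode(te)))),
                     unlist(lapply(xs, function(te)
                         as.character(patientId(te)))),
                     unlist(lapply(xs, function(te)
                         as.character(studyId(te)))),
                     scale = "log2")
}

#' Per-study HM/CT ratio table for a signature
#'
#' For every signature gene and study, the mean log2 expression over HM
#' samples minus the mean over CT samples; genes are ordered from most
#' down- to most up-regulated in the reference study.  Studies lacking
#' either tissue are omitted with a warning.
#'
#' @param te a merged log2-scale [TissueExperiment-class] with study ids and
#'   CT/HM tissue codes.
#' @param sig a [GeneSignature-class] (features must match the matrix's
#'   rownames; absent features are dropped).
#' @param referenceStudy study whose ratios define the gene ordering;
#'   default the first study listed.
#' @return numeric gene x study matrix of mean log2(HM/CT) ratios, rows
#'   ordered by the reference study's ratio ascending.
#' @export
ratioTable <- function(te, sig, referenceStudy = NULL) {
    stopifnot(methods::is(te, "TissueExperiment"),
              methods::is(sig, "GeneSignature"))
    feats <- intersect(featureIds(sig), rownames(te))
    if (!length(feats)) stop("no signature feature present in the matrix")
    m <- exprsValues(te)[feats, , drop = FALSE]
    batch <- as.character(studyId(te))
    tissue <- as.character(tissueCode(te))
    studies <- unique(batch)
    cols <- list()
    for (s in studies) {
        ct <- batch == s & tissue == "CT"
        hm <- batch == s & tissue == "HM"
        if (!any(ct) || !any(hm)) {
            warning("study '", s, "' lacks CT or HM samples; omitted")
            next
        }
        cols[[s]] <- rowMeans(m[, hm, drop = FALSE], na.rm = TRUE) -
            rowMeans(m[, ct, drop = FALSE], na.rm = TRUE)
    }
    if (!length(cols)) stop("no study has both CT and HM samples")
    tab <- do.call(cbind, cols)
    if (is.null(referenceStudy)) referenceStudy <- colnames(tab)[1L]
    if (!referenceStudy %in% colnames(tab))
        stop("reference study '", referenceStudy, "' not in the table")
    tab[order(tab[, referenceStudy]), , drop = FALSE]
}
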