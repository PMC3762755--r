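#' @name accessors
#' @title Accessors for metasig classes
#' @description Slot access for the package's S4 classes goes through these
#'   accessors, never through \code{@}.
#' @param x,object an object of the documented class.
#' @return the annotated component (see the individual generics).
NULL

#' @describeIn accessors per-sample tissue codes of a TissueExperiment.
#' @export
setGeneric("tissueCode", function(x) standardGeneric("tissueCode"))

#' @describeIn accessors per-sample patient ids.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @describeIn accessors per-sample study ids.
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @describeIn accessors scale flag, \code{"linear"} or \code{"log2"}.
#' @export
setGeneric("exprsScale", function(x) standardGeneric("exprsScale"))

#' @describeIn accessors expression matrix (assay \code{"exprs"}).
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @describeIn accessors number of pairs in a PairedDesign.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @describeIn accessors pair table of a PairedDesign.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @describeIn accessors feature ids of a GeneSignature.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @describeIn accessors entry table of a GeneSignature (or the signature of
#'   a SignatureFilterResult).
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))

#' @describeIn accessors per-probe statistic table of a SamResult.
#' @export
setGeneric("samTable", function(x) standardGeneric("samTable"))

#' @describeIn accessors probe-level audit trail of a SignatureFilterResult.
#' @export
setGeneric("auditTable", function(x) standardGeneric("auditTable"))

#' @describeIn accessors probe classes of a CohortTruth.
#' @export
setGeneric("probeClass", function(x) standardGeneric("probeClass"))

#' @describeIn accessors contamination fraction per HM sample (CohortTruth).
#' @export
setGeneric("lambdaBySample", function(x) standardGeneric("lambdaBySample"))

setMethod("tissueCode", "TissueExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$tissue_code, colnames(x)))

setMethod("patientId", "TissueExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$patient_id, colnames(x)))

setMethod("studyId", "TissueExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$study_id, colnames(x)))

setMethod("exprsScale", "TissueExperiment", function(x)
    S4Vectors::metadata(x)$scale)

setMethod("exprsValues", "TissueExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

setMethod("nPairs", "PairedDesign", function(x) nrow(x@pairs))

setMethod("pairTable", "PairedDesign", function(x) x@pairs)

setMethod("featureIds", "GeneSignature", function(x) x@entries$feature_id)

setMethod("signatureTable", "GeneSignature", function(x) x@entries)

setMethod("signatureTable", "SignatureFilterResult", function(x)
    x@signature@entries)

setMethod("samTable", "SamResult", function(x) x@table)

setMethod("auditTable", "SignatureFilterResult", function(x) x@audit)

setMethod("probeClass", "CohortTruth", function(x) x@probeClass)

setMethod("lambdaBySample", "CohortTruth", function(x) x@lambdaBySample)

#' @describeIn accessors number of entries in a GeneSignature.
#' @export
setMethod("length", "GeneSignature", function(x) nrow(x@entries))

setMethod("show", "TissueExperiment", function(object) {
    cat("TissueExperiment:", nrow(object), "probes x", ncol(object),
        "samples (", S4Vectors::metadata(object)$scale, "scale )\n")
    tc <- table(SummarizedExperiment::colData(object)$tissue_code)
    cat("  tissues:", paste(names(tc), tc, sep = ":", collapse = " "), "\n")
    st <- unique(SummarizedExperiment::colData(object)$study_id)
    cat("  studies:", paste(st, collapse = ", "), "\n")
})

setMethod("show", "PairedDesign", function(object) {
    cat("PairedDesign:", nrow(object@pairs), "pairs (",
        object@roleA, "/", object@roleB, ")\n")
})

setMethod("show", "GeneSignature", function(object) {
    dirs <- table(factor(object@entries$direction,
                         c("up_in_HM", "down_in_HM")))
    cat("GeneSignature:", nrow(object@entries), object@featureSpace,
        "features (", dirs[["up_in_HM"]], "up_in_HM,",
        dirs[["down_in_HM"]], "down_in_HM )\n")
})

setMethod("show", "SamResult", function(object) {
    cat("SamResult:", nrow(object@table), "probes, s0 =",
        signif(object@s0, 4), ",", object@nPermutations,
        if (object@exhaustive) "exhaustive sign flips\n"
        else "sampled sign flips\n")
})

setMethod("show", "SignatureFilterResult", function(object) {
    cat("SignatureFilterResult:", nrow(object@audit), "candidates ->",
        nrow(object@signature@entries), "kept\n")
})

setMethod("show", "CohortTruth", function(object) {
    cl <- table(object@probeClass)
    cat("CohortTruth:", paste(names(cl), cl, sep = ":", collapse = " "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
    cat("CohortSpec:", object@nPairs, "CT/HM pairs,", object@nRefPairs,
        "CT/HN reference pairs,", object@nProbes, "probes\n")
    cat("  planted:", object@nPlantedDE, "decoys:", object@nLiverDecoys,
        "tumor genes:", object@nTumorGenes, "\n")
    cat("  lambda ~ U(", object@lambdaRange[1], ",", object@lambdaRange[2],
        "), noise sd", object@noiseSd, "(log2), seed", object@seed, "\n")
})
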