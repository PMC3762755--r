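#' Valid two-letter tissue codes
#'
#' Samples are annotated with a two-letter code: the first letter gives the
#' organ (C colon, H hepatic, L lung, P peritoneum) and the second the tissue
#' state (N normal, P polyp, T primary tumor, M metastasis).  The alphabet is
#' closed but can be extended by the caller so that additional validation
#' cohorts (e.g. lung metastases, peritoneal carcinomatoses) load unchanged.
#'
#' @param extra character vector of additional codes to accept.
#' @return character vector of accepted codes.
#' @examples
#' validTissueCodes()
#' @export
validTissueCodes <- function(extra = character()) {
    codes <- as.vector(outer(c("C", "H", "L", "P"),
                             c("N", "P", "T", "M"), paste0))
    unique(c(codes, as.character(extra)))
}

#' TissueExperiment: annotated expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding a probe x sample matrix of
#' expression values (assay \code{"exprs"}) together with the per-sample
#' annotations the pipeline needs: \code{tissue_code}, \code{patient_id} and
#' \code{study_id} columns of \code{colData}.  A scale flag in
#' \code{metadata()$scale} (\code{"linear"} or \code{"log2"}) guards against
#' double log-transformation.
#'
#' @seealso [TissueExperiment()] for the constructor,
#'   [tissueCode()], [patientId()], [studyId()], [exprsScale()] accessors.
#' @export
setClass("TissueExperiment", contains = "SummarizedExperiment")

.validTissueExperiment <- function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("tissue_code", "patient_id", "study_id")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    if (nrow(object) > 0L &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "probe ids must be present and unique")
    if (ncol(object) > 0L &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "sample ids must be present and unique")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("linear", "log2"))
        msg <- c(msg, "metadata()$scale must be 'linear' or 'log2'")
    if (!length(miss)) {
        allowed <- S4Vectors::metadata(object)$tissue_alphabet
        if (is.null(allowed)) allowed <- validTissueCodes()
        bad <- !cd$tissue_code %in% allowed
        if (any(bad))
            msg <- c(msg, paste0("unknown tissue code '",
                                 cd$tissue_code[which(bad)[1L]],
                                 "' for sample '",
                                 colnames(object)[which(bad)[1L]], "'"))
    }
    if (length(msg)) msg else TRUE
}
setValidity("TissueExperiment", .validTissueExperiment)

#' Construct a TissueExperiment
#'
#' @param values numeric probe x sample matrix with rownames (probe ids) and
#'   colnames (sample ids); missing entries allowed as \code{NA}.
#' @param tissueCode,patientId,studyId per-sample annotation vectors, recycled
#'   checked against \code{ncol(values)}.
#' @param scale \code{"log2"} (default) or \code{"linear"}.
#' @param extraCodes additional tissue codes accepted beyond the built-in
#'   16-code alphabet (see [validTissueCodes()]).
#' @return a [TissueExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' te <- TissueExperiment(m, c("CT", "HM", "CN"), c("P1", "P1", "P2"))
#' tissueCode(te)
#' @export
TissueExperiment <- function(values, tissueCode, patientId,
                             studyId = "S1", scale = c("log2", "linear"),
                             extraCodes = character()) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (ncol(values) > 0L) {
        tissueCode <- rep_len(as.character(tissueCode), ncol(values))
        patientId <- rep_len(as.character(patientId), ncol(values))
        studyId <- rep_len(as.character(studyId), ncol(values))
    } else {
        tissueCode <- patientId <- studyId <- character()
    }
    if (is.null(rownames(values)) && nrow(values) > 0L)
        stop("'values' must carry probe ids as rownames")
    if (anyDuplicated(rownames(values)))
        stop("duplicated probe id: '",
             rownames(values)[anyDuplicated(rownames(values))], "'")
    if (anyDuplicated(colnames(values)))
        stop("duplicated sample id: '",
             colnames(values)[anyDuplicated(colnames(values))], "'")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(tissue_code = tissueCode,
                                       patient_id = patientId,
                                       study_id = studyId,
                                       row.names = colnames(values)))
    S4Vectors::metadata(se)$scale <- scale
    S4Vectors::metadata(se)$tissue_alphabet <- validTissueCodes(extraCodes)
    methods::new("TissueExperiment", se)
}

#' PairedDesign: patient-matched sample pairs
#'
#' Ordered list of (patient, sample A, sample B) triples with the tissue role
#' of each side, e.g. A = CT, B = HM.  Used for paired statistics and ratio
#' computation; each patient contributes at most one pair.
#'
#' @slot pairs data.frame with columns \code{patient_id}, \code{sample_A},
#'   \code{sample_B}, ordered by patient id.
#' @slot roleA,roleB the tissue codes of the two sides.
#' @seealso [buildPairs()]
#' @export
setClass("PairedDesign",
         representation(pairs = "data.frame",
                        roleA = "character", roleB = "character"))

.validPairedDesign <- function(object) {
    msg <- character()
    p <- object@pairs
    if (!all(c("patient_id", "sample_A", "sample_B") %in% colnames(p)))
        msg <- c(msg, "pairs needs patient_id, sample_A, sample_B columns")
    else if (anyDuplicated(p$patient_id))
        msg <- c(msg, "each patient may contribute at most one pair")
    if (length(msg)) msg else TRUE
}
setValidity("PairedDesign", .validPairedDesign)

#' SamResult: paired SAM statistics and permutation q-values
#'
#' @slot table data.frame with one row per probe: \code{probe},
#'   \code{mean_diff} (mean paired log2 difference), \code{se},
#'   \code{d} (SAM statistic), \code{q} (permutation FDR estimate),
#'   \code{n_pairs} (complete pairs used).
#' @slot s0 the fudge factor used.
#' @slot nPermutations number of sign-flip permutations evaluated.
#' @slot exhaustive whether all 2^n sign flips were enumerated.
#' @seealso [permutationFDR()], [selectProbes()]
#' @export
setClass("SamResult",
         representation(table = "data.frame", s0 = "numeric",
                        nPermutations = "integer", exhaustive = "logical"))

#' ReferenceEnvelope: per-probe CT/HN ratio bounds
#'
#' Minimum and maximum of log2(pCT/pHN) across the reference tumor/normal-liver
#' pairs, bracketing the unknown liver baseline of every probe.
#'
#' @slot probe probe ids.
#' @slot xMin,xMax envelope bounds in log2 units (NA where no reference pair
#'   had complete data: such probes are unfilterable).
#' @seealso [referenceEnvelope()]
#' @export
setClass("ReferenceEnvelope",
         representation(probe = "character",
                        xMin = "numeric", xMax = "numeric"))

setValidity("ReferenceEnvelope", function(object) {
    if (length(object@probe) != length(object@xMin) ||
        length(object@probe) != length(object@xMax))
        return("probe, xMin, xMax must have equal length")
    bad <- !is.na(object@xMin) & !is.na(object@xMax) &
        object@xMin > object@xMax
    if (any(bad)) return("xMin must be <= xMax for every probe")
    TRUE
})

#' GeneSignature: directed feature list
#'
#' Ordered list of probe or gene identifiers with the direction of change in
#' hepatic metastasis versus paired primary tumor, the headline output of the
#' pipeline.
#'
#' @slot entries data.frame with columns \code{feature_id},
#'   \code{direction} (\code{"up_in_HM"} or \code{"down_in_HM"}) and
#'   \code{source_probes} (semicolon-joined provenance probe ids).
#' @slot featureSpace \code{"probe"} or \code{"gene"}.
#' @seealso [probesToGenes()], [restrictToPlatform()],
#'   [liverMetastasisSignature()]
#' @export
setClass("GeneSignature",
         representation(entries = "data.frame", featureSpace = "character"))

.validGeneSignature <- function(object) {
    msg <- character()
    e <- object@entries
    if (!all(c("feature_id", "direction", "source_probes") %in% colnames(e)))
        msg <- c(msg, "entries needs feature_id, direction, source_probes")
    else {
        if (anyDuplicated(e$feature_id))
            msg <- c(msg, "feature ids must be unique")
        if (nrow(e) && !all(e$direction %in% c("up_in_HM", "down_in_HM")))
            msg <- c(msg, "direction must be up_in_HM or down_in_HM")
    }
    if (!object@featureSpace %in% c("probe", "gene"))
        msg <- c(msg, "featureSpace must be 'probe' or 'gene'")
    if (length(msg)) msg else TRUE
}
setValidity("GeneSignature", .validGeneSignature)

#' Construct a GeneSignature
#'
#' @param featureId character vector of unique probe or gene ids.
#' @param direction per feature, \code{"up_in_HM"} or \code{"down_in_HM"}.
#' @param sourceProbes provenance probe ids (semicolon-joined when several);
#'   defaults to the feature ids themselves for probe-space signatures.
#' @param featureSpace \code{"probe"} or \code{"gene"}.
#' @return a [GeneSignature-class].
#' @export
GeneSignature <- function(featureId, direction,
                          sourceProbes = featureId,
                          featureSpace = c("probe", "gene")) {
    featureSpace <- match.arg(featureSpace)
    entries <- data.frame(feature_id = as.character(featureId),
                          direction = as.character(direction),
                          source_probes = as.character(sourceProbes),
                          stringsAsFactors = FALSE)
    methods::new("GeneSignature", entries = entries,
                 featureSpace = featureSpace)
}

#' SignatureFilterResult: contamination-filter output with audit trail
#'
#' @slot signature the kept probes as a probe-space [GeneSignature-class].
#' @slot audit data.frame with one row per candidate probe: vote counts per
#'   quadrant, number of usable pairs, kept flag, direction and reason code.
#' @slot verdicts list with per-envelope (min/max) probe x pair verdict
#'   matrices, for diagnostics and plotting.
#' @slot params the [filterParams()] used.
#' @seealso [applyContaminationFilter()]
#' @export
setClass("SignatureFilterResult",
         representation(signature = "GeneSignature", audit = "data.frame",
                        verdicts = "list", params = "list"))

#' CohortTruth: planted structure of a synthetic cohort
#'
#' @slot probeClass named character vector: each probe is exactly one of
#'   \code{planted_up}, \code{planted_down}, \code{liver_decoy},
#'   \code{tumor_gene}, \code{null}.
#' @slot lambdaBySample named numeric: contamination fraction of each HM
#'   sample.
#' @slot batchBySample named character: study assignment after
#'   [injectBatches()] (empty before).
#' @seealso [generateCohort()]
#' @export
setClass("CohortTruth",
         representation(probeClass = "character",
                        lambdaBySample = "numeric",
                        batchBySample = "character"))

#' CohortSpec: parameters of the synthetic paired cohort
#'
#' Defaults mirror the geometry of the discovery study: 13 patients with a
#' CT/HM pair, 6 reference CT/HN pairs, contamination fraction drawn
#' uniformly on (0, 0.5) per metastasis sample (the pathology criterion keeps
#' cancer-cell content at 50\% or more), log-normal measurement noise, and
#' planted truth (metastasis effects, liver-marker decoys, primary-tumor
#' effects) on disjoint probe sets.
#'
#' @seealso [cohortSpec()] for the constructor and argument meanings.
#' @export
setClass("CohortSpec",
         representation(nPairs = "integer", nRefPairs = "integer",
                        nProbes = "integer", nPlantedDE = "integer",
                        plantedLog2fcRange = "numeric",
                        nLiverDecoys = "integer",
                        decoyLiverLog2fcRange = "numeric",
                        nTumorGenes = "integer",
                        tumorLog2fcRange = "numeric",
                        nCN = "integer", nHN = "integer",
                        lambdaRange = "numeric", noiseSd = "numeric",
                        baselineMean = "numeric", baselineSd = "numeric",
                        nStudies = "integer", batchShiftSd = "numeric",
                        batchScaleSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    cnt <- c(object@nPairs, object@nRefPairs, object@nProbes,
             object@nPlantedDE, object@nLiverDecoys, object@nTumorGenes,
             object@nCN, object@nHN)
    if (any(is.na(cnt)) || any(cnt < 0L))
        msg <- c(msg, "all counts must be >= 0")
    if (object@nPlantedDE + object@nLiverDecoys + object@nTumorGenes >
        object@nProbes)
        msg <- c(msg, "planted + decoy + tumor probes exceed nProbes")
    lr <- object@lambdaRange
    if (length(lr) != 2L || lr[1] > lr[2] || lr[1] < 0 || lr[2] >= 1)
        msg <- c(msg, "lambdaRange must be (lo, hi) within [0, 1)")
    for (nm in c("plantedLog2fcRange", "decoyLiverLog2fcRange",
                 "tumorLog2fcRange")) {
        r <- methods::slot(object, nm)
        if (length(r) != 2L || r[1] > r[2])
            msg <- c(msg, paste(nm, "must be (lo, hi) with lo <= hi"))
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})
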