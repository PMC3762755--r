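#' Specify a synthetic paired cohort
#'
#' Builds a validated [CohortSpec-class].  The defaults reproduce the
#' geometry of the discovery cohort: 13 patients contributing a primary-tumor
#' (CT) / hepatic-metastasis (HM) pair, 6 independent reference patients
#' contributing a CT / normal-liver (HN) pair, a contamination fraction
#' lambda drawn uniformly on (0, 0.5) for every HM sample (metastases are
#' pathology-checked to contain at least 50 percent cancer cells, so the
#' admixed normal-liver fraction is bounded at one half), and log-normal
#' measurement noise of 0.4 log2 units.
#'
#' Probe classes are disjoint: \code{nPlantedDE} probes carry a true
#' metastasis effect (half up, half down, |log2 fold change| drawn from
#' \code{plantedLog2fcRange}); \code{nLiverDecoys} probes are liver markers
#' whose pure metastasis expression equals the tumor's but whose normal-liver
#' expression is higher by \code{decoyLiverLog2fcRange} log2 units (these are
#' the false positives contamination creates); \code{nTumorGenes} probes
#' differ between normal colon (CN) and CT by \code{tumorLog2fcRange} log2
#' units in either direction (carried into the metastasis), giving the
#' three-class CN/CT/HM structure; the rest are null.
#'
#' @param nPairs patients with a CT+HM pair.
#' @param nRefPairs reference patients with a CT+HN pair.
#' @param nProbes total probes.
#' @param nPlantedDE probes with a true metastasis effect.
#' @param plantedLog2fcRange (lo, hi) magnitude of planted effects, log2.
#' @param nLiverDecoys liver-marker decoy probes.
#' @param decoyLiverLog2fcRange (lo, hi) of log2(pHN/pCT) for decoys.
#' @param nTumorGenes probes with a CN-vs-CT effect.
#' @param tumorLog2fcRange (lo, hi) magnitude of tumor effects, log2.
#' @param nCN normal-colon samples emitted (attached to the first paired
#'   patients, like the study's mucosa samples).
#' @param nHN standalone normal-liver samples emitted.
#' @param lambdaRange (lo, hi) of the per-HM-sample contamination fraction,
#'   within [0, 1).
#' @param noiseSd log-normal noise, sd in log2 units.
#' @param baselineMean,baselineSd per-probe baseline log2 abundance
#'   distribution (Normal).
#' @param nStudies number of studies for [injectBatches()] (>= 2 to use it).
#' @param batchShiftSd,batchScaleSd per-study per-probe additive shift sd
#'   (log2) and multiplicative residual-scale sd.
#' @param seed integer seed; all generator streams derive from it.
#' @return a [CohortSpec-class].
#' @examples
#' cohortSpec(nProbes = 1000, seed = 7)
#' @export
cohortSpec <- function(nPairs = 13, nRefPairs = 6, nProbes = 10000,
                       nPlantedDE = 150, plantedLog2fcRange = c(1.5, 3),
                       nLiverDecoys = 300,
                       decoyLiverLog2fcRange = c(1, 6),
                       nTumorGenes = 150, tumorLog2fcRange = c(0.5, 2),
                       nCN = nPairs, nHN = 6,
                       lambdaRange = c(0, 0.5), noiseSd = 0.4,
                       baselineMean = 8, baselineSd = 1.5,
                       nStudies = 1, batchShiftSd = 0.5,
                       batchScaleSd = 0, seed = 1) {
    methods::new("CohortSpec",
                 nPairs = as.integer(nPairs),
                 nRefPairs = as.integer(nRefPairs),
                 nProbes = as.integer(nProbes),
                 nPlantedDE = as.integer(nPlantedDE),
                 plantedLog2fcRange = as.numeric(plantedLog2fcRange),
                 nLiverDecoys = as.integer(nLiverDecoys),
                 decoyLiverLog2fcRange = as.numeric(decoyLiverLog2fcRange),
                 nTumorGenes = as.integer(nTumorGenes),
                 tumorLog2fcRange = as.numeric(tumorLog2fcRange),
                 nCN = as.integer(nCN), nHN = as.integer(nHN),
                 lambdaRange = as.numeric(lambdaRange),
                 noiseSd = as.numeric(noiseSd),
                 baselineMean = as.numeric(baselineMean),
                 baselineSd = as.numeric(baselineSd),
                 nStudies = as.integer(nStudies),
                 batchShiftSd = as.numeric(batchShiftSd),
                 batchScaleSd = as.numeric(batchScaleSd),
                 seed = as.integer(seed))
}

# Probe-level profiles shared by the cohort and the reference pairs: drawn
# from spec@seed so both ops see the same liver/colon biology, while sample
# noise comes from separate substreams.
.cohortProfiles <- function(spec) {
    probes <- sprintf("probe_%05d", seq_len(spec@nProbes))
    cls <- rep("null", spec@nProbes)
    iPl <- seq_len(spec@nPlantedDE)
    iDe <- spec@nPlantedDE + seq_len(spec@nLiverDecoys)
    iTu <- spec@nPlantedDE + spec@nLiverDecoys + seq_len(spec@nTumorGenes)
    nUp <- ceiling(spec@nPlantedDE / 2)
    cls[iPl] <- rep(c("planted_up", "planted_down"),
                    c(nUp, spec@nPlantedDE - nUp))
    cls[iDe] <- "liver_decoy"
    cls[iTu] <- "tumor_gene"
    set.seed(spec@seed)
    baseline <- stats::rnorm(spec@nProbes, spec@baselineMean,
                             spec@baselineSd)
    plantedEff <- numeric(spec@nProbes)
    plantedEff[iPl] <- ifelse(cls[iPl] == "planted_up", 1, -1) *
        stats::runif(spec@nPlantedDE, spec@plantedLog2fcRange[1],
                     spec@plantedLog2fcRange[2])
    decoyEff <- numeric(spec@nProbes)
    decoyEff[iDe] <- stats::runif(spec@nLiverDecoys,
                                  spec@decoyLiverLog2fcRange[1],
                                  spec@decoyLiverLog2fcRange[2])
    tumorEff <- numeric(spec@nProbes)
    tumorEff[iTu] <- sample(c(-1, 1), spec@nTumorGenes, replace = TRUE) *
        stats::runif(spec@nTumorGenes, spec@tumorLog2fcRange[1],
                     spec@tumorLog2fcRange[2])
    list(probes = probes, class = stats::setNames(cls, probes),
         cn = baseline,                       # normal colon, log2
         ct = baseline + tumorEff,            # primary tumor
         hmPure = baseline + tumorEff + plantedEff,  # uncontaminated HM
         hn = baseline + decoyEff)            # normal liver
}

#' Generate a synthetic paired cohort with known truth
#'
#' Emits CN, CT and HM samples (plus optional standalone HN samples) for the
#' patients of a [cohortSpec()], with the planted structure recorded in a
#' [CohortTruth-class].  The pure metastasis profile is the tumor profile
#' plus the planted effects; the observed HM intensity is the linear-space
#' mixture (1 - lambda_s) * pure HM + lambda_s * normal liver, to which
#' log-normal noise is applied before the log2 transform — contamination
#' physically mixes RNA mass, so the mixing model is linear even though
#' everything is reported in log2 units.  Deterministic under the spec's
#' seed.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements \code{experiment} (a log2-scale
#'   [TissueExperiment-class]) and \code{truth} (a [CohortTruth-class]).
#' @examples
#' co <- generateCohort(cohortSpec(nProbes = 200, nPlantedDE = 20,
#'                                 nLiverDecoys = 20, nTumorGenes = 20,
#'                                 noiseSd = 0, seed = 3))
#' co$experiment
#' @export
generateCohort <- function(spec) {
    stopifnot(methods::is(spec, "CohortSpec"))
    methods::validObject(spec)
    pr <- .cohortProfiles(spec)
    set.seed(spec@seed + 1L)
    pat <- sprintf("P%02d", seq_len(spec@nPairs))
    lambda <- stats::runif(spec@nPairs, spec@lambdaRange[1],
                           spec@lambdaRange[2])
    noise <- function(n) if (spec@noiseSd > 0)
        stats::rnorm(n, 0, spec@noiseSd) else numeric(n)
    nP <- spec@nProbes
    cols <- list(); tissue <- character(); patient <- character()
    cnPat <- pat[seq_len(min(spec@nCN, spec@nPairs))]
    if (spec@nCN > spec@nPairs)
        cnPat <- c(cnPat, sprintf("Q%02d", seq_len(spec@nCN - spec@nPairs)))
    for (p in cnPat) {
        cols[[paste0(p, "_CN")]] <- pr$cn + noise(nP)
        tissue <- c(tissue, "CN"); patient <- c(patient, p)
    }
    for (i in seq_len(spec@nPairs)) {
        cols[[paste0(pat[i], "_CT")]] <- pr$ct + noise(nP)
        tissue <- c(tissue, "CT"); patient <- c(patient, pat[i])
    }
    hmNames <- character(spec@nPairs)
    for (i in seq_len(spec@nPairs)) {
        mix <- log2((1 - lambda[i]) * 2^pr$hmPure + lambda[i] * 2^pr$hn)
        hmNames[i] <- paste0(pat[i], "_HM")
        cols[[hmNames[i]]] <- mix + noise(nP)
        tissue <- c(tissue, "HM"); patient <- c(patient, pat[i])
    }
    for (i in seq_len(spec@nHN)) {
        nm <- sprintf("N%02d_HN", i)
        cols[[nm]] <- pr$hn + noise(nP)
        tissue <- c(tissue, "HN"); patient <- c(patient, sprintf("N%02d", i))
    }
    values <- do.call(cbind, cols)
    rownames(values) <- pr$probes
    te <- TissueExperiment(values, tissue, patient, "S1", scale = "log2")
    truth <- methods::new("CohortTruth",
                          probeClass = pr$class,
                          lambdaBySample = stats::setNames(lambda, hmNames),
                          batchBySample = character())
    list(experiment = te, truth = truth)
}

#' Generate reference tumor / normal-liver pairs
#'
#' Emits CT/HN pairs for independent reference patients sharing the cohort's
#' probe-level colon and liver profiles (same spec, same seed-derived
#' biology) with independent measurement noise.  These pairs supply the
#' per-probe CT/HN ratio envelope of the contamination filter.
#'
#' @param spec a [CohortSpec-class] with \code{nRefPairs >= 1}.
#' @return list with \code{experiment} (log2 [TissueExperiment-class]) and
#'   \code{design} (the CT/HN [PairedDesign-class]).
#' @export
generateReferencePairs <- function(spec) {
    stopifnot(methods::is(spec, "CohortSpec"))
    methods::validObject(spec)
    if (spec@nRefPairs < 1L)
        stop("nRefPairs must be >= 1: the reference envelope is undefined ",
             "without reference pairs")
    pr <- .cohortProfiles(spec)
    set.seed(spec@seed + 2L)
    noise <- function(n) if (spec@noiseSd > 0)
        stats::rnorm(n, 0, spec@noiseSd) else numeric(n)
    pat <- sprintf("R%02d", seq_len(spec@nRefPairs))
    cols <- list(); tissue <- character(); patient <- character()
    for (p in pat) {
        cols[[paste0(p, "_CT")]] <- pr$ct + noise(spec@nProbes)
        cols[[paste0(p, "_HN")]] <- pr$hn + noise(spec@nProbes)
        tissue <- c(tissue, "CT", "HN"); patient <- c(patient, p, p)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- pr$probes
    te <- TissueExperiment(values, tissue, patient, "REF", scale = "log2")
    list(experiment = te, design = buildPairs(te, "CT", "HN"))
}

#' Inject multi-study batch effects
#'
#' Partitions the cohort's patients into \code{spec@nStudies} studies (all
#' samples of a patient stay together) and applies, per study and probe, an
#' additive log2 shift drawn from Normal(0, batchShiftSd) and a
#' multiplicative scaling of the residual around the probe's grand mean with
#' factor drawn from 2^Normal(0, batchScaleSd).  With both sds zero the
#' matrix is returned unchanged (up to the study relabeling).
#'
#' @param te a log2-scale [TissueExperiment-class].
#' @param spec the [CohortSpec-class] (uses \code{nStudies},
#'   \code{batchShiftSd}, \code{batchScaleSd}, \code{seed}).
#' @param truth optional [CohortTruth-class] to update with the batch
#'   assignments.
#' @return list with \code{experiment} (study ids reassigned), \code{batch}
#'   (named character, sample -> study) and \code{truth} (updated, or NULL).
#' @export
injectBatches <- function(te, spec, truth = NULL) {
    stopifnot(methods::is(te, "TissueExperiment"),
              methods::is(spec, "CohortSpec"))
    if (spec@nStudies < 2L)
        stop("nStudies must be >= 2 to inject batch effects")
    set.seed(spec@seed + 3L)
    pats <- sort(unique(as.character(patientId(te))))
    study <- sprintf("S%d", rep_len(seq_len(spec@nStudies),
                                    length(pats)))[sample(length(pats))]
    names(study) <- pats
    sampleStudy <- study[as.character(patientId(te))]
    names(sampleStudy) <- colnames(te)
    m <- exprsValues(te)
    gm <- rowMeans(m, na.rm = TRUE)
    for (s in unique(sampleStudy)) {
        shift <- stats::rnorm(nrow(m), 0, spec@batchShiftSd)
        scale <- 2^stats::rnorm(nrow(m), 0, spec@batchScaleSd)
        idx <- which(sampleStudy == s)
        m[, idx] <- gm + (m[, idx, drop = FALSE] - gm) * scale + shift
    }
    SummarizedExperiment::assay(te, "exprs") <- m
    SummarizedExperiment::colData(te)$study_id <- unname(sampleStudy)
    if (!is.null(truth)) truth@batchBySample <- sampleStudy
    list(experiment = te, batch = sampleStudy, truth = truth)
}
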