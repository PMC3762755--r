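#' Read an expression matrix with sample annotations
#'
#' Reads a probe x sample expression table plus tissue/patient/study
#' annotations into a [TissueExperiment-class].  Two dialects are supported:
#' plain TSV (first column probe id, header row sample ids, \code{NA} for
#' missing, with a sidecar annotation TSV carrying \code{sample_id},
#' \code{tissue_code}, \code{patient_id}, \code{study_id}), and the GEO
#' series-matrix format, where sample metadata come from the \code{!Sample_}
#' header rows and the expression block sits between the
#' \code{!series_matrix_table_begin}/\code{end} markers.
#'
#' For the GEO dialect the tissue code is extracted from the
#' \code{!Sample_title} row (or another \code{!Sample_} row named by
#' \code{tissueField}) as the first match of a two-letter code from the
#' accepted alphabet; the patient id defaults to the sample id unless
#' \code{patientRegex} captures one from the same field.
#'
#' @param path path to the matrix (or series-matrix) file.
#' @param annot path to the annotation TSV (tsv dialect only).
#' @param dialect \code{"tsv"} or \code{"geo_series_matrix"}.
#' @param scale scale of the stored values, \code{"log2"} (default) or
#'   \code{"linear"}.
#' @param extraCodes extra tissue codes beyond the built-in alphabet.
#' @param tissueField,patientRegex GEO dialect: which \code{!Sample_} row to
#'   scan for tissue codes, and an optional regex whose first capture group
#'   is the patient id.
#' @param studyId GEO dialect: study label to assign (default the file name).
#' @return a validated [TissueExperiment-class]; missing values preserved.
#' @examples
#' mp <- tempfile(fileext = ".tsv"); ap <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' te <- TissueExperiment(m, c("CT", "HM", "CN"), c("P1", "P1", "P2"))
#' writeExpressionMatrix(te, mp, ap)
#' te2 <- readExpressionMatrix(mp, ap)
#' @export
readExpressionMatrix <- function(path, annot = NULL,
                                 dialect = c("tsv", "geo_series_matrix"),
                                 scale = c("log2", "linear"),
                                 extraCodes = character(),
                                 tissueField = "title",
                                 patientRegex = NULL,
                                 studyId = NULL) {
    dialect <- match.arg(dialect)
    scale <- match.arg(scale)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "tsv") {
        if (is.null(annot)) stop("the tsv dialect needs an annotation file")
        if (!file.exists(annot)) stop("file not found: ", annot)
        tab <- utils::read.delim(path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        probes <- as.character(tab[[1L]])
        if (anyDuplicated(probes))
            stop("duplicated probe id: '", probes[anyDuplicated(probes)], "'")
        values <- as.matrix(tab[, -1L, drop = FALSE])
        storage.mode(values) <- "double"
        rownames(values) <- probes
        ann <- utils::read.delim(annot, stringsAsFactors = FALSE,
                                 colClasses = "character")
        need <- c("sample_id", "tissue_code", "patient_id", "study_id")
        if (!all(need %in% colnames(ann)))
            stop("annotation file needs columns: ",
                 paste(need, collapse = ", "))
        if (anyDuplicated(ann$sample_id))
            stop("duplicated sample id: '",
                 ann$sample_id[anyDuplicated(ann$sample_id)], "'")
        miss <- setdiff(colnames(values), ann$sample_id)
        if (length(miss))
            stop("samples without annotation: ", paste(miss, collapse = ", "))
        ann <- ann[match(colnames(values), ann$sample_id), ]
        TissueExperiment(values, ann$tissue_code, ann$patient_id,
                         ann$study_id, scale = scale,
                         extraCodes = extraCodes)
    } else {
        .readSeriesMatrix(path, scale, extraCodes, tissueField,
                          patientRegex,
                          if (is.null(studyId)) basename(path) else studyId)
    }
}

.readSeriesMatrix <- function(path, scale, extraCodes, tissueField,
                              patientRegex, studyId) {
    lines <- readLines(path)
    unq <- function(x) gsub('^"|"$', "", x)
    sampleRows <- grep("^!Sample_", lines, value = TRUE)
    meta <- list()
    for (row in sampleRows) {
        parts <- strsplit(row, "\t", fixed = TRUE)[[1L]]
        key <- sub("^!Sample_", "", parts[1L])
        if (!key %in% names(meta))        # first occurrence wins
            meta[[key]] <- unq(parts[-1L])
    }
    if (!"geo_accession" %in% names(meta))
        stop("no !Sample_geo_accession row found")
    ids <- meta$geo_accession
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
        stop("no expression block between series_matrix_table markers")
    block <- lines[(beg + 1L):(end - 1L)]
    tab <- utils::read.delim(text = block, check.names = FALSE,
                             stringsAsFactors = FALSE)
    probes <- unq(as.character(tab[[1L]]))
    if (anyDuplicated(probes))
        stop("duplicated probe id: '", probes[anyDuplicated(probes)], "'")
    values <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- probes
    colnames(values) <- unq(colnames(values))
    if (!setequal(colnames(values), ids))
        stop("expression columns do not match !Sample_geo_accession ids")
    field <- meta[[tissueField]]
    if (is.null(field))
        stop("no !Sample_", tissueField, " row to derive tissue codes from")
    field <- field[match(colnames(values), ids)]
    codes <- validTissueCodes(extraCodes)
    pat <- paste0("\\b(", paste(codes, collapse = "|"), ")\\b")
    hit <- regmatches(field, regexpr(pat, field))
    if (length(hit) != length(field))
        stop("sample '",
             colnames(values)[!seq_along(field) %in%
                              which(regexpr(pat, field) > 0)][1L],
             "' has no recognizable tissue code in !Sample_", tissueField)
    patient <- colnames(values)
    if (!is.null(patientRegex)) {
        m <- regexec(patientRegex, field)
        cap <- vapply(regmatches(field, m), function(g)
            if (length(g) >= 2L) g[2L] else NA_character_, character(1L))
        patient <- ifelse(is.na(cap), patient, cap)
    }
    TissueExperiment(values, hit, patient, studyId, scale = scale,
                     extraCodes = extraCodes)
}

#' Write a TissueExperiment to matrix + annotation TSV
#'
#' Inverse of [readExpressionMatrix()] (tsv dialect): UTF-8, "." decimal,
#' \code{NA} for missing.
#'
#' @param te a [TissueExperiment-class].
#' @param matrixPath,annotPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionMatrix <- function(te, matrixPath, annotPath) {
    stopifnot(methods::is(te, "TissueExperiment"))
    m <- exprsValues(te)
    out <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    ann <- data.frame(sample_id = colnames(m),
                      tissue_code = as.character(tissueCode(te)),
                      patient_id = as.character(patientId(te)),
                      study_id = as.character(studyId(te)),
                      stringsAsFactors = FALSE)
    utils::write.table(ann, annotPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(c(matrixPath, annotPath))
}

#' Detection calls from an intensity threshold
#'
#' When platform present/absent calls are unavailable, a probe is called
#' present in a sample when its value exceeds a linear-scale threshold.  The
#' default threshold is the study-wide 25th percentile of all (non-missing)
#' values.
#'
#' @param te a [TissueExperiment-class].
#' @param threshold call threshold on the matrix's own scale; default the
#'   25th percentile of all values.
#' @return logical probe x sample matrix (missing values are not present).
#' @export
presenceCalls <- function(te, threshold = NULL) {
    m <- exprsValues(te)
    if (is.null(threshold))
        threshold <- stats::quantile(m, 0.25, na.rm = TRUE, names = FALSE)
    pres <- !is.na(m) & m > threshold
    pres
}

#' Filter probes by presence fraction
#'
#' Retains exactly the probes called present in at least \code{minFraction}
#' of the samples (the boundary is inclusive: 13 of 26 samples passes at
#' 0.5).  The sample set is unchanged.
#'
#' @param te a [TissueExperiment-class].
#' @param present optional logical probe x sample matrix of detection calls,
#'   congruent with \code{te}; when omitted, [presenceCalls()] generates one.
#' @param minFraction required presence fraction in (0, 1].
#' @param threshold passed to [presenceCalls()] when \code{present} is NULL.
#' @return the filtered [TissueExperiment-class].
#' @export
presenceFilter <- function(te, present = NULL, minFraction = 0.5,
                           threshold = NULL) {
    stopifnot(methods::is(te, "TissueExperiment"))
    if (!is.numeric(minFraction) || length(minFraction) != 1L ||
        is.na(minFraction) || minFraction <= 0 || minFraction > 1)
        stop("minFraction must be a single value in (0, 1]")
    if (is.null(present)) present <- presenceCalls(te, threshold)
    if (!is.logical(present) || !identical(dim(present), dim(exprsValues(te))))
        stop("'present' must be a logical matrix congruent with the data")
    frac <- rowMeans(present)
    te[frac >= minFraction, ]
}

#' Log2-transform a linear-scale matrix
#'
#' Replaces every value v by log2(max(v, floor)); the floor keeps ratios
#' finite for near-zero intensities.  The scale flag is flipped to
#' \code{"log2"}, and transforming an already-log matrix is an error.
#'
#' @param te a linear-scale [TissueExperiment-class] with non-negative values.
#' @param floor positive linear-scale floor (default 1, i.e. log2 value 0).
#' @return the transformed [TissueExperiment-class].
#' @export
log2Transform <- function(te, floor = 1) {
    stopifnot(methods::is(te, "TissueExperiment"))
    if (exprsScale(te) == "log2")
        stop("matrix is already on the log2 scale")
    if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
        stop("floor must be a single positive value")
    m <- exprsValues(te)
    if (any(m < 0, na.rm = TRUE))
        stop("negative values cannot be log2-transformed")
    m2 <- log2(pmax(m, floor))
    SummarizedExperiment::assay(te, "exprs") <- m2
    S4Vectors::metadata(te)$scale <- "log2"
    te
}

#' Build a patient-matched paired design
#'
#' One pair per patient possessing exactly one sample of each role; patients
#' lacking either role are omitted; patients with two samples of the same
#' role abort (ambiguous pairing).  Pairs are ordered by patient id, so the
#' result is invariant to row/column permutations of the input.
#'
#' @param te a [TissueExperiment-class] annotated with patient ids.
#' @param roleA,roleB tissue codes of the two sides (e.g. \code{"CT"},
#'   \code{"HM"}).
#' @return a [PairedDesign-class].
#' @examples
#' m <- matrix(0, 1, 4, dimnames = list("p", paste0("s", 1:4)))
#' te <- TissueExperiment(m, c("CT", "HM", "CT", "HM"),
#'                        c("P1", "P1", "P2", "P2"))
#' nPairs(buildPairs(te, "CT", "HM"))
#' @export
buildPairs <- function(te, roleA, roleB) {
    stopifnot(methods::is(te, "TissueExperiment"))
    tc <- as.character(tissueCode(te))
    pid <- as.character(patientId(te))
    sel <- tc %in% c(roleA, roleB)
    pid <- pid[sel]; tc <- tc[sel]; ids <- colnames(te)[sel]
    pairs <- lapply(sort(unique(pid)), function(p) {
        a <- ids[pid == p & tc == roleA]
        b <- ids[pid == p & tc == roleB]
        if (length(a) > 1L || length(b) > 1L)
            stop("patient '", p, "' has multiple samples with role ",
                 if (length(a) > 1L) roleA else roleB,
                 ": ambiguous pairing")
        if (length(a) == 1L && length(b) == 1L)
            data.frame(patient_id = p, sample_A = a, sample_B = b,
                       stringsAsFactors = FALSE)
        else NULL
    })
    pairs <- do.call(rbind, pairs)
    if (is.null(pairs))
        pairs <- data.frame(patient_id = character(),
                            sample_A = character(),
                            sample_B = character(),
                            stringsAsFactors = FALSE)
    methods::new("PairedDesign", pairs = pairs,
                 roleA = as.character(roleA), roleB = as.character(roleB))
}
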