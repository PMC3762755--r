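#' Parameters of the contamination filter
#'
#' @param lambdaMax maximal contamination fraction considered, in [0, 1);
#'   the default 0.5 is the pathology bound (metastases contain at least
#'   50 percent cancer cells).
#' @param minAbsY minimal |log2(pCT/pHM)| for a dot to count (default 1,
#'   i.e. a two-fold CT/HM difference).
#' @param minDiagDist minimal |y - x| = |log2(pHN/pHM)| (default 1: the
#'   metastasis must differ two-fold from the surrounding normal liver).
#' @param minVotes pairs that must agree on a quadrant for a probe to be
#'   kept; defaults to ceiling(8/13 * nPairs), preserving the discovery
#'   study's 8-of-13 fraction.
#' @param nPairs number of CT/HM pairs in the cohort (context for the
#'   default \code{minVotes}).
#' @return validated list of class \code{"FilterParams"}.
#' @export
filterParams <- function(lambdaMax = 0.5, minAbsY = 1, minDiagDist = 1,
                         minVotes = NULL, nPairs = 13) {
    if (!is.numeric(lambdaMax) || lambdaMax < 0 || lambdaMax >= 1)
        stop("lambdaMax must be in [0, 1)")
    if (minAbsY < 0 || minDiagDist < 0)
        stop("thresholds must be >= 0")
    if (is.null(minVotes)) minVotes <- ceiling(8 / 13 * nPairs)
    if (minVotes > nPairs)
        stop("minVotes cannot exceed nPairs")
    structure(list(lambdaMax = lambdaMax, minAbsY = minAbsY,
                   minDiagDist = minDiagDist,
                   minVotes = as.integer(minVotes),
                   nPairs = as.integer(nPairs)),
              class = "FilterParams")
}

#' Contamination boundary in log-ratio coordinates
#'
#' For a probe whose true metastasis expression equals the tumor's
#' (pHM = pCT), mixing a fraction \code{lam} of normal liver into the
#' metastasis sample moves the observed point to
#' y = f_lam(x) = x - log2((1 - lam) 2^x + lam), where
#' x = log2(pCT/pHN).  f_0 is identically zero (no contamination keeps the
#' point on the x-axis); f_0.5 rises from the shifted diagonal y = x + 1 at
#' very negative x to the horizontal y = 1 at very positive x.  Any dot
#' between the x-axis and f_lambdaMax is explainable by contamination alone.
#'
#' @param x log2(pCT/pHN), any real (vectorized).
#' @param lam contamination fraction in [0, 1).
#' @return f_lam(x), same length as x.
#' @examples
#' contaminationBoundary(3, 0.5)    # ~0.830
#' contaminationBoundary(-3, 0.5)   # ~-2.170
#' @export
contaminationBoundary <- function(x, lam) {
    if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
        lam < 0 || lam >= 1)
        stop("lam must be a single value in [0, 1)")
    if (lam == 0) return(rep(0, length(x)))
    # two algebraically identical forms, each stable on its half-line
    y <- ifelse(x >= 0,
                -log2((1 - lam) + lam * 2^(-x)),
                x - log2((1 - lam) * 2^x + lam))
    y
}

#' Per-probe reference CT/HN ratio envelope
#'
#' The minimum and maximum of log2(pCT/pHN) across the reference
#' tumor/normal-liver pairs bracket the unknown liver baseline of each
#' probe.  Probes with no complete reference pair get NA bounds and are
#' treated as unfilterable downstream.
#'
#' @param refTe log2-scale [TissueExperiment-class] of the reference study.
#' @param refDesign the CT/HN [PairedDesign-class] (A = CT, B = HN).
#' @return a [ReferenceEnvelope-class].
#' @export
referenceEnvelope <- function(refTe, refDesign) {
    if (nPairs(refDesign) < 1L)
        stop("at least one reference pair is required")
    d <- pairedDifferences(refTe, refDesign)   # HN - CT
    x <- -d                                     # log2(CT/HN)
    xMin <- suppressWarnings(apply(x, 1L, min, na.rm = TRUE))
    xMax <- suppressWarnings(apply(x, 1L, max, na.rm = TRUE))
    xMin[!is.finite(xMin)] <- NA_real_
    xMax[!is.finite(xMax)] <- NA_real_
    methods::new("ReferenceEnvelope", probe = rownames(x),
                 xMin = unname(xMin), xMax = unname(xMax))
}

#' Log-ratio dots of the tumor/metastasis pairs
#'
#' One dot per probe and pair: y from the pair's own samples
#' (log2(pCT/pHM)), x from the chosen envelope bound, constant per probe —
#' the pairs of a probe line up on a vertical line.
#'
#' @param te log2-scale [TissueExperiment-class] of the paired cohort.
#' @param design the CT/HM [PairedDesign-class] (A = CT, B = HM).
#' @param envelope a [ReferenceEnvelope-class] covering the probes.
#' @param which \code{"min"} or \code{"max"} envelope bound.
#' @return data.frame with columns probe, pair, x, y.
#' @export
ratioPoints <- function(te, design, envelope, which = c("min", "max")) {
    which <- match.arg(which)
    d <- pairedDifferences(te, design)          # HM - CT
    y <- -d                                      # log2(CT/HM)
    bound <- if (which == "min") envelope@xMin else envelope@xMax
    idx <- match(rownames(y), envelope@probe)
    x <- bound[idx]
    data.frame(probe = rep(rownames(y), ncol(y)),
               pair = rep(colnames(y), each = nrow(y)),
               x = rep(x, ncol(y)),
               y = as.vector(y),
               stringsAsFactors = FALSE)
}

#' Classify log-ratio dots
#'
#' Applies, in order: the fold-change filter (|y| >= minAbsY), the diagonal
#' filter (|y - x| >= minDiagDist), and the contamination band (y between
#' the x-axis and f_lambdaMax(x), boundary included: a dot exactly
#' explainable by some lambda <= lambdaMax is removed).  Survivors are
#' assigned their quadrant: b (y < 0, y < x: up in HM versus both CT and
#' HN), d (y > 0, y > x: down in HM versus both), or the in-principle
#' quadrants a (y < 0, y > x) and c (y > 0, y < x), which are recorded but
#' never earn votes.  Dots on a quadrant boundary (y = 0 or y = x) are
#' removed — ties break toward removal.
#'
#' @param x,y dot coordinates (equal-length vectors); NA yields verdict
#'   \code{"unfilterable"}.
#' @param params a [filterParams()] list.
#' @return character vector of verdicts: \code{kept_a/b/c/d},
#'   \code{removed_low_fc}, \code{removed_near_diagonal},
#'   \code{removed_contamination} or \code{unfilterable}.
#' @examples
#' p <- filterParams()
#' classifyPoints(c(-4, 0, -3, 3), c(-2.5, 0.5, 2, 1.2), p)
#' @export
classifyPoints <- function(x, y, params = filterParams()) {
    stopifnot(inherits(params, "FilterParams"), length(x) == length(y))
    out <- rep(NA_character_, length(x))
    na <- is.na(x) | is.na(y)
    out[na] <- "unfilterable"
    f <- contaminationBoundary(ifelse(na, 0, x), params$lambdaMax)
    lowFc <- !na & (abs(y) < params$minAbsY | y == 0)
    out[lowFc] <- "removed_low_fc"
    todo <- is.na(out)
    nearDiag <- todo & (abs(y - x) < params$minDiagDist | y == x)
    out[nearDiag] <- "removed_near_diagonal"
    todo <- is.na(out)
    inBand <- todo & f != 0 & sign(y) == sign(f) & abs(y) <= abs(f)
    out[inBand] <- "removed_contamination"
    todo <- is.na(out)
    quad <- ifelse(y < 0, ifelse(y < x, "b", "a"),
                   ifelse(y > x, "d", "c"))
    out[todo] <- paste0("kept_", quad[todo])
    out
}

#' Vote over pairs and envelopes
#'
#' A pair earns a vote for a quadrant only when its dot survives with the
#' SAME quadrant under both the minimum and the maximum reference envelope.
#' A probe is kept when one quadrant among b and d accumulates at least
#' \code{minVotes} votes; its direction follows the quadrant (b: up in HM,
#' d: down in HM).
#'
#' @param verdMin,verdMax probe x pair verdict matrices from
#'   [classifyPoints()] under the two envelope bounds.
#' @param params a [filterParams()] list.
#' @return data.frame (one row per probe): vote counts per quadrant, number
#'   of usable pairs, \code{kept}, \code{direction}, \code{reason}.
#' @export
voteFilter <- function(verdMin, verdMax, params = filterParams()) {
    stopifnot(identical(dim(verdMin), dim(verdMax)))
    agree <- function(q) rowSums(verdMin == paste0("kept_", q) &
                                 verdMax == paste0("kept_", q), na.rm = TRUE)
    votes <- vapply(c("a", "b", "c", "d"), agree,
                    numeric(nrow(verdMin)))
    if (nrow(verdMin) == 1L) votes <- matrix(votes, 1L,
                                             dimnames = list(NULL,
                                                             c("a", "b",
                                                               "c", "d")))
    usable <- rowSums(verdMin != "unfilterable" &
                      verdMax != "unfilterable", na.rm = TRUE)
    if (params$minVotes > ncol(verdMin))
        warning("minVotes exceeds the number of available pairs; ",
                "no probe can be kept")
    vb <- votes[, "b"]; vd <- votes[, "d"]
    keptB <- vb >= params$minVotes & vd < params$minVotes
    keptD <- vd >= params$minVotes & vb < params$minVotes
    kept <- keptB | keptD
    direction <- ifelse(keptB, "up_in_HM", "down_in_HM")
    direction[!kept] <- NA_character_
    reason <- ifelse(kept, "kept",
              ifelse(usable == 0, "unfilterable", "insufficient_votes"))
    data.frame(probe = rownames(verdMin),
               votes_a = votes[, "a"], votes_b = vb,
               votes_c = votes[, "c"], votes_d = vd,
               n_pairs_usable = usable,
               kept = kept, direction = direction, reason = reason,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Contamination-aware signature filter
#'
#' Orchestrates the whole geometric filter for a candidate probe list:
#' reference envelope, log-ratio dots under both envelope bounds, dot
#' classification, and the both-envelope quadrant vote.  Probes absent from
#' the reference matrix (or with no complete reference pair) cannot be
#' screened against liver contamination and are excluded with audit code
#' \code{"unfilterable"} rather than passed through.
#'
#' @param candidates character vector of candidate probe ids (typically
#'   [selectProbes()] output), all present in \code{te}.
#' @param te,design the paired cohort matrix and its CT/HM design.
#' @param refTe,refDesign the reference matrix and its CT/HN design.
#' @param params a [filterParams()] list; \code{nPairs}/\code{minVotes}
#'   default to the design's size when not supplied.
#' @return a [SignatureFilterResult-class] with the kept probes as a
#'   probe-space [GeneSignature-class] and a full per-probe audit trail.
#' @export
applyContaminationFilter <- function(candidates, te, design, refTe,
                                     refDesign, params = NULL) {
    if (is.null(params))
        params <- filterParams(nPairs = nPairs(design))
    stopifnot(inherits(params, "FilterParams"))
    candidates <- as.character(candidates)
    if (!length(candidates)) {
        sig <- GeneSignature(character(), character(),
                             featureSpace = "probe")
        return(methods::new("SignatureFilterResult", signature = sig,
                            audit = data.frame(), verdicts = list(),
                            params = unclass(params)))
    }
    miss <- setdiff(candidates, rownames(te))
    if (length(miss))
        stop("candidates absent from the cohort matrix: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    sub <- te[candidates, ]
    env <- referenceEnvelope(refTe, refDesign)
    verdict <- function(which) {
        pts <- ratioPoints(sub, design, env, which)
        matrix(classifyPoints(pts$x, pts$y, params),
               nrow = length(candidates),
               dimnames = list(candidates, unique(pts$pair)))
    }
    vMin <- verdict("min")
    vMax <- verdict("max")
    audit <- voteFilter(vMin, vMax, params)
    keptTab <- audit[audit$kept, , drop = FALSE]
    ord <- order(-pmax(keptTab$votes_b, keptTab$votes_d))
    keptTab <- keptTab[ord, , drop = FALSE]
    sig <- GeneSignature(keptTab$probe, keptTab$direction,
                         featureSpace = "probe")
    methods::new("SignatureFilterResult", signature = sig, audit = audit,
                 verdicts = list(min = vMin, max = vMax),
                 params = unclass(params))
}

#' Diagnostic plot of the log-ratio plane
#'
#' Draws the dots of selected probes in the (x, y) = (log2 pCT/pHN,
#' log2 pCT/pHM) plane together with the x-axis, the diagonal, the
#' contamination boundary f_lambdaMax and the excluded bands.
#'
#' @param te,design,refTe,refDesign as in [applyContaminationFilter()].
#' @param probes probe ids to draw (one color each).
#' @param params a [filterParams()] list.
#' @param which envelope bound for the x coordinate.
#' @return invisibly, the plotted data.frame of dots.
#' @export
plotRatioPlane <- function(te, design, refTe, refDesign, probes,
                           params = filterParams(), which = "min") {
    env <- referenceEnvelope(refTe, refDesign)
    pts <- ratioPoints(te[probes, ], design, env, which)
    xl <- range(pts$x, -5, 5, na.rm = TRUE)
    yl <- range(pts$y, -5, 5, na.rm = TRUE)
    plot(NA, xlim = xl, ylim = yl, xlab = "log2(pCT/pHN)",
         ylab = "log2(pCT/pHM)", main = "contamination filter geometry")
    xs <- seq(xl[1], xl[2], length.out = 400L)
    graphics::polygon(c(xs, rev(xs)),
                      c(pmin(contaminationBoundary(xs, params$lambdaMax), 0),
                        rev(pmax(contaminationBoundary(xs,
                                                       params$lambdaMax),
                                 0))),
                      col = grDevices::adjustcolor("red", 0.15),
                      border = NA)
    graphics::abline(h = 0, col = "grey30")
    graphics::abline(a = 0, b = 1, col = "grey30", lty = 2)
    graphics::abline(h = c(-1, 1) * params$minAbsY, col = "grey70",
                     lty = 3)
    graphics::lines(xs, contaminationBoundary(xs, params$lambdaMax),
                    col = "red", lty = 2)
    cols <- grDevices::rainbow(length(probes))
    for (i in seq_along(probes)) {
        sel <- pts$probe == probes[i]
        graphics::points(pts$x[sel], pts$y[sel], col = cols[i], pch = 19,
                         cex = 0.7)
    }
    invisible(pts)
}
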