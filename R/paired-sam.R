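#' Parameters for the paired SAM analysis
#'
#' @param fdrThreshold FDR call threshold in (0, 1); the discovery analysis
#'   uses 0.001.
#' @param nPermutations sign-flip permutations; when 2^n_pairs <=
#'   \code{nPermutations} the full set of 2^n flips is enumerated instead of
#'   sampled, making the result exact and seed-independent.
#' @param s0 the fudge factor added to the standard error, or \code{"auto"}
#'   to select it by the SAM coefficient-of-variation criterion
#'   ([estimateS0()]).
#' @param seed seed for the sampling branch.
#' @return a validated list of class \code{"SamParams"}.
#' @export
samParams <- function(fdrThreshold = 0.001, nPermutations = 1000,
                      s0 = "auto", seed = 1) {
    if (!is.numeric(fdrThreshold) || fdrThreshold <= 0 || fdrThreshold >= 1)
        stop("fdrThreshold must be in (0, 1)")
    if (!is.numeric(nPermutations) || nPermutations < 1)
        stop("nPermutations must be >= 1")
    if (!identical(s0, "auto") && (!is.numeric(s0) || s0 < 0))
        stop("s0 must be \"auto\" or a non-negative number")
    structure(list(fdrThreshold = fdrThreshold,
                   nPermutations = as.integer(nPermutations),
                   s0 = s0, seed = as.integer(seed)),
              class = "SamParams")
}

#' Per-pair paired differences
#'
#' Entry (i, p) is the log2 value of pair p's B-side sample minus its A-side
#' sample (HM minus CT for the canonical design); missing values propagate.
#'
#' @param te a log2-scale [TissueExperiment-class].
#' @param design a [PairedDesign-class] whose samples all exist in \code{te}.
#' @return numeric probe x pair matrix, columns named by patient id.
#' @export
pairedDifferences <- function(te, design) {
    stopifnot(methods::is(te, "TissueExperiment"),
              methods::is(design, "PairedDesign"))
    p <- pairTable(design)
    miss <- setdiff(c(p$sample_A, p$sample_B), colnames(te))
    if (length(miss))
        stop("design references samples absent from the matrix: ",
             paste(miss, collapse = ", "))
    m <- exprsValues(te)
    d <- m[, p$sample_B, drop = FALSE] - m[, p$sample_A, drop = FALSE]
    colnames(d) <- p$patient_id
    d
}

.rowStats <- function(diffs) {
    ok <- !is.na(diffs)
    n <- rowSums(ok)
    d0 <- diffs; d0[!ok] <- 0
    m <- rowSums(d0) / n
    ss <- rowSums(d0^2)
    v <- pmax(ss - n * m^2, 0) / (n - 1)
    se <- sqrt(v / n)
    se[n < 2] <- NA_real_
    m[n < 1] <- NA_real_
    list(mean = m, se = se, n = n, ss = ss)
}

#' SAM statistic on paired differences
#'
#' d_i = mean_i / (se_i + s0), the one-sample moderated t of the SAM method
#' applied to the per-pair differences.  Probes with fewer than two complete
#' pairs get \code{NA}.
#'
#' @param diffs probe x pair difference matrix ([pairedDifferences()]).
#' @param s0 non-negative fudge factor.
#' @return named numeric vector of d statistics.
#' @export
samStatistic <- function(diffs, s0) {
    if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 < 0)
        stop("s0 must be a single non-negative number")
    st <- .rowStats(as.matrix(diffs))
    d <- st$mean / (st$se + s0)
    names(d) <- rownames(diffs)
    d
}

#' Select the SAM fudge factor
#'
#' The standard SAM selection: candidate s0 values are percentiles of the
#' per-probe standard errors; for each candidate, probes are binned into
#' percentile groups of se and the median absolute deviation of d within
#' each bin computed; the candidate minimizing the coefficient of variation
#' of these spreads is chosen.  Deterministic given the input.
#'
#' @param diffs probe x pair difference matrix.
#' @return the chosen s0 (>= 0); 0 with a warning when every se is zero.
#' @export
estimateS0 <- function(diffs) {
    st <- .rowStats(as.matrix(diffs))
    keep <- !is.na(st$se)
    m <- st$mean[keep]; se <- st$se[keep]
    if (!length(se)) stop("no probe has >= 2 complete pairs")
    if (all(se == 0)) {
        warning("all standard errors are zero; returning s0 = 0")
        return(0)
    }
    alphas <- seq(0, 1, by = 0.05)
    cand <- unique(stats::quantile(se, alphas, names = FALSE))
    br <- unique(stats::quantile(se, seq(0, 1, by = 0.01), names = FALSE))
    if (length(br) < 2L) br <- range(se) + c(-1e-12, 1e-12)
    bin <- cut(se, breaks = br, include.lowest = TRUE)
    cv <- vapply(cand, function(s0) {
        d <- m / (se + s0)
        v <- tapply(d, bin, stats::mad)
        v <- v[!is.na(v)]
        if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
    }, numeric(1L))
    cand[which.min(cv)]
}

# All 2^n sign vectors as an n x 2^n matrix of +-1.
.allSignFlips <- function(n) {
    stopifnot(n <= 25L)
    B <- 2L^n
    S <- matrix(1, n, B)
    for (j in seq_len(n))
        S[j, ] <- ifelse(bitwAnd(seq_len(B) - 1L, 2L^(j - 1L)) > 0L, -1, 1)
    S
}

#' Permutation FDR for the paired SAM statistic
#'
#' The null distribution comes from sign flips of the pair columns (flipping
#' a pair swaps its two tissues).  When 2^n_pairs does not exceed
#' \code{nPermutations} all flips are enumerated, making q-values exact and
#' seed-independent; otherwise flips are sampled.  The q-value of a probe at
#' cut |d| is the median, over flips, of the number of null statistics at or
#' beyond the cut, divided by the observed count at the cut, clamped to
#' [0, 1] and monotonized (running minimum from least to most significant)
#' so that threshold sets are nested.
#'
#' @param diffs probe x pair difference matrix.
#' @param params a [samParams()] list.
#' @return a [SamResult-class].
#' @examples
#' set.seed(1)
#' d <- matrix(rnorm(50 * 6), 50, 6,
#'             dimnames = list(sprintf("p%02d", 1:50), NULL))
#' res <- permutationFDR(d, samParams(nPermutations = 64))
#' res
#' @export
permutationFDR <- function(diffs, params = samParams()) {
    stopifnot(inherits(params, "SamParams"))
    diffs <- as.matrix(diffs)
    if (is.null(rownames(diffs)))
        rownames(diffs) <- sprintf("probe_%05d", seq_len(nrow(diffs)))
    n <- ncol(diffs)
    if (n < 2L) stop("at least 2 pairs are required")
    st <- .rowStats(diffs)
    usable <- st$n >= 2L
    D <- diffs[usable, , drop = FALSE]
    stU <- .rowStats(D)
    s0 <- if (identical(params$s0, "auto")) estimateS0(D) else params$s0
    dObs <- stU$mean / (stU$se + s0)
    G <- nrow(D)
    exhaustive <- 2^n <= params$nPermutations
    if (exhaustive) {
        S <- .allSignFlips(n)
    } else {
        set.seed(params$seed)
        S <- matrix(sample(c(-1, 1), n * params$nPermutations,
                           replace = TRUE), n, params$nPermutations)
    }
    B <- ncol(S)
    D0 <- D; D0[is.na(D0)] <- 0
    cs <- sort(abs(dObs))                       # ascending cuts
    counts <- matrix(0L, G, B)
    chunk <- max(1L, min(B, as.integer(2^26 / max(G, 1L))))
    done <- 0L
    while (done < B) {
        idx <- (done + 1L):min(done + chunk, B)
        M <- (D0 %*% S[, idx, drop = FALSE]) / stU$n
        V <- pmax(stU$ss - stU$n * M^2, 0) / (stU$n - 1)
        Dstar <- abs(M / (sqrt(V / stU$n) + s0))
        for (k in seq_along(idx)) {
            sn <- sort(Dstar[, k])
            counts[, idx[k]] <-
                G - findInterval(cs, sn, left.open = TRUE)
        }
        done <- idx[length(idx)]
    }
    medNull <- apply(counts, 1L, stats::median)
    rObs <- G - findInterval(cs, cs, left.open = TRUE)
    qraw <- pmin(medNull / rObs, 1)
    qmono <- cummin(qraw)                       # least -> most significant
    ord <- order(abs(dObs))                     # matches cs ordering
    q <- numeric(G); q[ord] <- qmono
    tab <- data.frame(probe = rownames(diffs),
                      mean_diff = st$mean, se = st$se,
                      d = NA_real_, q = NA_real_, n_pairs = st$n,
                      stringsAsFactors = FALSE, row.names = NULL)
    tab$d[usable] <- dObs
    tab$q[usable] <- q
    nCalled <- sum(tab$q < params$fdrThreshold, na.rm = TRUE)
    res <- methods::new("SamResult", table = tab, s0 = s0,
                        nPermutations = B, exhaustive = exhaustive)
    attr(res@table, "n_called") <- nCalled
    res
}

#' Select probes below an FDR threshold
#'
#' @param res a [SamResult-class].
#' @param fdrThreshold q-value cut; probes with q strictly below it are
#'   returned, ordered by |d| descending.
#' @return character vector of probe ids.
#' @export
selectProbes <- function(res, fdrThreshold = 0.001) {
    stopifnot(methods::is(res, "SamResult"))
    tab <- res@table
    sel <- !is.na(tab$q) & tab$q < fdrThreshold
    tab <- tab[sel, , drop = FALSE]
    tab$probe[order(-abs(tab$d))]
}
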