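# Small builders and independent oracles shared across the suite.

makeTE <- function(values, tissue, patient, study = "S1",
                   scale = "log2") {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
    TissueExperiment(values, tissue, patient, study, scale = scale)
}

# Naive O(n^3) agglomerative Ward via the Lance-Williams recurrence,
# independent of stats::hclust: scans all active pairs each step.
naiveWard <- function(D) {
    n <- nrow(D)
    d <- D
    sz <- rep(1, n)
    id <- -(seq_len(n))
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (s in seq_len(n - 1L)) {
        best <- c(Inf, 0L, 0L)
        na <- length(id)
        for (i in seq_len(na - 1L))
            for (j in (i + 1L):na)
                if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
        i <- best[2]; j <- best[3]
        merge[s, ] <- sort(c(id[i], id[j]))
        height[s] <- best[1]
        ni <- sz[i]; nj <- sz[j]
        keep <- setdiff(seq_len(na), c(i, j))
        newd <- vapply(keep, function(k)
            ((ni + sz[k]) * d[i, k] + (nj + sz[k]) * d[j, k] -
             sz[k] * d[i, j]) / (ni + nj + sz[k]), numeric(1L))
        d2 <- matrix(0, length(keep) + 1L, length(keep) + 1L)
        d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
        d2[length(keep) + 1L, seq_along(keep)] <- newd
        d2[seq_along(keep), length(keep) + 1L] <- newd
        d <- d2
        sz <- c(sz[keep], ni + nj)
        id <- c(id[keep], s)
    }
    list(merge = merge, height = height)
}

sameMergeSequence <- function(hc, oracle, tol = 1e-8) {
    m1 <- t(apply(hc$merge, 1L, sort))
    all(m1 == oracle$merge) &&
        max(abs(hc$height - oracle$height)) < tol
}
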