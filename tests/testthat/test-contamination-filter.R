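test_that("the contamination boundary has the right shape", {
    xs <- seq(-20, 20, by = 0.25)
    expect_true(all(contaminationBoundary(xs, 0) == 0))
    # closed-form spot values
    expect_equal(contaminationBoundary(3, 0.5), 3 - log2(4.5),
                 tolerance = 1e-12)
    expect_equal(contaminationBoundary(-3, 0.5), -3 - log2(0.5 / 8 + 0.5),
                 tolerance = 1e-12)
    # asymptotes: y -> 1 at x -> +Inf, y -> x + 1 at x -> -Inf (lambda 0.5)
    expect_equal(contaminationBoundary(20, 0.5), 1, tolerance = 1e-3)
    expect_equal(contaminationBoundary(-20, 0.5), -19, tolerance = 1e-3)
    expect_equal(contaminationBoundary(0, 0.5), 0, tolerance = 1e-12)
    # |f| non-decreasing in lambda, f non-decreasing in x
    for (x in c(-4, -1, 0.5, 2, 6)) {
        fs <- vapply(seq(0, 0.9, 0.05), function(l)
            abs(contaminationBoundary(x, l)), numeric(1))
        expect_true(all(diff(fs) >= -1e-12))
    }
    for (l in c(0.1, 0.3, 0.5, 0.8))
        expect_true(all(diff(contaminationBoundary(xs, l)) >= -1e-12))
    expect_error(contaminationBoundary(0, 1), "lam")
})

test_that("reference envelope equals brute-force row min/max", {
    set.seed(31)
    m <- matrix(rnorm(30 * 12, 8), 30, 12,
                dimnames = list(sprintf("p%02d", 1:30),
                                sprintf("s%02d", 1:12)))
    m[4, 1:2] <- NA
    te <- makeTE(m, rep(c("CT", "HN"), 6), rep(sprintf("R%d", 1:6), each = 2))
    des <- buildPairs(te, "CT", "HN")
    env <- referenceEnvelope(te, des)
    p <- pairTable(des)
    for (i in seq_len(nrow(m))) {
        xs <- m[i, p$sample_A] - m[i, p$sample_B]
        xs <- xs[!is.na(xs)]
        expect_equal(env@xMin[i], min(xs))
        expect_equal(env@xMax[i], max(xs))
    }
    expect_true(all(env@xMin <= env@xMax, na.rm = TRUE))
    # single reference pair: xMin = xMax
    te1 <- te[, 1:2]
    env1 <- referenceEnvelope(te1, buildPairs(te1, "CT", "HN"))
    expect_identical(env1@xMin, env1@xMax)
    # probe missing in all pairs is NA (unfilterable)
    m2 <- m; m2[9, ] <- NA
    te2 <- makeTE(m2, rep(c("CT", "HN"), 6),
                  rep(sprintf("R%d", 1:6), each = 2))
    env2 <- referenceEnvelope(te2, buildPairs(te2, "CT", "HN"))
    expect_true(is.na(env2@xMin[9]) && is.na(env2@xMax[9]))
})

test_that("ratio points put 13 dots per probe on a vertical line", {
    sp <- cohortSpec(nProbes = 30, nPlantedDE = 6, nLiverDecoys = 6,
                     nTumorGenes = 0, noiseSd = 0, lambdaRange = c(0, 0),
                     plantedLog2fcRange = c(2, 2), seed = 32)
    co <- generateCohort(sp); ref <- generateReferencePairs(sp)
    des <- buildPairs(co$experiment, "CT", "HM")
    env <- referenceEnvelope(ref$experiment, ref$design)
    pts <- ratioPoints(co$experiment, des, env, "min")
    expect_identical(nrow(pts), 30L * 13L)
    expect_true(all(table(pts$probe) == 13L))
    # x constant per probe (the envelope bound)
    expect_true(all(tapply(pts$x, pts$probe, function(v)
        max(v) - min(v)) == 0))
    cls <- probeClass(co$truth)
    up <- names(cls)[cls == "planted_up"]
    nul <- names(cls)[cls == "null"]
    # planted +2, noise-free, lambda 0: y = -2 exactly; null probes y = 0
    expect_true(all(abs(pts$y[pts$probe %in% up] + 2) < 1e-12))
    expect_true(all(abs(pts$y[pts$probe %in% nul]) < 1e-12))
})

test_that("dot classification applies the hatched-region rules in order", {
    p <- filterParams()
    # inside the contamination band (y between 0 and f_0.5(-4) ~ -3.087)
    expect_identical(classifyPoints(-4, -2.5, p), "removed_contamination")
    # under the 2-fold CT/HM threshold
    expect_identical(classifyPoints(0, 0.5, p), "removed_low_fc")
    # clear survivor below the axis... above: y=2, x=-3 -> quadrant d
    expect_identical(classifyPoints(-3, 2, p), "kept_d")
    # quadrant c survivor is recorded (f_0.5(3) ~ 0.830 < 1.2 < 3 - 1)
    expect_identical(classifyPoints(3, 1.2, p), "kept_c")
    # near the diagonal
    expect_identical(classifyPoints(2.5, 1.8, p), "removed_near_diagonal")
    # boundary dots are removed (ties toward removal)
    p0 <- filterParams(minAbsY = 0, minDiagDist = 0)
    expect_identical(classifyPoints(3, 0, p0), "removed_low_fc")
    expect_identical(classifyPoints(2, 2, p0), "removed_near_diagonal")
    # the curve itself is removed (closed band); at lambdaMax 0.3 the curve
    # at x = -4 is far enough from both the axis and the diagonal that only
    # the band rule can catch it
    p3 <- filterParams(lambdaMax = 0.3)
    f <- contaminationBoundary(-4, 0.3)
    expect_identical(classifyPoints(-4, f, p3), "removed_contamination")
    # NA coordinates are unfilterable
    expect_identical(classifyPoints(NA, 1, p), "unfilterable")
})

test_that("no dot with y < 0 above the diagonal survives at defaults", {
    # quadrant-(a) vacuity on a coarse grid (the acceptance suite runs the
    # dense one): survival needs y <= f(x) - band <= x + 1 - eps while the
    # diagonal filter needs y >= x + 1 on that side
    p <- filterParams()
    xs <- seq(-10, 10, by = 0.1)
    for (chunk in split(xs, ceiling(seq_along(xs) / 50))) {
        X <- rep(chunk, each = length(xs))
        Y <- rep(xs, length(chunk))
        v <- classifyPoints(X, Y, p)
        expect_identical(sum(v == "kept_a"), 0L)
    }
})

test_that("noise-free contaminated decoys are always removed", {
    sp <- cohortSpec(nProbes = 400, nPlantedDE = 0, nLiverDecoys = 400,
                     nTumorGenes = 0, noiseSd = 0,
                     decoyLiverLog2fcRange = c(1, 6), seed = 33)
    co <- generateCohort(sp); ref <- generateReferencePairs(sp)
    des <- buildPairs(co$experiment, "CT", "HM")
    fr <- applyContaminationFilter(rownames(co$experiment), co$experiment,
                                   des, ref$experiment, ref$design)
    expect_identical(length(signatureTable(fr)$feature_id), 0L)
    ad <- auditTable(fr)
    expect_true(all(ad$votes_a + ad$votes_b + ad$votes_c + ad$votes_d == 0))
})

test_that("voting needs the same quadrant under both envelopes", {
    p <- filterParams(nPairs = 13)      # minVotes 8
    mk <- function(v) matrix(v, 1, 13, dimnames = list("pr", NULL))
    # 13/13 kept_d under both -> kept, down_in_HM
    d <- voteFilter(mk(rep("kept_d", 13)), mk(rep("kept_d", 13)), p)
    expect_true(d$kept); expect_identical(d$direction, "down_in_HM")
    # 7 votes < 8 -> removed
    d7 <- voteFilter(mk(c(rep("kept_b", 7), rep("removed_low_fc", 6))),
                     mk(c(rep("kept_b", 7), rep("removed_low_fc", 6))), p)
    expect_false(d7$kept)
    expect_identical(d7$reason, "insufficient_votes")
    # disagreement between envelopes contributes no vote
    d8 <- voteFilter(mk(rep("kept_b", 13)),
                     mk(c(rep("kept_b", 7), rep("removed_contamination", 6))),
                     p)
    expect_identical(d8$votes_b, 7)
    expect_false(d8$kept)
    # quadrant switch between envelopes contributes no vote either
    d9 <- voteFilter(mk(rep("kept_b", 13)), mk(rep("kept_a", 13)), p)
    expect_identical(d9$votes_b + d9$votes_a, 0)
    # vote counting is invariant to pair order
    set.seed(34)
    vm <- mk(sample(c("kept_d", "kept_b", "removed_low_fc"), 13, TRUE))
    vx <- mk(sample(c("kept_d", "removed_low_fc"), 13, TRUE))
    perm <- sample(13)
    a1 <- voteFilter(vm, vx, p)
    a2 <- voteFilter(vm[, perm, drop = FALSE], vx[, perm, drop = FALSE], p)
    expect_identical(a1[, -1], a2[, -1])
})

test_that("the full filter recovers robust planted probes exactly and
          shrinks the kept set as lambdaMax grows", {
    sp <- cohortSpec(nProbes = 600, nPlantedDE = 150, nLiverDecoys = 300,
                     nTumorGenes = 0, noiseSd = 0,
                     plantedLog2fcRange = c(4, 6),
                     decoyLiverLog2fcRange = c(1, 6), seed = 35)
    co <- generateCohort(sp); ref <- generateReferencePairs(sp)
    des <- buildPairs(co$experiment, "CT", "HM")
    cls <- probeClass(co$truth)
    planted <- names(cls)[startsWith(cls, "planted")]
    decoys <- names(cls)[cls == "liver_decoy"]
    fr <- applyContaminationFilter(rownames(co$experiment), co$experiment,
                                   des, ref$experiment, ref$design)
    sig <- signatureTable(fr)
    expect_setequal(sig$feature_id, planted)
    expect_identical(sum(sig$feature_id %in% decoys), 0L)
    # directions match the planted truth
    expect_identical(unname(sig$direction[match(names(cls)[cls ==
        "planted_up"], sig$feature_id)]),
        rep("up_in_HM", sum(cls == "planted_up")))
    # filter is monotone in lambdaMax: smaller lambdaMax keeps more
    pLo <- filterParams(lambdaMax = 0.2, nPairs = 13)
    frLo <- applyContaminationFilter(rownames(co$experiment),
                                     co$experiment, des, ref$experiment,
                                     ref$design, pLo)
    expect_true(all(sig$feature_id %in%
                    signatureTable(frLo)$feature_id))
    # candidates that are all null probes give an empty signature
    nul <- names(cls)[cls == "null"]
    fr0 <- applyContaminationFilter(nul, co$experiment, des,
                                    ref$experiment, ref$design)
    expect_identical(length(signatureTable(fr0)$feature_id), 0L)
    # empty candidate list short-circuits
    frE <- applyContaminationFilter(character(), co$experiment, des,
                                    ref$experiment, ref$design)
    expect_identical(length(signatureTable(frE)$feature_id), 0L)
})

test_that("probes absent from the reference are unfilterable, not passed", {
    sp <- cohortSpec(nProbes = 50, nPlantedDE = 10, nLiverDecoys = 0,
                     nTumorGenes = 0, noiseSd = 0,
                     plantedLog2fcRange = c(4, 4), seed = 36)
    co <- generateCohort(sp); ref <- generateReferencePairs(sp)
    des <- buildPairs(co$experiment, "CT", "HM")
    refNA <- ref$experiment
    SummarizedExperiment::assay(refNA, "exprs")[1:3, ] <- NA
    fr <- applyContaminationFilter(rownames(co$experiment), co$experiment,
                                   des, refNA, ref$design)
    ad <- auditTable(fr)
    blocked <- rownames(co$experiment)[1:3]
    expect_true(all(ad$reason[ad$probe %in% blocked] == "unfilterable"))
    expect_false(any(signatureTable(fr)$feature_id %in% blocked))
})
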