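test_that("matrix/annotation TSV round-trips exactly", {
    set.seed(1)
    m <- matrix(rnorm(30 * 8, 8, 2), 30, 8,
                dimnames = list(sprintf("probe%02d", 1:30),
                                sprintf("s%02d", 1:8)))
    m[3, 5] <- NA
    te <- makeTE(m, rep(c("CT", "HM"), 4), rep(sprintf("P%d", 1:4), each = 2))
    mp <- withr::local_tempfile(fileext = ".tsv")
    ap <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionMatrix(te, mp, ap)
    te2 <- readExpressionMatrix(mp, ap)
    expect_identical(dim(te2), dim(te))
    expect_lt(max(abs(exprsValues(te2) - exprsValues(te)), na.rm = TRUE),
              1e-12)
    expect_true(is.na(exprsValues(te2)[3, 5]))
    expect_identical(as.character(tissueCode(te2)),
                     as.character(tissueCode(te)))
    expect_identical(as.character(patientId(te2)),
                     as.character(patientId(te)))
})

test_that("load validation rejects duplicate ids and unknown tissue codes", {
    m <- matrix(0, 2, 2, dimnames = list(c("pA", "pA"), c("s1", "s2")))
    expect_error(TissueExperiment(m, c("CT", "HM"), c("P1", "P1")),
                 "pA")
    m2 <- matrix(0, 2, 2, dimnames = list(c("pA", "pB"), c("s1", "s2")))
    expect_error(TissueExperiment(m2, c("CT", "XX"), c("P1", "P1")),
                 "XX")
    # extensible alphabet admits extra codes
    expect_silent(TissueExperiment(m2, c("CT", "ZZ"), c("P1", "P1"),
                                   extraCodes = "ZZ"))
    # duplicate probe id in a file names the probe
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("probe_id\ts1\ts2", "pA\t1\t2", "pA\t3\t4"), mp)
    ap <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\ttissue_code\tpatient_id\tstudy_id",
                 "s1\tCT\tP1\tS1", "s2\tHM\tP1\tS1"), ap)
    expect_error(readExpressionMatrix(mp, ap), "pA")
})

test_that("GEO series-matrix dialect parses samples and expression block", {
    gp <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(
        "!Series_title\t\"demo\"",
        "!Sample_title\t\"patient 1 CT\"\t\"patient 1 HM\"\t\"patient 2 CT\"",
        "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"",
        "!series_matrix_table_begin",
        "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"",
        "\"pA\"\t1.5\t2.5\t3.5",
        "\"pB\"\t4\tNA\t6",
        "!series_matrix_table_end"), gp)
    te <- readExpressionMatrix(gp, dialect = "geo_series_matrix",
                               patientRegex = "patient ([0-9]+)")
    expect_identical(dim(te), c(2L, 3L))
    expect_identical(unname(as.character(tissueCode(te))),
                     c("CT", "HM", "CT"))
    expect_identical(unname(as.character(patientId(te))),
                     c("1", "1", "2"))
    expect_true(is.na(exprsValues(te)["pB", "GSM2"]))
})

test_that("presence filter keeps the inclusive boundary and matches a
          brute-force recount", {
    # probe present in exactly 13 of 26 samples passes at 0.5
    m <- matrix(10, 2, 26,
                dimnames = list(c("border", "absent"), sprintf("s%02d", 1:26)))
    pres <- rbind(border = rep(c(TRUE, FALSE), each = 13),
                  absent = rep(FALSE, 26))
    te <- makeTE(m, rep(c("CT", "HM"), 13),
                 rep(sprintf("P%02d", 1:13), each = 2))
    kept <- presenceFilter(te, present = pres, minFraction = 0.5)
    expect_identical(rownames(kept), "border")
    expect_identical(ncol(kept), 26L)
    expect_error(presenceFilter(te, pres, minFraction = 0),
                 "minFraction")
    expect_error(presenceFilter(te, pres, minFraction = 1.2),
                 "minFraction")
    # random presence matrix vs an independent loop-based recount
    set.seed(7)
    m2 <- matrix(rnorm(100 * 20), 100, 20)
    te2 <- makeTE(m2, rep(c("CT", "HM"), 10), rep(sprintf("P%d", 1:10), 2))
    pres2 <- matrix(runif(2000) > 0.4, 100, 20)
    kept2 <- presenceFilter(te2, pres2, minFraction = 0.5)
    expected <- character()
    for (i in 1:100) {
        cnt <- 0L
        for (j in 1:20) if (pres2[i, j]) cnt <- cnt + 1L
        if (cnt / 20 >= 0.5) expected <- c(expected, rownames(te2)[i])
    }
    expect_identical(rownames(kept2), expected)
    # idempotence on the surviving set
    kept3 <- presenceFilter(kept2, pres2[rownames(te2) %in% rownames(kept2),
                                         , drop = FALSE], 0.5)
    expect_identical(rownames(kept3), rownames(kept2))
})

test_that("log2 transform floors, round-trips and refuses misuse", {
    m <- matrix(c(1, 2, 4, 8), 1, 4,
                dimnames = list("p", sprintf("s%d", 1:4)))
    te <- makeTE(m, c("CT", "HM", "CT", "HM"),
                 c("P1", "P1", "P2", "P2"), scale = "linear")
    lt <- log2Transform(te, floor = 1)
    expect_equal(unname(exprsValues(lt)[1, ]), c(0, 1, 2, 3))
    expect_identical(exprsScale(lt), "log2")
    expect_error(log2Transform(lt), "already")
    mneg <- matrix(-1, 1, 2, dimnames = list("p", c("s1", "s2")))
    expect_error(log2Transform(makeTE(mneg, c("CT", "HM"), "P1",
                                      scale = "linear")),
                 "negative")
    # round-trip above the floor
    set.seed(2)
    m2 <- matrix(runif(200, 0.5, 100), 20, 10)
    te2 <- makeTE(m2, rep(c("CT", "HM"), 5), rep(sprintf("P%d", 1:5), 2),
                  scale = "linear")
    back <- 2^exprsValues(log2Transform(te2, floor = 0.25))
    expect_lt(max(abs(back - m2)), 1e-9)
    # value at the floor maps to log2(floor)
    expect_equal(exprsValues(log2Transform(
        makeTE(matrix(4, 1, 2, dimnames = list("p", c("a", "b"))),
               c("CT", "HM"), "P1", scale = "linear"), floor = 4))[1, 1],
        2)
})

test_that("buildPairs pairs patients deterministically and flags ambiguity", {
    # 13 patients with CT+HM, 7 with CT only -> 13 pairs
    pats <- c(rep(sprintf("P%02d", 1:13), each = 2), sprintf("X%02d", 1:7))
    tiss <- c(rep(c("CT", "HM"), 13), rep("CT", 7))
    m <- matrix(0, 1, length(pats),
                dimnames = list("p", sprintf("s%02d", seq_along(pats))))
    te <- makeTE(m, tiss, pats)
    d <- buildPairs(te, "CT", "HM")
    expect_identical(nPairs(d), 13L)
    expect_identical(pairTable(d)$patient_id, sort(sprintf("P%02d", 1:13)))
    # empty matrix -> empty design
    e <- TissueExperiment(matrix(numeric(), 0, 0), character(), character())
    expect_identical(nPairs(buildPairs(e, "CT", "HM")), 0L)
    # shuffled sample order -> identical pair list
    set.seed(3)
    perm <- sample(ncol(te))
    d2 <- buildPairs(te[, perm], "CT", "HM")
    expect_identical(pairTable(d2), pairTable(d))
    # two samples of the same role abort
    te3 <- makeTE(matrix(0, 1, 3, dimnames = list("p", c("a", "b", "c"))),
                  c("CT", "CT", "HM"), c("P1", "P1", "P1"))
    expect_error(buildPairs(te3, "CT", "HM"), "ambiguous")
})
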