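test_that("expressed-gene counts match brute-force counting and are monotone", {
    v <- cbind(S1 = c(0.5, 1, 5, 25))
    rownames(v) <- paste0("g", 1:4)
    m <- makeFPKM(v, level = "gene")
    cc <- expressedGeneCounts(m, grid = c(1, 20))
    expect_equal(unname(perSampleCurves(cc)[, "S1"]), c(3, 1))

    ## grid entirely below the minimum positive FPKM: all genes counted
    cc2 <- expressedGeneCounts(m, grid = c(0.01, 0.1))
    expect_equal(unname(perSampleCurves(cc2)[, "S1"]), c(4, 4))

    ## random matrix vs independent filter-then-count oracle, plus
    ## monotone non-increase along the grid
    m3 <- geneLevelFromTranscripts(randomTxMatrix(80, 6, seed = 21))
    grid <- defaultThresholdGrid()
    cc3 <- expressedGeneCounts(m3, grid)
    for (s in colnames(fpkm(m3))) {
        oracle <- vapply(grid,
                         function(t) sum(fpkm(m3)[, s] >= t), numeric(1))
        expect_equal(unname(perSampleCurves(cc3)[, s]), oracle)
        expect_true(all(diff(perSampleCurves(cc3)[, s]) <= 0))
    }
})

test_that("genes-per-transcript ratio counts passing events on both sides", {
    ## G1 isoforms {10, 5}, G2 isoform {0.5}: at t=1, 1 gene / 2 transcripts
    v <- cbind(S1 = c(10, 5, 0.5))
    rownames(v) <- c("t1", "t2", "t3")
    m <- makeFPKM(v, geneId = c("G1", "G1", "G2"))
    r <- transcriptsPerGeneRatio(m, grid = c(1, 50))
    expect_equal(unname(perSampleCurves(r)[1, "S1"]), 0.5)
    expect_true(is.na(perSampleCurves(r)[2, "S1"]))  # nothing passes at 50

    ## all genes single-isoform -> ratio exactly 1 wherever defined
    m2 <- makeFPKM(v, geneId = c("a", "b", "c"))
    r2 <- transcriptsPerGeneRatio(m2, grid = c(0.25, 1))
    expect_equal(unname(perSampleCurves(r2)[, "S1"]), c(1, 1))

    ## brute-force oracle on a random table; ratio in (0, 1]; ratio is 1
    ## iff no gene has two passing isoforms
    m3 <- randomTxMatrix(40, 4, seed = 31)
    grid <- c(0.5, 2, 8, 32)
    r3 <- perSampleCurves(transcriptsPerGeneRatio(m3, grid))
    for (s in colnames(fpkm(m3))) for (i in seq_along(grid)) {
        pass <- fpkm(m3)[, s] >= grid[i]
        n_tx <- sum(pass)
        n_gene <- length(unique(geneIds(m3)[pass]))
        if (n_tx == 0) {
            expect_true(is.na(r3[i, s]))
        } else {
            expect_equal(unname(r3[i, s]), n_gene / n_tx)
            expect_true(r3[i, s] > 0 && r3[i, s] <= 1)
            multi <- any(table(geneIds(m3)[pass]) >= 2)
            expect_identical(unname(r3[i, s] == 1), !multi)
        }
    }
})

test_that("mean transcript length curve averages passing transcripts", {
    v <- cbind(S1 = c(30, 2))
    rownames(v) <- c("t1", "t2")
    m <- makeFPKM(v, geneId = c("g1", "g2"), length = c(1000, 3000))
    l <- meanTranscriptLengthCurve(m, grid = c(1, 20))
    expect_equal(unname(perSampleCurves(l)[, "S1"]), c(2000, 1000))

    ## constant lengths -> constant curve
    m2 <- randomTxMatrix(30, 2, seed = 41)
    SummarizedExperiment::rowData(m2)$length <- 1500L
    l2 <- meanTranscriptLengthCurve(m2, grid = c(0.5, 5))
    expect_true(all(perSampleCurves(l2) == 1500, na.rm = TRUE))

    ## random input vs filter-then-mean oracle
    m3 <- randomTxMatrix(50, 4, seed = 43)
    grid <- c(1, 10)
    l3 <- perSampleCurves(meanTranscriptLengthCurve(m3, grid))
    for (s in colnames(fpkm(m3))) for (i in seq_along(grid)) {
        pass <- fpkm(m3)[, s] >= grid[i]
        if (any(pass))
            expect_equal(unname(l3[i, s]), unname(mean(txLengths(m3)[pass])))
    }
})

test_that("length-expression correlation respects bins and flags sparse ones", {
    ## proportional length and FPKM within a bin -> r = 1
    v <- cbind(S1 = c(1.2, 2.4, 3.6, 4.8, 20))
    rownames(v) <- paste0("t", 1:5)
    m <- makeFPKM(v, geneId = paste0("g", 1:5),
                  length = c(1200, 2400, 3600, 4800, 500))
    b <- lengthExpressionCorrelation(m, bins = cbind(lo = c(1, 5),
                                                     hi = c(5, Inf)))
    expect_equal(unname(b@perSample[1, "S1"]), 1)
    expect_true(is.na(b@perSample[2, "S1"]))  # only 1 transcript in (5, Inf]

    ## planted independence: mean r near zero across seeds
    rs <- sapply(1:10, function(s) {
        set.seed(s)
        n <- 2000
        vv <- cbind(S1 = runif(n, 1.01, 4.99))
        rownames(vv) <- paste0("t", seq_len(n))
        mm <- makeFPKM(vv, geneId = paste0("g", seq_len(n)),
                       length = sample(200:8000, n, replace = TRUE))
        bb <- lengthExpressionCorrelation(mm, bins = cbind(1, 5))
        bb@perSample[1, "S1"]
    })
    expect_lt(abs(mean(rs)), 0.05)
})

test_that("cell-type summaries use the SEM formula and permutation invariance holds", {
    m <- randomTxMatrix(60, 6, seed = 51)  # 3 cell types x 2 replicates
    g <- geneLevelFromTranscripts(m)
    cc <- expressedGeneCounts(g, c(1, 5))
    info <- sampleInfo(g)
    for (ct in unique(info$cell_type)) {
        cols <- info$sample_id[info$cell_type == ct]
        sub <- perSampleCurves(cc)[, cols, drop = FALSE]
        expect_equal(unname(cellTypeMeans(cc)[, ct]), unname(rowMeans(sub)))
        expect_equal(unname(cellTypeSEMs(cc)[, ct]),
                     unname(apply(sub, 1, sd) / sqrt(length(cols))))
    }
    ## permuting features and samples leaves curves unchanged (up to relabel)
    perm_f <- sample(nrow(g)); perm_s <- sample(ncol(g))
    cc2 <- expressedGeneCounts(g[perm_f, perm_s], c(1, 5))
    expect_equal(perSampleCurves(cc2)[, colnames(perSampleCurves(cc))],
                 perSampleCurves(cc))
    r1 <- transcriptsPerGeneRatio(m, c(1, 5))
    r2 <- transcriptsPerGeneRatio(m[sample(nrow(m)), perm_s], c(1, 5))
    expect_equal(perSampleCurves(r2)[, colnames(perSampleCurves(r1))],
                 perSampleCurves(r1))
})

test_that("group ratio curve divides high by low cell-type means", {
    m <- randomTxMatrix(60, 8, seed = 61)  # 4 cell types x 2 replicates
    g <- geneLevelFromTranscripts(m)
    cc <- expressedGeneCounts(g, c(0.5, 2, 8))
    groups <- setNames(c("high", "high", "low", "low"),
                       unique(sampleInfo(g)$cell_type))
    ratio <- groupRatioCurve(cc, groups)
    hi <- rowMeans(cellTypeMeans(cc)[, c("ct1", "ct2")])
    lo <- rowMeans(cellTypeMeans(cc)[, c("ct3", "ct4")])
    expect_equal(unname(ratio), unname(hi / lo))
    ## identical groups -> ratio exactly 1
    groups_same <- setNames(c("high", "low", "high", "low"),
                            unique(sampleInfo(g)$cell_type))
    cc_dup <- ThresholdCurveSet(c(1, 2), "gene_count",
                                matrix(c(4, 2, 4, 2), 2, 2,
                                       dimnames = list(NULL, c("A", "B"))),
                                cellType = c("ctA", "ctB"))
    expect_equal(unname(groupRatioCurve(cc_dup,
                     c(ctA = "high", ctB = "low"))), c(1, 1))
    ## doubled counts -> constant 2
    cc_dbl <- ThresholdCurveSet(c(1, 2), "gene_count",
                                matrix(c(8, 4, 4, 2), 2, 2,
                                       dimnames = list(NULL, c("A", "B"))),
                                cellType = c("ctA", "ctB"))
    expect_equal(unname(groupRatioCurve(cc_dbl,
                     c(ctA = "high", ctB = "low"))), c(2, 2))
})
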