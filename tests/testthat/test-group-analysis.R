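## shared small curve set: 4 cell types x 2 replicates, 3 thresholds
makeCurves <- function(perCt, noise = 0, seed = 1) {
    set.seed(seed)
    samples <- as.vector(sapply(names(perCt), paste0, c("_r1", "_r2")))
    ps <- sapply(seq_along(samples), function(j) {
        ct <- sub("_r[12]$", "", samples[j])
        perCt[[ct]] + rnorm(length(perCt[[ct]]), 0, noise)
    })
    colnames(ps) <- samples
    ThresholdCurveSet(c(1, 5, 20), "mean_tx_length", ps,
                      cellType = sub("_r[12]$", "", samples))
}

test_that("permutation curve test: identical groups give statistic 0 and p 1", {
    perCt <- list(A = c(10, 8, 6), B = c(10, 8, 6),
                  C = c(10, 8, 6), D = c(10, 8, 6))
    cc <- makeCurves(perCt)
    groups <- c(A = "high", B = "high", C = "low", D = "low")
    res <- curveGroupTest(cc, groups, "permutation", nPerm = 99, seed = 3)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
    expect_identical(unname(res$group_sizes), c(2L, 2L))
    ## fewer than 2 cell types per group is not exchangeable
    expect_error(curveGroupTest(cc, c(A = "high", B = "low", C = "low",
                                      D = "low"), "permutation"),
                 "insufficient exchangeability")
})

test_that("repeated-measures F detects a planted group shift", {
    perCt <- list(A = c(100, 80, 60), B = c(102, 82, 61),
                  C = c(50, 40, 30), D = c(51, 41, 31))
    cc <- makeCurves(perCt, noise = 1, seed = 11)
    groups <- c(A = "high", B = "high", C = "low", D = "low")
    res <- curveGroupTest(cc, groups, "rm_anova_f")
    expect_identical(res$n_permutations, 0L)
    expect_gt(res$statistic, 50)
    expect_lt(res$p_value, 0.05)
    ## permutation p on 4 cell types is bounded below by 1/(nPerm+1) and
    ## cannot beat the label-exchange granularity
    resp <- curveGroupTest(cc, groups, "permutation", nPerm = 199, seed = 5)
    expect_gte(resp$p_value, 1 / 200)
    expect_lte(resp$p_value, 0.5)
})

test_that("fold-change histogram applies the printed filters and bins by direction", {
    de <- data.frame(
        gene_id = paste0("g", 1:6),
        fpkm_a = c(1, 10, 6, 8, 2, 0),
        fpkm_b = c(10, 1, 30, 8.5, 40, 7),
        log2_fold = c(log2(10), log2(0.1), log2(5), log2(8.5 / 8),
                      log2(20), Inf),
        q_value = c(0.01, 0.01, 0.2, 0.01, 0.04, 0.001),
        status = c(rep("tested", 5), "tested"))
    h <- deFoldChangeHistogram(de, minFpkm = 5, minFold = 3, maxQ = 0.05,
                               binEdges = c(3, 10, 30, Inf))
    kept <- attr(h, "retained")
    ## g1 up fold 10; g2 down fold 10; g3 fails q; g4 fails fold;
    ## g5 up fold 20; g6 infinite fold -> last bin, up
    expect_setequal(kept$gene_id, c("g1", "g2", "g5", "g6"))
    expect_equal(h$up, c(0, 2, 1))
    expect_equal(h$down, c(0, 1, 0))

    ## 20 random records vs a brute-force filter-then-bin oracle
    set.seed(13)
    de2 <- data.frame(gene_id = paste0("r", 1:20),
                      fpkm_a = runif(20, 0, 30), fpkm_b = runif(20, 0, 30),
                      q_value = runif(20, 0, 0.2), status = "tested")
    de2$log2_fold <- log2(de2$fpkm_b / de2$fpkm_a)
    h2 <- deFoldChangeHistogram(de2, binEdges = c(3, 5, 10, Inf))
    fold <- 2^abs(de2$log2_fold)
    keep <- de2$q_value < 0.05 & pmax(de2$fpkm_a, de2$fpkm_b) > 5 & fold >= 3
    for (b in 1:3) {
        lo <- c(3, 5, 10)[b]; hi <- c(5, 10, Inf)[b]
        expect_identical(h2$up[b],
            sum(keep & de2$log2_fold > 0 & fold >= lo & fold < hi))
        expect_identical(h2$down[b],
            sum(keep & de2$log2_fold < 0 & fold >= lo & fold < hi))
    }

    ## filter monotonicity: loosening q or fold never drops a record
    loose_q <- attr(deFoldChangeHistogram(de2, maxQ = 0.1,
                                          binEdges = c(3, Inf)), "retained")
    strict <- attr(deFoldChangeHistogram(de2, binEdges = c(3, Inf)), "retained")
    expect_true(all(strict$gene_id %in% loose_q$gene_id))
    loose_f <- attr(deFoldChangeHistogram(de2, minFold = 2,
                                          binEdges = c(2, Inf)), "retained")
    expect_true(all(strict$gene_id %in% loose_f$gene_id))
})

test_that("enriched-DE counts require every cell type in the group to pass", {
    ## high group cell types with per-type FPKMs {25, 30, 22, 40} for gene gA
    cts <- paste0("ct", 1:8)
    grp <- rep(c("high", "low"), each = 4)
    v <- matrix(1, 2, 16)
    rownames(v) <- c("gA", "gB")
    colnames(v) <- as.vector(sapply(cts, paste0, c("_r1", "_r2")))
    v["gA", 1:8] <- rep(c(25, 30, 22, 40), each = 2)   # high-group cts
    v["gA", 9:16] <- 2
    v["gB", ] <- 5
    m <- makeFPKM(v, level = "gene",
                  cellType = rep(cts, each = 2),
                  replicate = rep(1:2, 8), group = rep(grp, each = 2))
    de <- data.frame(gene_id = c("gA", "gB"),
                     fpkm_a = c(2, 5), fpkm_b = c(29.25, 5),
                     log2_fold = c(log2(29.25 / 2), 0),
                     q_value = c(0.01, 0.8), status = "tested")
    res <- enrichedDECountsByThreshold(de, m, grid = c(1, 20, 50))
    cnt <- perSampleCurves(res$curves)
    expect_equal(unname(cnt[, "high"]), c(1, 1, 0))  # counted at 20, not 50
    expect_equal(unname(cnt[, "low"]), c(0, 0, 0))
    expect_true(all(diff(cnt[, "high"]) <= 0))
    ## ratio flagged where the low count is zero
    expect_true(all(is.na(res$ratio)))
    ## empty DE table -> zero curves
    res0 <- enrichedDECountsByThreshold(de[0, ], m, grid = c(1, 20))
    expect_true(all(perSampleCurves(res0$curves) == 0))
    ## unknown gene id -> warning and reported exclusion
    de_bad <- rbind(de, data.frame(gene_id = "missing", fpkm_a = 1,
                                   fpkm_b = 10, log2_fold = log2(10),
                                   q_value = 0.001, status = "tested"))
    expect_warning(res2 <- enrichedDECountsByThreshold(de_bad, m,
                                                       grid = c(1, 20)),
                   "absent")
    expect_identical(res2$excluded, "missing")
})

test_that("DE length comparison selects by the 1 percent closeness rule", {
    ## 10.0 vs 10.05 is within 1%; 10.0 vs 10.2 is not
    expect_true(abs(10.0 - 10.05) <= 0.01 * max(10.0, 10.05))
    expect_false(abs(10.0 - 10.2) <= 0.01 * max(10.0, 10.2))
    set.seed(17)
    n <- 50
    de <- data.frame(gene_id = paste0("g", 1:n),
                     fpkm_a = runif(n, 2, 40), status = "tested")
    close <- seq_len(n) %% 2 == 0
    de$fpkm_b <- ifelse(close, de$fpkm_a * 1.005, de$fpkm_a * 4)
    de$log2_fold <- log2(de$fpkm_b / de$fpkm_a)
    de$q_value <- ifelse(close, runif(n, 0.2, 1), runif(n, 0, 0.04))
    k <- c(2L, 1L, 3L, rep(1L, n - 3L))  # a few multi-isoform genes
    gene <- rep(de$gene_id, k)
    vtx <- matrix(runif(length(gene), 2, 5), ncol = 1,
                  dimnames = list(paste0(gene, ".", sequence(k)), "S1"))
    tx <- makeFPKM(vtx, geneId = gene,
                   length = sample(500:3000, length(gene), replace = TRUE))
    res <- deLengthComparison(de, tx)
    ## brute-force select-then-average oracle
    not_ids <- de$gene_id[close]
    de_ids <- de$gene_id[!close]
    expect_equal(res$mean_length_not_de,
                 mean(txLengths(tx)[geneIds(tx) %in% not_ids]))
    expect_equal(res$mean_length_de,
                 mean(txLengths(tx)[geneIds(tx) %in% de_ids]))
    oracle <- t.test(txLengths(tx)[geneIds(tx) %in% de_ids],
                     txLengths(tx)[geneIds(tx) %in% not_ids])
    expect_equal(res$t_statistic, unname(oracle$statistic))
    expect_equal(res$p_value, oracle$p.value)
    ## identical length distributions in both sets: mean difference 0, t = 0
    de6 <- de[1:12, ]
    de6$fpkm_a <- 10; de6$fpkm_b <- ifelse(close[1:12], 10.05, 40)
    de6$log2_fold <- log2(de6$fpkm_b / de6$fpkm_a)
    vv <- matrix(10, 12, 1, dimnames = list(de6$gene_id, "S1"))
    tx6 <- makeFPKM(vv, geneId = de6$gene_id,
                    length = rep(c(1000L, 1500L, 2000L), 4))
    res6 <- deLengthComparison(de6, tx6)
    expect_equal(res6$mean_length_de - res6$mean_length_not_de, 0)
    expect_equal(res6$t_statistic, 0)
    expect_gt(res6$p_value, 0.05)
    ## insufficient data errors
    expect_error(deLengthComparison(de[1:2, ], tx), "insufficient data")
})
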