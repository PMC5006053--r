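test_that("upper-quartile normalization matches hand-computed order statistics", {
    ## UQ(A) of {1,2,3,4} = 3.25, UQ(B) of {2,4,6,8} = 6.5 by linear
    ## interpolation; mean 4.875 -> scale A x1.5, B x0.75
    v <- cbind(A = c(1, 2, 3, 4, 0), B = c(2, 4, 6, 8, 0))
    rownames(v) <- paste0("g", 1:5)
    m <- makeFPKM(v, geneId = rownames(v), level = "gene")
    out <- fpkm(upperQuartileNormalize(m))
    expect_equal(unname(out[, "A"]), c(1, 2, 3, 4, 0) * 1.5)
    expect_equal(unname(out[, "B"]), c(2, 4, 6, 8, 0) * 0.75)

    ## identical samples -> identity
    v2 <- cbind(A = c(1, 5, 9, 2), B = c(1, 5, 9, 2))
    rownames(v2) <- paste0("g", 1:4)
    m2 <- makeFPKM(v2, level = "gene")
    expect_equal(fpkm(upperQuartileNormalize(m2)), v2)

    ## degenerate sample (<4 positive values) errors with the sample name
    v3 <- cbind(A = c(1, 2, 0, 0, 3), B = c(1, 2, 3, 4, 5))
    rownames(v3) <- paste0("g", 1:5)
    expect_error(upperQuartileNormalize(makeFPKM(v3, level = "gene")),
                 "degenerate sample.*A")
})

test_that("normalization equalizes per-sample UQs, is idempotent and rank-preserving", {
    set.seed(42)
    v <- matrix(rlnorm(600, 1, 1.3), 150, 4,
                dimnames = list(paste0("g", 1:150), paste0("S", 1:4)))
    v[sample(length(v), 40)] <- 0
    m <- makeFPKM(v, level = "gene", cellType = paste0("ct", 1:4))
    n1 <- upperQuartileNormalize(m)
    uq <- apply(fpkm(n1), 2, function(x) quantile(x[x > 0], 0.75, type = 7))
    expect_lt(max(uq) - min(uq), 1e-9)
    n2 <- upperQuartileNormalize(n1)
    expect_lt(max(abs(fpkm(n2) - fpkm(n1)) / pmax(fpkm(n1), 1e-300)), 1e-9)
    for (j in 1:4)
        expect_identical(order(fpkm(n1)[, j]), order(v[, j]))
    expect_identical(fpkm(n1) == 0, v == 0)
})

test_that("expression filtering honours scope, threshold inclusivity and nesting", {
    v <- cbind(S1 = c(0.5, 1.0, 5.0), S2 = c(0.2, 0.3, 0.4))
    rownames(v) <- c("a", "b", "c")
    m <- makeFPKM(v, level = "gene", cellType = c("x", "y"))
    expect_identical(rownames(filterExpressed(m, 1, "any_sample")), c("b", "c"))
    ## inclusive >=: gene b (S2 = 0.3) passes at exactly 0.3 in all samples
    expect_identical(rownames(filterExpressed(m, 0.3, "all_samples")),
                     c("b", "c"))
    expect_identical(nrow(filterExpressed(m, 0, "any_sample")), 3L)
    ## nesting: higher threshold retains a subset; all_samples within any_sample
    m2 <- randomTxMatrix(60, 6, seed = 9)
    for (t in c(0.5, 2, 10)) {
        lo <- rownames(filterExpressed(m2, t, "any_sample"))
        hi <- rownames(filterExpressed(m2, t * 4, "any_sample"))
        expect_true(all(hi %in% lo))
        expect_true(all(rownames(filterExpressed(m2, t, "all_samples")) %in% lo))
    }
})

test_that("replicate correlations match the covariance formula and flag degeneracy", {
    set.seed(5)
    v <- matrix(rlnorm(800), 200, 4,
                dimnames = list(paste0("g", 1:200), paste0("S", 1:4)))
    m <- makeFPKM(v, level = "gene", cellType = c("a", "a", "b", "b"),
                  replicate = c(1L, 2L, 1L, 2L))
    r <- replicateCorrelationMatrix(m, transform = "none")
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 4))
    ## independent textbook formula: cov / (sigma_x sigma_y)
    x <- v[, 1]; y <- v[, 3]
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
        (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
    expect_equal(unname(r["S1", "S3"]), oracle, tolerance = 1e-12)
    ## duplicated sample column -> r = 1
    v2 <- v; v2[, 2] <- v2[, 1]
    m2 <- makeFPKM(v2, level = "gene", cellType = c("a", "a", "b", "b"),
                   replicate = c(1L, 2L, 1L, 2L))
    expect_equal(unname(replicateCorrelationMatrix(m2)["S1", "S2"]), 1)
    ## zero-variance column errors with the sample name
    v3 <- v; v3[, 4] <- 2
    m3 <- makeFPKM(v3, level = "gene", cellType = c("a", "a", "b", "b"),
                   replicate = c(1L, 2L, 1L, 2L))
    expect_error(replicateCorrelationMatrix(m3, "none"), "zero-variance.*S4")
})

test_that("within-cell-type mean correlation averages replicate pairs", {
    ref <- referenceCorrelationMatrix()
    w <- meanWithinCellTypeCorrelation(ref$r, ref$meta)
    expect_identical(length(w$per_cell_type), 8L)
    expect_equal(round(w$mean, 3), 0.949)
    ## identical replicate columns -> mean exactly 1
    v <- matrix(rlnorm(100), 25, 4,
                dimnames = list(paste0("g", 1:25), paste0("S", 1:4)))
    v[, 2] <- v[, 1]; v[, 4] <- v[, 3]
    m <- makeFPKM(v, level = "gene", cellType = c("a", "a", "b", "b"),
                  replicate = c(1L, 2L, 1L, 2L))
    w2 <- meanWithinCellTypeCorrelation(replicateCorrelationMatrix(m),
                                        sampleInfo(m))
    expect_equal(w2$mean, 1)
    ## a single-sample cell type is excluded with a warning
    meta3 <- data.frame(sample_id = paste0("S", 1:4),
                        cell_type = c("a", "a", "a", "c"),
                        replicate = c(1L, 2L, 3L, 1L))
    expect_warning(w3 <- meanWithinCellTypeCorrelation(
        replicateCorrelationMatrix(m), meta3), "single sample")
    expect_identical(names(w3$per_cell_type), "a")
})

test_that("planted correlation structure is recovered from simulated replicates", {
    ## shared + independent log-normal components with known correlation
    ## correlation planted on the log2(FPKM + 1) scale: shared component
    ## weight a^2 = r_between, within-type extra weight b^2 = r_within -
    ## r_between, independent noise the rest
    gen <- function(seed, n = 2000, r_within = 0.95, r_between = 0.3) {
        set.seed(seed)
        a <- sqrt(r_between); b <- sqrt(r_within - r_between)
        cc <- sqrt(1 - r_within)
        base <- rnorm(n); ct1 <- rnorm(n); ct2 <- rnorm(n)
        z <- cbind(S1 = a * base + b * ct1 + cc * rnorm(n),
                   S2 = a * base + b * ct1 + cc * rnorm(n),
                   S3 = a * base + b * ct2 + cc * rnorm(n),
                   S4 = a * base + b * ct2 + cc * rnorm(n))
        z <- 4 + 1.5 * z  # log2 scale, almost surely positive
        rownames(z) <- paste0("g", seq_len(n))
        pmax(2^z - 1, 0)  # so that log2(FPKM + 1) recovers z
    }
    within <- sapply(1:5, function(s) {
        m <- makeFPKM(gen(s), level = "gene",
                      cellType = c("a", "a", "b", "b"),
                      replicate = c(1L, 2L, 1L, 2L))
        r <- replicateCorrelationMatrix(m, transform = "log2p1")
        meanWithinCellTypeCorrelation(r, sampleInfo(m))$mean
    })
    expect_true(all(abs(within - 0.95) < 0.02))
})
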