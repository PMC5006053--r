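## Shared fixtures and independent oracles for the test suite.

## quick FPKMExperiment builder: values matrix -> transcript/gene container
makeFPKM <- function(values, geneId = rownames(values), length = 1000L,
                     cellType = colnames(values),
                     replicate = rep(1L, ncol(values)),
                     group = NULL, level = "transcript") {
    meta <- data.frame(sample_id = colnames(values), cell_type = cellType,
                       replicate = replicate, stringsAsFactors = FALSE)
    if (!is.null(group)) meta$group <- group
    FPKMExperiment(values, geneId = geneId, length = length, meta = meta,
                   level = level)
}

## random transcript table: nGenes genes, 1..3 isoforms, nSamples columns
randomTxMatrix <- function(nGenes, nSamples, seed, maxIso = 3) {
    set.seed(seed)
    k <- sample.int(maxIso, nGenes, replace = TRUE)
    gene <- rep(sprintf("g%03d", seq_len(nGenes)), k)
    ids <- paste0(gene, ".", sequence(k))
    v <- matrix(round(rlnorm(length(ids) * nSamples, log(3), 1.5), 4),
                length(ids), nSamples,
                dimnames = list(ids, sprintf("S%02d", seq_len(nSamples))))
    makeFPKM(v, geneId = gene,
             length = sample(200:5000, length(ids), replace = TRUE),
             cellType = rep(sprintf("ct%d", seq_len(ceiling(nSamples / 2))),
                            each = 2)[seq_len(nSamples)],
             replicate = rep(1:2, length.out = nSamples))
}

## exhaustive-rescan clustering oracle, independent of the implementation:
## keeps explicit leaf-member sets, recomputes every pairwise centroid
## similarity from scratch each step, same lexicographic tie-break.
## Returns the merge sequence as a list of sorted leaf-index pairs of sets.
bruteCentroidMerges <- function(items, sim = function(x, y)
                                    sum(x * y) / sqrt(sum(x^2) * sum(y^2))) {
    n <- nrow(items)
    clusters <- lapply(seq_len(n), identity)  # creation order preserved
    created <- seq_len(n)
    merges <- list()
    heights <- numeric()
    while (length(clusters) > 1L) {
        best <- NULL; best_s <- -Inf; best_key <- c(Inf, Inf)
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            ci <- colMeans(items[clusters[[i]], , drop = FALSE])
            cj <- colMeans(items[clusters[[j]], , drop = FALSE])
            s <- sim(ci, cj)
            key <- sort(c(created[i], created[j]))
            better <- s > best_s + 1e-12 ||
                (s >= best_s - 1e-12 &&
                 (key[1] < best_key[1] ||
                  (key[1] == best_key[1] && key[2] < best_key[2])))
            if (better) { best_s <- max(s, best_s); best <- c(i, j); best_key <- key }
        }
        merges[[length(merges) + 1L]] <-
            list(sort(clusters[[best[1]]]), sort(clusters[[best[2]]]))
        heights <- c(heights, 1 - best_s)
        newc <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        keep <- setdiff(seq_along(clusters), best)
        clusters <- c(clusters[keep], list(newc))
        created <- c(created[keep], n + length(merges))
    }
    list(merges = merges, heights = heights)
}

## merge sequence of a CentroidDendrogram as leaf-set pairs, for comparison
dendMerges <- function(d) {
    n <- length(d@labels)
    leaves_of <- vector("list", n - 1L)
    expand <- function(code) {
        if (code < 0L) -code else leaves_of[[code]]
    }
    out <- vector("list", n - 1L)
    for (s in seq_len(n - 1L)) {
        a <- expand(d@merge[s, 1]); b <- expand(d@merge[s, 2])
        leaves_of[[s]] <- sort(c(a, b))
        pair <- list(sort(a), sort(b))
        ## order the pair by smallest leaf for set comparison
        if (min(pair[[2]]) < min(pair[[1]])) pair <- pair[c(2, 1)]
        out[[s]] <- pair
    }
    out
}

normalizeMergePair <- function(pair) {
    if (min(pair[[2]]) < min(pair[[1]])) pair[c(2, 1)] else pair
}
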