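## Core statistics over an FPKM threshold grid: expressed-gene counts,
## genes-per-transcript ratios, transcript-length diagnostics, binned
## length-expression correlations and two-group ratio curves.

#' Default FPKM threshold grid
#'
#' Log-spaced grid covering the landmarks of interest for expressed-gene
#' counting (below 1 FPKM, the 1-FPKM expression cutoff, and the >= 20 FPKM
#' high-expression regime).
#'
#' @return numeric vector of strictly increasing FPKM thresholds.
#' @export
defaultThresholdGrid <- function() c(0.125, 0.25, 0.5, 1, 2, 5, 10, 20, 50, 100)

#' Default FPKM bins for length-expression correlation
#' @return two-column matrix of half-open (lo, hi] FPKM intervals.
#' @export
defaultFpkmBins <- function() {
    lo <- c(0, 0.125, 0.5, 1, 5, 20)
    hi <- c(0.125, 0.5, 1, 5, 20, Inf)
    cbind(lo = lo, hi = hi)
}

.check_grid <- function(grid) {
    if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
        stop("threshold grid must be strictly increasing and positive")
    grid
}

#' Expressed-gene counts across FPKM thresholds
#'
#' For each sample and threshold t, the number of genes with FPKM >= t
#' (inclusive), with per-cell-type mean and SEM over replicates. Counts are
#' non-increasing along the grid by construction.
#'
#' @param m a gene-level \linkS4class{FPKMExperiment}.
#' @param grid increasing positive FPKM thresholds.
#' @return A \linkS4class{ThresholdCurveSet} with statistic
#'   \code{"gene_count"}.
#' @export
expressedGeneCounts <- function(m, grid = defaultThresholdGrid()) {
    if (exprLevel(m) != "gene")
        stop("expressedGeneCounts needs a gene-level matrix; see geneLevelFromTranscripts()")
    .check_grid(grid)
    v <- fpkm(m)
    counts <- vapply(grid, function(t) colSums(v >= t), numeric(ncol(v)))
    counts <- matrix(t(counts), nrow = length(grid),
                     dimnames = list(NULL, colnames(v)))
    ThresholdCurveSet(grid, "gene_count", counts, sampleInfo(m)$cell_type)
}

#' Genes-per-transcript ratio across FPKM thresholds
#'
#' For each sample and threshold t: (number of distinct genes with at least
#' one transcript at FPKM >= t) divided by (number of transcripts at
#' FPKM >= t). The ratio lies in (0, 1]; it equals 1 exactly when no gene
#' has two passing isoforms, and lower values mean more expressed isoforms
#' per gene. Thresholds where no transcript passes are flagged \code{NA}.
#'
#' @param tx a transcript-level \linkS4class{FPKMExperiment}.
#' @param grid increasing positive FPKM thresholds.
#' @return A \linkS4class{ThresholdCurveSet} with statistic
#'   \code{"genes_per_transcript_ratio"}.
#' @export
transcriptsPerGeneRatio <- function(tx, grid = defaultThresholdGrid()) {
    if (exprLevel(tx) != "transcript")
        stop("transcriptsPerGeneRatio needs a transcript-level matrix")
    .check_grid(grid)
    v <- fpkm(tx)
    gf <- factor(geneIds(tx), levels = unique(geneIds(tx)))
    ratios <- matrix(NA_real_, length(grid), ncol(v),
                     dimnames = list(NULL, colnames(v)))
    for (i in seq_along(grid)) {
        pass <- v >= grid[i]
        n_tx <- colSums(pass)
        n_gene <- colSums(rowsum(pass + 0, gf, reorder = FALSE) > 0)
        ok <- n_tx > 0
        ratios[i, ok] <- n_gene[ok] / n_tx[ok]
    }
    ThresholdCurveSet(grid, "genes_per_transcript_ratio", ratios,
                      sampleInfo(tx)$cell_type)
}

#' Mean expressed-transcript length across FPKM thresholds
#'
#' For each sample and threshold t, the mean length (bp) of transcripts
#' with FPKM >= t; flagged \code{NA} when no transcript passes.
#'
#' @param tx a transcript-level \linkS4class{FPKMExperiment} with lengths.
#' @param grid increasing positive FPKM thresholds.
#' @return A \linkS4class{ThresholdCurveSet} with statistic
#'   \code{"mean_tx_length"}.
#' @export
meanTranscriptLengthCurve <- function(tx, grid = defaultThresholdGrid()) {
    if (exprLevel(tx) != "transcript")
        stop("meanTranscriptLengthCurve needs a transcript-level matrix")
    .check_grid(grid)
    v <- fpkm(tx)
    len <- txLengths(tx)
    out <- matrix(NA_real_, length(grid), ncol(v),
                  dimnames = list(NULL, colnames(v)))
    for (i in seq_along(grid)) {
        pass <- v >= grid[i]
        n <- colSums(pass)
        ok <- n > 0
        out[i, ok] <- colSums(pass * len)[ok] / n[ok]
    }
    ThresholdCurveSet(grid, "mean_tx_length", out, sampleInfo(tx)$cell_type)
}

#' Length-expression correlation within FPKM bins
#'
#' Per sample and half-open FPKM bin (lo, hi], the Pearson correlation
#' between transcript length and FPKM among transcripts whose FPKM lies in
#' the bin. Bins with fewer than 3 transcripts (or zero length/FPKM
#' variance) are flagged \code{NA}, not fatal.
#'
#' @param tx a transcript-level \linkS4class{FPKMExperiment}.
#' @param bins two-column matrix of (lo, hi] FPKM intervals
#'   (default \code{\link{defaultFpkmBins}}).
#' @return A \linkS4class{BinnedCorrelation}.
#' @export
lengthExpressionCorrelation <- function(tx, bins = defaultFpkmBins()) {
    if (exprLevel(tx) != "transcript")
        stop("lengthExpressionCorrelation needs a transcript-level matrix")
    bins <- as.matrix(bins)
    v <- fpkm(tx)
    len <- txLengths(tx)
    out <- matrix(NA_real_, nrow(bins), ncol(v),
                  dimnames = list(NULL, colnames(v)))
    for (b in seq_len(nrow(bins))) for (j in seq_len(ncol(v))) {
        idx <- v[, j] > bins[b, 1] & v[, j] <= bins[b, 2]
        if (sum(idx) < 3L) next
        if (sd(len[idx]) == 0 || sd(v[idx, j]) == 0) next
        out[b, j] <- cor(len[idx], v[idx, j])
    }
    ct <- sampleInfo(tx)$cell_type
    cts <- unique(ct)
    ctMean <- matrix(NA_real_, nrow(bins), length(cts),
                     dimnames = list(NULL, cts))
    ctSEM <- ctMean
    for (type in cts) {
        cols <- which(ct == type)
        sub <- out[, cols, drop = FALSE]
        ctMean[, type] <- rowMeans(sub)
        if (length(cols) > 1L)
            ctSEM[, type] <- apply(sub, 1, sd) / sqrt(length(cols))
    }
    new("BinnedCorrelation", binLo = unname(bins[, 1]), binHi = unname(bins[, 2]),
        perSample = out, cellType = setNames(ct, colnames(v)),
        ctMean = ctMean, ctSEM = ctSEM)
}

#' High-to-low group ratio of cell-type mean curves
#'
#' Per threshold, the ratio of the mean statistic over cell types labelled
#' \code{high} to the mean over cell types labelled \code{low}. Cell-type
#' means (not individual samples) are the averaging unit. Thresholds where
#' the low-group mean is zero are flagged \code{NA}.
#'
#' @param c a \linkS4class{ThresholdCurveSet}.
#' @param groups named character vector, cell type -> \code{"high"}/
#'   \code{"low"} (see \code{\link{cellTypeGroups}}), or a sample metadata
#'   data.frame carrying a \code{group} column.
#' @return numeric vector over the grid, named by threshold.
#' @export
groupRatioCurve <- function(c, groups) {
    if (is.data.frame(groups)) groups <- cellTypeGroups(groups)
    cts <- colnames(c@ctMean)
    g <- groups[cts]
    hi <- cts[!is.na(g) & g == "high"]
    lo <- cts[!is.na(g) & g == "low"]
    if (!length(hi) || !length(lo))
        stop("both a high and a low group of cell types are required")
    num <- rowMeans(c@ctMean[, hi, drop = FALSE])
    den <- rowMeans(c@ctMean[, lo, drop = FALSE])
    out <- ifelse(den == 0, NA_real_, num / den)
    setNames(out, c@thresholds)
}
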