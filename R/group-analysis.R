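## Two-group statistics: permutation test on threshold curves (with a
## classical repeated-measures F for comparability), DE-table filtering and
## summary curves, and DE vs not-DE transcript-length comparison.

#' Two-group difference test on threshold curves
#'
#' Tests whether the two groups of cell types differ in their threshold
#' curves (e.g. expressed-gene counts).
#'
#' \code{method = "permutation"} (primary): the statistic is the mean over
#' thresholds of the absolute difference between group means of the
#' per-cell-type mean curves. The null distribution is built by permuting
#' the cell-type group labels — the cell type, not the sample, is the
#' exchangeable unit — and the p-value is
#' (1 + #\{null >= observed\}) / (1 + nPerm).
#'
#' \code{method = "rm_anova_f"}: classical one-way repeated-measures F for
#' the group factor with thresholds as the repeated (within-subject) factor
#' and cell types as subjects, sphericity assumed; reported for
#' comparability with conventional ANOVA summaries.
#'
#' @param c a \linkS4class{ThresholdCurveSet}.
#' @param groups named cell type -> \code{"high"}/\code{"low"} vector or a
#'   metadata data.frame with a \code{group} column.
#' @param method \code{"permutation"} or \code{"rm_anova_f"}.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutation draw (required explicitly;
#'   no hidden global state).
#' @return list with \code{statistic_name}, \code{statistic},
#'   \code{p_value}, \code{n_permutations} (0 for the analytic F) and
#'   \code{group_sizes}.
#' @export
curveGroupTest <- function(c, groups, method = c("permutation", "rm_anova_f"),
                           nPerm = 999, seed = 1) {
    method <- match.arg(method)
    if (is.data.frame(groups)) groups <- cellTypeGroups(groups)
    cts <- colnames(c@ctMean)
    g <- groups[cts]
    if (anyNA(g) || !all(g %in% c("high", "low")))
        stop("every cell type needs a high/low group label")
    curves <- c@ctMean  # thresholds x cell types
    if (anyNA(curves))
        stop("curves contain flagged (NA) points; restrict the grid first")
    n_hi <- sum(g == "high"); n_lo <- sum(g == "low")
    stat_of <- function(lab) {
        mean(abs(rowMeans(curves[, lab == "high", drop = FALSE]) -
                 rowMeans(curves[, lab == "low", drop = FALSE])))
    }
    if (method == "permutation") {
        if (n_hi < 2L || n_lo < 2L)
            stop("insufficient exchangeability: need at least 2 cell types per group")
        obs <- stat_of(g)
        old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
        null <- vapply(seq_len(nPerm),
                       function(i) stat_of(sample(g)), numeric(1))
        list(statistic_name = "mean_abs_group_difference", statistic = obs,
             p_value = (1 + sum(null >= obs)) / (1 + nPerm),
             n_permutations = as.integer(nPerm),
             group_sizes = c(high = n_hi, low = n_lo))
    } else {
        df <- data.frame(
            value = as.vector(curves),
            threshold = factor(rep(seq_along(c@thresholds), length(cts))),
            cell_type = factor(rep(cts, each = length(c@thresholds))),
            group = factor(rep(g, each = length(c@thresholds))))
        fit <- aov(value ~ group * threshold + Error(cell_type / threshold),
                   data = df)
        tab <- summary(fit)[["Error: cell_type"]][[1]]
        Fval <- tab["group", "F value"]
        p <- tab["group", "Pr(>F)"]
        list(statistic_name = "rm_anova_group_F", statistic = unname(Fval),
             p_value = unname(p), n_permutations = 0L,
             group_sizes = c(high = n_hi, low = n_lo))
    }
}

## fold changes are reconstructed as 2^|log2_fold|, so a nominal 3-fold
## record can land a few ulps below 3; fold comparisons and bin edges use a
## 1e-9 relative tolerance
.fold_tol <- function(fold) {
    fold * (1 + 1e-9)
}

#' Filter and bin differentially expressed genes by fold change
#'
#' Retains DE records with q-value below \code{maxQ} (strict by default,
#' the conventional phrasing of this filter), expression strictly above
#' \code{minFpkm} in at least one condition, and fold change (2^|log2
#' fold|) of at least \code{minFold}; then counts records per fold-change
#' bin and direction (up = enriched in the high-proportion group, i.e.
#' positive log2 fold of condition b over a).
#'
#' @param de DE data.frame (see \code{\link{readDETable}}).
#' @param minFpkm minimum FPKM in at least one condition (strict >).
#' @param minFold minimum fold change (inclusive >=), >= 1.
#' @param maxQ q-value cutoff.
#' @param binEdges increasing fold-change bin edges; bin i is
#'   [edge_i, edge_{i+1}); an infinite final edge catches infinite folds.
#' @param qInclusive use q <= maxQ instead of the default strict q < maxQ.
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi}, \code{up},
#'   \code{down}; the retained record set is attached as
#'   \code{attr(, "retained")}.
#' @export
deFoldChangeHistogram <- function(de, minFpkm = 5, minFold = 3, maxQ = 0.05,
                                  binEdges = c(3, 5, 10, 20, 50, 100, Inf),
                                  qInclusive = FALSE) {
    stopifnot(minFold >= 1)
    fold <- .fold_tol(2^abs(de$log2_fold))
    qpass <- if (qInclusive) de$q_value <= maxQ else de$q_value < maxQ
    keep <- de$status == "tested" & qpass &
        pmax(de$fpkm_a, de$fpkm_b) > minFpkm & fold >= minFold
    kept <- de[keep, , drop = FALSE]
    up <- kept$log2_fold > 0
    bins <- cbind(binEdges[-length(binEdges)], binEdges[-1])
    cnt <- function(f) {
        idx <- findInterval(f, binEdges, rightmost.closed = FALSE)
        tabulate(idx[idx >= 1 & idx < length(binEdges)],
                 nbins = nrow(bins))
    }
    fk <- .fold_tol(2^abs(kept$log2_fold))
    fk[is.infinite(fk)] <- binEdges[length(binEdges) - 1]  # land in last bin
    out <- data.frame(bin_lo = bins[, 1], bin_hi = bins[, 2],
                      up = cnt(fk[up]), down = cnt(fk[!up]))
    attr(out, "retained") <- kept
    out
}

#' Enriched DE gene counts across FPKM thresholds
#'
#' For each threshold t and group, counts the DE-passing genes (fold >=
#' \code{minFold}, q <= \code{maxQ}) enriched in that group whose
#' expression is at least t in every cell type comprising the group (the
#' cell-type FPKM is the mean over its replicates). Enrichment direction is
#' taken from the sign of \code{log2_fold}, with condition b being the
#' high-proportion group. The companion ratio is high count / low count per
#' threshold, flagged \code{NA} where the low count is zero. DE genes
#' absent from the expression matrix are excluded with a warning; their ids
#' are reported in the result.
#'
#' @param de DE data.frame.
#' @param m a gene-level \linkS4class{FPKMExperiment} with group labels in
#'   its sample metadata.
#' @param grid increasing positive FPKM thresholds.
#' @param minFold minimum fold change (inclusive).
#' @param maxQ q-value cutoff (inclusive, as this filter is conventionally
#'   stated).
#' @return list with \code{curves} (a \linkS4class{ThresholdCurveSet} of
#'   statistic \code{"de_count"} whose two columns are the groups),
#'   \code{ratio} (named vector over the grid) and \code{excluded}
#'   (character vector of unresolvable gene ids).
#' @export
enrichedDECountsByThreshold <- function(de, m, grid = defaultThresholdGrid(),
                                        minFold = 3, maxQ = 0.05) {
    .check_grid(grid)
    groups <- cellTypeGroups(m)
    if (!all(c("high", "low") %in% groups))
        stop("expression matrix metadata must assign high and low groups")
    fold <- .fold_tol(2^abs(de$log2_fold))
    pass <- de$status == "tested" & de$q_value <= maxQ & fold >= minFold
    kept <- de[pass, , drop = FALSE]
    excluded <- setdiff(kept$gene_id, rownames(m))
    if (length(excluded))
        warning(length(excluded),
                " DE gene(s) absent from the expression matrix; excluded")
    kept <- kept[kept$gene_id %in% rownames(m), , drop = FALSE]
    ## per-cell-type mean FPKM over replicates, genes x cell types
    info <- sampleInfo(m)
    ctf <- factor(info$cell_type, levels = unique(info$cell_type))
    ctm <- t(rowsum(t(fpkm(m)), ctf, reorder = FALSE) /
             as.vector(table(ctf)[levels(ctf)]))
    counts <- matrix(0, length(grid), 2,
                     dimnames = list(NULL, c("high", "low")))
    for (grp in c("high", "low")) {
        dir_keep <- if (grp == "high") kept$log2_fold > 0 else kept$log2_fold < 0
        gids <- kept$gene_id[dir_keep]
        if (!length(gids)) next
        grp_cts <- names(groups)[groups == grp]
        minf <- apply(ctm[gids, grp_cts, drop = FALSE], 1, min)
        counts[, grp] <- vapply(grid, function(t) sum(minf >= t), numeric(1))
    }
    curves <- ThresholdCurveSet(grid, "de_count", counts,
                                cellType = c("high", "low"))
    ratio <- ifelse(counts[, "low"] == 0, NA_real_,
                    counts[, "high"] / counts[, "low"])
    list(curves = curves, ratio = setNames(ratio, grid), excluded = excluded)
}

#' Compare transcript lengths of DE and not-DE genes
#'
#' The not-DE set contains genes expressed above 1 FPKM whose two condition
#' FPKMs lie within 1\% of each other (relative to the larger value) with
#' q > 0.05; the DE set contains genes above 1 FPKM in at least one
#' condition with fold >= 2 and q < 0.05. Each selected gene contributes
#' the lengths of its annotated transcripts, and the two length sets are
#' compared with a Welch two-sample t-test.
#'
#' @param de DE data.frame.
#' @param tx a transcript-level \linkS4class{FPKMExperiment} with lengths.
#' @param minFpkm expression cutoff (strict >; default 1 FPKM).
#' @param minFold DE fold-change cutoff (default 2).
#' @param maxQ DE q-value cutoff (strict <; default 0.05).
#' @param relTol closeness tolerance for the not-DE set (default 0.01).
#' @return list with \code{mean_length_de}, \code{mean_length_not_de},
#'   \code{t_statistic}, \code{p_value}, \code{n_de}, \code{n_not_de}.
#' @export
deLengthComparison <- function(de, tx, minFpkm = 1, minFold = 2, maxQ = 0.05,
                               relTol = 0.01) {
    hi <- pmax(de$fpkm_a, de$fpkm_b)
    tested <- de$status == "tested"
    not_de <- tested & hi > minFpkm & de$q_value > maxQ &
        abs(de$fpkm_a - de$fpkm_b) <= relTol * hi
    is_de <- tested & hi > minFpkm & de$q_value < maxQ &
        .fold_tol(2^abs(de$log2_fold)) >= minFold
    g <- geneIds(tx)
    len <- txLengths(tx)
    len_de <- len[g %in% de$gene_id[is_de]]
    len_not <- len[g %in% de$gene_id[not_de]]
    if (length(len_de) < 3L || length(len_not) < 3L)
        stop("insufficient data: need at least 3 transcripts per set (DE: ",
             length(len_de), ", not-DE: ", length(len_not), ")")
    tt <- t.test(len_de, len_not)
    list(mean_length_de = mean(len_de), mean_length_not_de = mean(len_not),
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         n_de = length(len_de), n_not_de = length(len_not))
}
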