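## Upper-quartile normalization, expression filtering and
## replicate-correlation QC.

#' Upper-quartile normalization
#'
#' Rescales each sample so that its upper quartile of expressed values
#' matches the grand scale: every value in sample s is multiplied by
#' mean(UQ over all samples) / UQ(s), where UQ(s) is the 75th percentile of
#' that sample's strictly positive FPKM values (linear interpolation between
#' order statistics, i.e. \code{quantile(type = 7)}). Zeros stay zero, so
#' the statistic is a property of expressed genes and does not depend on
#' annotation size. The operation is idempotent: after one application all
#' per-sample UQs are equal, so a second application is the identity.
#'
#' @param m an \linkS4class{FPKMExperiment}.
#' @return An \linkS4class{FPKMExperiment} with rescaled values.
#' @examples
#' v <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2,
#'     dimnames = list(paste0("g", 1:4), c("A", "B")))
#' meta <- data.frame(sample_id = c("A", "B"), cell_type = c("a", "b"),
#'     replicate = 1L)
#' m <- FPKMExperiment(v, geneId = paste0("g", 1:4), length = 1000L,
#'     meta = meta, level = "gene")
#' fpkm(upperQuartileNormalize(m))  # A scaled x1.5, B scaled x0.75
#' @export
upperQuartileNormalize <- function(m) {
    v <- fpkm(m)
    uq <- vapply(seq_len(ncol(v)), function(j) {
        pos <- v[v[, j] > 0, j]
        if (length(pos) < 4L)
            stop("degenerate sample for upper-quartile normalization: ",
                 colnames(v)[j], " has fewer than 4 positive values")
        unname(quantile(pos, 0.75, type = 7))
    }, numeric(1))
    scale <- mean(uq) / uq
    out <- m
    SummarizedExperiment::assay(out, "fpkm") <-
        sweep(v, 2, scale, `*`)
    out
}

#' Filter features by minimum expression
#'
#' Retains features whose FPKM is at least \code{minFpkm} (inclusive) in at
#' least one sample (\code{scope = "any_sample"}) or in every sample
#' (\code{scope = "all_samples"}); feature order is preserved.
#'
#' @param m an \linkS4class{FPKMExperiment}.
#' @param minFpkm non-negative FPKM cutoff.
#' @param scope \code{"any_sample"} or \code{"all_samples"}.
#' @return The filtered \linkS4class{FPKMExperiment}.
#' @export
filterExpressed <- function(m, minFpkm,
                            scope = c("any_sample", "all_samples")) {
    scope <- match.arg(scope)
    v <- fpkm(m)
    keep <- if (scope == "any_sample")
        apply(v >= minFpkm, 1, any)
    else
        apply(v >= minFpkm, 1, all)
    m[keep, ]
}

#' Pairwise replicate correlation matrix
#'
#' Standard centered Pearson correlation between all pairs of sample
#' columns, by default after a log2(FPKM + 1) transform (raw-FPKM Pearson is
#' dominated by a handful of very highly expressed genes; the transform is
#' configurable because the convention differs between studies).
#'
#' @param m an \linkS4class{FPKMExperiment} with at least 3 features.
#' @param transform \code{"log2p1"} (default) or \code{"none"}.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal, sample ids as dimnames and the per-sample cell type attached
#'   as \code{attr(, "cell_type")}.
#' @export
replicateCorrelationMatrix <- function(m, transform = c("log2p1", "none")) {
    transform <- match.arg(transform)
    v <- fpkm(m)
    if (nrow(v) < 3L) stop("need at least 3 features")
    if (transform == "log2p1") v <- log2(v + 1)
    sds <- apply(v, 2, sd)
    if (any(sds == 0))
        stop("undefined correlation: zero-variance sample column(s): ",
             paste(colnames(v)[sds == 0], collapse = ", "))
    r <- cor(v)
    r[cbind(seq_len(ncol(v)), seq_len(ncol(v)))] <- 1
    attr(r, "cell_type") <- setNames(sampleInfo(m)$cell_type, colnames(v))
    r
}

#' Mean within-cell-type replicate correlation
#'
#' Averages, over cell types, the Pearson correlation(s) between the
#' replicates of each cell type (with more than two replicates, the mean of
#' all within-type pairs). Cell types with a single sample are excluded
#' with a warning.
#'
#' @param r symmetric correlation matrix with sample ids as dimnames (as
#'   from \code{\link{replicateCorrelationMatrix}}, or any published
#'   correlation matrix).
#' @param meta sample metadata data.frame mapping \code{sample_id} to
#'   \code{cell_type}.
#' @return list with \code{mean} (mean over cell types) and
#'   \code{per_cell_type} (named vector of within-type values).
#' @export
meanWithinCellTypeCorrelation <- function(r, meta) {
    ids <- colnames(r)
    ct <- meta$cell_type[match(ids, meta$sample_id)]
    if (anyNA(ct)) stop("metadata missing for sample(s): ",
                        paste(ids[is.na(ct)], collapse = ", "))
    per <- c()
    for (type in unique(ct)) {
        cols <- which(ct == type)
        if (length(cols) < 2L) {
            warning("cell type ", type,
                    " has a single sample; excluded from the within-type mean")
            next
        }
        pairs <- utils::combn(cols, 2)
        per[type] <- mean(r[cbind(pairs[1, ], pairs[2, ])])
    }
    list(mean = mean(per), per_cell_type = per)
}

#' Write a correlation matrix as a lower-triangle TSV
#'
#' Mirrors the familiar replicate-correlation table layout: only the lower
#' triangle (including the unit diagonal) is populated, and cells pairing
#' two replicates of the same cell type are flagged with a trailing
#' \code{*}.
#'
#' @param r correlation matrix from \code{\link{replicateCorrelationMatrix}}.
#' @param path output path.
#' @param meta optional metadata to flag within-type cells (defaults to the
#'   \code{cell_type} attribute of \code{r}).
#' @return \code{path}, invisibly.
#' @export
writeCorrelationMatrix <- function(r, path, meta = NULL) {
    ct <- if (!is.null(meta)) setNames(meta$cell_type, meta$sample_id)[colnames(r)]
          else attr(r, "cell_type")
    n <- ncol(r)
    out <- matrix("", n, n, dimnames = dimnames(r))
    for (i in seq_len(n)) for (j in seq_len(i)) {
        cell <- sprintf("%.6g", r[i, j])
        if (!is.null(ct) && i != j && ct[i] == ct[j])
            cell <- paste0(cell, "*")
        out[i, j] <- cell
    }
    df <- data.frame(sample = rownames(out), out, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
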