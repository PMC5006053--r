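#' Accessors for FPKMExperiment and curve objects
#'
#' \code{fpkm} returns the FPKM assay matrix; \code{exprLevel} the
#' quantification level; \code{geneIds} the per-feature gene ids;
#' \code{txLengths} the per-feature lengths (bp); \code{sampleInfo} the
#' sample metadata as a plain data.frame with a \code{sample_id} column.
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @return See each function's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
fpkm <- function(x) SummarizedExperiment::assay(x, "fpkm")

#' @rdname accessors
#' @export
exprLevel <- function(x) x@level

#' @rdname accessors
#' @export
geneIds <- function(x) {
    setNames(as.character(SummarizedExperiment::rowData(x)$gene_id),
             rownames(x))
}

#' @rdname accessors
#' @export
txLengths <- function(x) {
    setNames(as.numeric(SummarizedExperiment::rowData(x)$length), rownames(x))
}

#' @rdname accessors
#' @export
sampleInfo <- function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    data.frame(sample_id = rownames(cd), cd, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Cell-type to group assignment
#'
#' Returns the \code{high}/\code{low}/\code{unassigned} group label per cell
#' type, derived from sample metadata (each cell type's samples must agree).
#'
#' @param meta sample metadata data.frame (or an
#'   \linkS4class{FPKMExperiment}, whose \code{\link{sampleInfo}} is used).
#' @return named character vector, cell type -> group.
#' @export
cellTypeGroups <- function(meta) {
    if (is(meta, "FPKMExperiment")) meta <- sampleInfo(meta)
    sp <- split(as.character(meta$group), as.character(meta$cell_type))
    bad <- names(sp)[vapply(sp, function(g) length(unique(g)) > 1L, logical(1))]
    if (length(bad))
        stop("inconsistent group labels within cell type(s): ",
             paste(bad, collapse = ", "))
    vapply(sp, `[`, character(1), 1L)[unique(as.character(meta$cell_type))]
}

#' Accessors for ThresholdCurveSet
#'
#' \code{thresholds} returns the FPKM grid; \code{curveStatistic} the
#' statistic name; \code{perSampleCurves} the thresholds x samples matrix;
#' \code{cellTypeMeans} / \code{cellTypeSEMs} the per-cell-type replicate
#' summaries; \code{curveCellTypes} the cell type of each sample column.
#'
#' @param x a \linkS4class{ThresholdCurveSet}.
#' @return See each function's description.
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
thresholds <- function(x) x@thresholds

#' @rdname curve-accessors
#' @export
curveStatistic <- function(x) x@statistic

#' @rdname curve-accessors
#' @export
perSampleCurves <- function(x) x@perSample

#' @rdname curve-accessors
#' @export
cellTypeMeans <- function(x) x@ctMean

#' @rdname curve-accessors
#' @export
cellTypeSEMs <- function(x) x@ctSEM

#' @rdname curve-accessors
#' @export
curveCellTypes <- function(x) x@cellType

#' Write threshold curves as tidy TSV
#'
#' Emits one row per (cell type, threshold) with columns \code{cell_type},
#' \code{statistic}, \code{threshold}, \code{mean}, \code{sem}, plus a
#' companion per-sample table when \code{perSamplePath} is given.
#'
#' @param x a \linkS4class{ThresholdCurveSet}.
#' @param path output TSV path for the per-cell-type summary.
#' @param perSamplePath optional output path for per-sample values.
#' @return \code{path}, invisibly.
#' @export
writeCurves <- function(x, path, perSamplePath = NULL) {
    cts <- colnames(x@ctMean)
    df <- data.frame(
        cell_type = rep(cts, each = length(x@thresholds)),
        statistic = x@statistic,
        threshold = rep(x@thresholds, length(cts)),
        mean = as.vector(x@ctMean),
        sem = as.vector(x@ctSEM))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(perSamplePath)) {
        ps <- data.frame(threshold = x@thresholds, x@perSample,
                         check.names = FALSE)
        write.table(ps, perSamplePath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}
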