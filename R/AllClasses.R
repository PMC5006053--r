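#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor quantile sd setNames aov rnorm runif rpois rlnorm
#'   rgamma t.test pnorm plnorm
#' @importFrom utils read.delim write.table head
NULL

#' @importMethodsFrom SummarizedExperiment "assay<-"
NULL

#' FPKMExperiment: an expression matrix of FPKM values
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a features x samples
#' matrix of non-negative FPKM values at either gene or transcript level.
#' Row metadata carries \code{gene_id} and \code{length} (bp; at gene level
#' the maximum isoform length, possibly \code{NA}); column metadata carries
#' \code{cell_type}, \code{replicate} and an optional \code{group} label
#' (\code{"high"}, \code{"low"} or \code{"unassigned"}).
#'
#' @slot level \code{"gene"} or \code{"transcript"}.
#' @seealso \code{\link{FPKMExperiment}} for the constructor,
#'   \code{\link{fpkm}}, \code{\link{geneIds}}, \code{\link{txLengths}},
#'   \code{\link{sampleInfo}} for accessors.
#' @exportClass FPKMExperiment
setClass("FPKMExperiment",
    contains = "SummarizedExperiment",
    representation(level = "character"))

setValidity("FPKMExperiment", function(object) {
    msg <- character()
    if (length(object@level) != 1L || !object@level %in% c("gene", "transcript"))
        msg <- c(msg, "level must be \"gene\" or \"transcript\"")
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay \"fpkm\" is required")
    else {
        v <- SummarizedExperiment::assay(object, "fpkm")
        if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "FPKM values must be finite and non-missing")
        else if (any(v < 0))
            msg <- c(msg, "FPKM values must be non-negative")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("gene_id", "length") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain gene_id and length")
    else {
        if (any(is.na(rd$gene_id)) || any(!nzchar(rd$gene_id)))
            msg <- c(msg, "gene_id must be non-empty")
        len <- rd$length
        if (any(!is.na(len) & len < 1))
            msg <- c(msg, "lengths must be >= 1")
        if (length(object@level) == 1L && object@level == "transcript" &&
            anyNA(len))
            msg <- c(msg, "transcript-level lengths must not be missing")
        if (length(object@level) == 1L && object@level == "gene" &&
            !identical(as.character(rd$gene_id), rownames(object)))
            msg <- c(msg, "at gene level feature ids must equal gene_id")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("cell_type", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain cell_type and replicate")
    else if (anyDuplicated(paste(cd$cell_type, cd$replicate)))
        msg <- c(msg, "(cell_type, replicate) pairs must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an FPKMExperiment
#'
#' @param values numeric matrix of non-negative FPKM values, features in rows
#'   (rownames are feature ids), samples in columns (colnames are sample ids).
#' @param geneId character vector mapping each feature to its gene id. At
#'   gene level this defaults to the rownames.
#' @param length integer vector of feature lengths in bp (transcript level:
#'   required; gene level: maximum isoform length, may be \code{NA}).
#' @param meta data.frame of sample metadata with columns \code{sample_id},
#'   \code{cell_type}, \code{replicate} and optionally \code{group}; matched
#'   to the columns of \code{values} by \code{sample_id}.
#' @param level \code{"gene"} or \code{"transcript"}.
#' @return An \linkS4class{FPKMExperiment}.
#' @examples
#' v <- matrix(c(1, 5, 0, 2), 2, 2,
#'     dimnames = list(c("t1", "t2"), c("S1", "S2")))
#' meta <- data.frame(sample_id = c("S1", "S2"),
#'     cell_type = c("A", "B"), replicate = c(1L, 1L))
#' FPKMExperiment(v, geneId = c("g1", "g1"), length = c(500L, 900L),
#'     meta = meta, level = "transcript")
#' @export
FPKMExperiment <- function(values, geneId = rownames(values), length = NA_integer_,
                           meta, level = c("transcript", "gene")) {
    level <- match.arg(level)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("values must have feature rownames and sample colnames")
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% colnames(meta))
        stop("metadata must contain sample_id")
    idx <- match(colnames(values), meta$sample_id)
    if (anyNA(idx))
        stop("metadata missing for sample(s): ",
             paste(colnames(values)[is.na(idx)], collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
    if (!"group" %in% colnames(meta)) meta$group <- "unassigned"
    meta$group[is.na(meta$group) | !nzchar(meta$group)] <- "unassigned"
    cd <- S4Vectors::DataFrame(cell_type = as.character(meta$cell_type),
                               replicate = as.integer(meta$replicate),
                               group = as.character(meta$group),
                               row.names = colnames(values))
    rd <- S4Vectors::DataFrame(gene_id = as.character(rep_len(geneId, nrow(values))),
                               length = suppressWarnings(as.integer(rep_len(length, nrow(values)))),
                               row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = values), rowData = rd, colData = cd)
    new("FPKMExperiment", se, level = level)
}

#' @describeIn FPKMExperiment display a short summary
#' @param object an \code{FPKMExperiment}
#' @export
setMethod("show", "FPKMExperiment", function(object) {
    cat("FPKMExperiment (", object@level, " level): ",
        nrow(object), " features x ", ncol(object), " samples\n", sep = "")
    cd <- SummarizedExperiment::colData(object)
    cat("cell types:", paste(unique(cd$cell_type), collapse = ", "), "\n")
    callNextMethod()
})

#' A set of per-sample statistic curves over an FPKM threshold grid
#'
#' Holds one statistic (expressed-gene count, genes-per-transcript ratio,
#' mean transcript length or DE count) evaluated per sample on a shared
#' strictly increasing FPKM threshold grid, together with per-cell-type
#' mean and SEM summaries over replicates. Undefined points (e.g. a ratio
#' with no passing transcripts) are flagged as \code{NA}.
#'
#' @slot thresholds strictly increasing positive FPKM thresholds.
#' @slot statistic one of \code{"gene_count"},
#'   \code{"genes_per_transcript_ratio"}, \code{"mean_tx_length"},
#'   \code{"de_count"}.
#' @slot perSample thresholds x samples matrix of statistic values.
#' @slot cellType cell type per sample (named by sample id).
#' @slot ctMean,ctSEM thresholds x cell-types matrices of replicate means
#'   and standard errors (SD with n-1 denominator over sqrt(n)).
#' @exportClass ThresholdCurveSet
setClass("ThresholdCurveSet",
    representation(thresholds = "numeric", statistic = "character",
                   perSample = "matrix", cellType = "character",
                   ctMean = "matrix", ctSEM = "matrix"))

setValidity("ThresholdCurveSet", function(object) {
    msg <- character()
    t <- object@thresholds
    if (any(t <= 0) || is.unsorted(t, strictly = TRUE))
        msg <- c(msg, "thresholds must be strictly increasing and positive")
    if (nrow(object@perSample) != length(t))
        msg <- c(msg, "perSample rows must match grid length")
    if (length(object@cellType) != ncol(object@perSample))
        msg <- c(msg, "cellType must be given per sample")
    if (!object@statistic %in% c("gene_count", "genes_per_transcript_ratio",
                                 "mean_tx_length", "de_count"))
        msg <- c(msg, "unknown statistic")
    if (object@statistic %in% c("gene_count", "de_count")) {
        ps <- object@perSample
        if (ncol(ps) && any(apply(ps, 2, function(x) any(diff(x) > 1e-9, na.rm = TRUE))))
            msg <- c(msg, "count curves must be non-increasing in threshold")
    }
    if (object@statistic == "genes_per_transcript_ratio") {
        r <- object@perSample
        if (any(!is.na(r) & (r <= 0 | r > 1)))
            msg <- c(msg, "ratio values must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ThresholdCurveSet from per-sample curves
#'
#' Cell-type means and SEMs are computed over the replicate samples of each
#' cell type; SEM uses the n-1 standard deviation divided by sqrt(n) and is
#' \code{NA} for a single replicate.
#'
#' @param thresholds increasing positive FPKM grid.
#' @param statistic statistic name (see \linkS4class{ThresholdCurveSet}).
#' @param perSample thresholds x samples numeric matrix with sample colnames.
#' @param cellType character vector of cell types, one per sample column.
#' @return A \linkS4class{ThresholdCurveSet}.
#' @export
ThresholdCurveSet <- function(thresholds, statistic, perSample, cellType) {
    perSample <- as.matrix(perSample)
    cellType <- as.character(cellType)
    names(cellType) <- colnames(perSample)
    cts <- unique(cellType)
    ctMean <- matrix(NA_real_, length(thresholds), length(cts),
                     dimnames = list(NULL, cts))
    ctSEM <- ctMean
    for (ct in cts) {
        cols <- which(cellType == ct)
        sub <- perSample[, cols, drop = FALSE]
        ctMean[, ct] <- rowMeans(sub)
        if (length(cols) > 1L)
            ctSEM[, ct] <- apply(sub, 1, sd) / sqrt(length(cols))
    }
    new("ThresholdCurveSet", thresholds = thresholds, statistic = statistic,
        perSample = perSample, cellType = cellType,
        ctMean = ctMean, ctSEM = ctSEM)
}

#' @describeIn ThresholdCurveSet display a short summary
#' @param object a \code{ThresholdCurveSet}
#' @export
setMethod("show", "ThresholdCurveSet", function(object) {
    cat("ThresholdCurveSet: statistic ", object@statistic, ", ",
        length(object@thresholds), " thresholds (",
        min(object@thresholds), " .. ", max(object@thresholds), " FPKM), ",
        ncol(object@perSample), " samples, ",
        ncol(object@ctMean), " cell types\n", sep = "")
})

#' Per-bin length-expression correlations
#'
#' Pearson correlation between transcript length and FPKM, evaluated per
#' sample within half-open FPKM bins (lo, hi]. Bins with fewer than three
#' transcripts are flagged \code{NA}.
#'
#' @slot binLo,binHi bin edges; bins are non-overlapping and increasing.
#' @slot perSample bins x samples matrix of correlation coefficients.
#' @slot cellType cell type per sample.
#' @slot ctMean,ctSEM per-cell-type summaries over replicates.
#' @exportClass BinnedCorrelation
setClass("BinnedCorrelation",
    representation(binLo = "numeric", binHi = "numeric",
                   perSample = "matrix", cellType = "character",
                   ctMean = "matrix", ctSEM = "matrix"))

setValidity("BinnedCorrelation", function(object) {
    msg <- character()
    if (length(object@binLo) != length(object@binHi))
        msg <- c(msg, "bin edge vectors must match")
    if (any(object@binHi <= object@binLo))
        msg <- c(msg, "bins must have hi > lo")
    if (length(object@binLo) > 1L &&
        any(object@binLo[-1] < object@binHi[-length(object@binHi)] - 1e-12))
        msg <- c(msg, "bins must be non-overlapping and increasing")
    if (length(msg)) msg else TRUE
})

#' @describeIn BinnedCorrelation display a short summary
#' @param object a \code{BinnedCorrelation}
#' @export
setMethod("show", "BinnedCorrelation", function(object) {
    cat("BinnedCorrelation:", length(object@binLo), "FPKM bins,",
        ncol(object@perSample), "samples\n")
})

#' Centroid-linkage dendrogram
#'
#' Agglomerative merge tree produced by \code{\link{centroidLinkageCluster}}.
#' The merge matrix follows \code{\link[stats]{hclust}} conventions (negative
#' entries index leaves, positive entries earlier merges); heights are
#' 1 - similarity at each merge, recorded as computed — centroid linkage can
#' produce non-monotonic height inversions, which are preserved, not
#' silenced. Each merge also stores the centroid (unweighted mean over
#' member leaves) used for subsequent similarity computations.
#'
#' @slot labels leaf (item) identifiers in input order.
#' @slot merge (n-1) x 2 integer matrix of merges.
#' @slot height merge heights (1 - similarity).
#' @slot centroids (n-1) x p matrix of merged-node centroids.
#' @slot similarity similarity used: \code{"uncentered_pearson"} or
#'   \code{"pearson"}.
#' @slot order leaf ordering for display/export.
#' @exportClass CentroidDendrogram
setClass("CentroidDendrogram",
    representation(labels = "character", merge = "matrix", height = "numeric",
                   centroids = "matrix", similarity = "character",
                   order = "integer"))

setValidity("CentroidDendrogram", function(object) {
    n <- length(object@labels)
    msg <- character()
    if (nrow(object@merge) != n - 1L)
        msg <- c(msg, "need exactly n-1 merges for n leaves")
    if (length(object@height) != n - 1L)
        msg <- c(msg, "one height per merge")
    m <- object@merge
    if (nrow(m) == n - 1L && n > 1L) {
        row_of <- row(m)
        if (any(m > 0 & m >= row_of))
            msg <- c(msg, "merges must reference earlier merges only")
        if (anyDuplicated(m[m < 0]) || anyDuplicated(m[m > 0]))
            msg <- c(msg, "each node may be merged only once")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CentroidDendrogram display a short summary
#' @param object a \code{CentroidDendrogram}
#' @export
setMethod("show", "CentroidDendrogram", function(object) {
    n <- length(object@labels)
    inv <- sum(diff(object@height) < -1e-12)
    cat("CentroidDendrogram:", n, "leaves,", object@similarity,
        "similarity\n")
    cat("merge heights:", paste(signif(object@height, 4), collapse = ", "),
        if (inv) sprintf("(%d inversion%s)", inv, if (inv > 1) "s" else ""),
        "\n")
})
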