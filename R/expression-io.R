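## Readers/writers for expression quantification tables (Cufflinks-style
## *.fpkm_tracking and a bit-exact generic TSV dialect), Cuffdiff-style DE
## tables, and sample metadata.

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file does not exist: ", path)
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", quote = "", comment.char = "")
}

.require_cols <- function(df, cols, path) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop("format error in ", path, ": missing required column(s): ",
             paste(miss, collapse = ", "))
}

#' Read an expression quantification table
#'
#' Parses a Cufflinks-style tracking file (\code{tracking_id}, \code{gene_id},
#' \code{length}, plus one \code{<sample>_FPKM} column per sample) or the
#' package's generic TSV dialect (\code{transcript_id}, \code{gene_id},
#' \code{length}, then one plain column per sample) into an
#' \linkS4class{FPKMExperiment}. Rows whose FPKM fields are not numeric are
#' rejected with a warning naming their row numbers (nothing is dropped
#' silently: rows kept + rows rejected = rows read, and the rejected row
#' numbers are attached as \code{attr(x, "rejected_rows")}). Negative FPKM
#' values and duplicated feature ids are errors.
#'
#' @param path path to the table.
#' @param meta sample metadata data.frame (columns \code{sample_id},
#'   \code{cell_type}, \code{replicate}, optional \code{group}) or a path to
#'   a metadata TSV; sample columns are matched to \code{sample_id}.
#' @param dialect \code{"generic_tsv"} or \code{"cufflinks_tracking"}.
#' @param level \code{"transcript"} or \code{"gene"}.
#' @return An \linkS4class{FPKMExperiment}.
#' @seealso \code{\link{writeTrackingTable}}, \code{\link{readSampleMetadata}}
#' @export
readTrackingTable <- function(path, meta,
                              dialect = c("generic_tsv", "cufflinks_tracking"),
                              level = c("transcript", "gene")) {
    dialect <- match.arg(dialect)
    level <- match.arg(level)
    if (is.character(meta)) meta <- readSampleMetadata(meta)
    df <- .read_tsv(path)
    if (dialect == "generic_tsv") {
        .require_cols(df, c("transcript_id", "gene_id", "length"), path)
        id_col <- "transcript_id"
        sample_cols <- setdiff(colnames(df),
                               c("transcript_id", "gene_id", "length"))
        sample_ids <- sample_cols
    } else {
        .require_cols(df, c("tracking_id", "gene_id", "length"), path)
        id_col <- "tracking_id"
        sample_cols <- grep("_FPKM$", colnames(df), value = TRUE)
        if (!length(sample_cols))
            stop("format error in ", path, ": no *_FPKM columns found")
        sample_ids <- sub("_FPKM$", "", sample_cols)
    }
    known <- sample_ids %in% meta$sample_id
    sample_cols <- sample_cols[known]
    sample_ids <- sample_ids[known]
    if (!length(sample_cols))
        stop("format error in ", path,
             ": no sample column matches the metadata sample ids")
    vals <- suppressWarnings(
        vapply(df[sample_cols], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(NULL, sample_ids))
    bad <- which(rowSums(is.na(vals)) > 0L)
    if (length(bad)) {
        warning("rejected ", length(bad), " row(s) with non-numeric FPKM in ",
                path, " (rows ", paste(bad + 1L, collapse = ", "),
                " counting the header)")
        df <- df[-bad, , drop = FALSE]
        vals <- vals[-bad, , drop = FALSE]
    }
    if (any(vals < 0))
        stop("value error in ", path, ": negative FPKM values")
    ids <- df[[id_col]]
    if (anyDuplicated(ids))
        stop("integrity error in ", path, ": duplicated feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    rownames(vals) <- ids
    len <- df$length
    len[len %in% c("-", "")] <- NA
    len <- suppressWarnings(as.numeric(len))
    if (level == "transcript" && anyNA(len))
        stop("format error in ", path, ": missing transcript length(s)")
    out <- FPKMExperiment(vals, geneId = df$gene_id, length = len,
                          meta = meta, level = level)
    attr(out, "rejected_rows") <- if (length(bad)) bad + 1L else integer()
    out
}

#' Write an expression table in the generic TSV dialect
#'
#' Emits tab-separated text with columns \code{transcript_id},
#' \code{gene_id}, \code{length}, then one column per sample, using
#' full-precision (17 significant digit) numeric formatting so that a
#' write/read round trip reproduces every value bit-exactly.
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrackingTable <- function(x, path) {
    v <- fpkm(x)
    rd <- SummarizedExperiment::rowData(x)
    df <- data.frame(transcript_id = rownames(x),
                     gene_id = rd$gene_id,
                     length = rd$length,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (s in colnames(v)) df[[s]] <- sprintf("%.17g", v[, s])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata
#'
#' Metadata TSV with columns \code{sample_id}, \code{cell_type},
#' \code{replicate} and optionally \code{group} (\code{high}/\code{low}/
#' \code{unassigned}).
#'
#' @param path metadata TSV path.
#' @return data.frame of sample metadata.
#' @export
readSampleMetadata <- function(path) {
    df <- .read_tsv(path)
    .require_cols(df, c("sample_id", "cell_type", "replicate"), path)
    df$replicate <- as.integer(df$replicate)
    if (anyDuplicated(paste(df$cell_type, df$replicate)))
        stop("integrity error in ", path,
             ": duplicated (cell_type, replicate) pair")
    if (!"group" %in% colnames(df)) df$group <- "unassigned"
    df
}

#' Write sample metadata
#' @param meta metadata data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Aggregate a transcript-level matrix to gene level
#'
#' Gene FPKM is the sum of its isoforms' FPKM in each sample (Cufflinks'
#' gene abundance semantics); gene length is recorded as the maximum isoform
#' length. Output rows are ordered by first appearance of each gene in the
#' input, and the result is invariant to permutations of the input rows up
#' to that ordering.
#'
#' @param tx a transcript-level \linkS4class{FPKMExperiment}.
#' @return A gene-level \linkS4class{FPKMExperiment}.
#' @export
geneLevelFromTranscripts <- function(tx) {
    stopifnot(is(tx, "FPKMExperiment"))
    if (exprLevel(tx) != "transcript")
        stop("input must be a transcript-level matrix")
    g <- geneIds(tx)
    genes <- unique(g)
    gf <- factor(g, levels = genes)
    v <- rowsum(fpkm(tx), gf, reorder = FALSE)
    rownames(v) <- genes
    len <- as.integer(tapply(txLengths(tx), gf, max))
    FPKMExperiment(v, geneId = genes, length = len,
                   meta = sampleInfo(tx), level = "gene")
}

#' Read a differential-expression table
#'
#' Parses a Cuffdiff \code{gene_exp.diff}-style table (columns \code{gene},
#' \code{value_1}, \code{value_2}, \code{log2(fold_change)}, \code{q_value},
#' \code{status}) or a generic TSV (\code{gene_id}, \code{fpkm_a},
#' \code{fpkm_b}, \code{log2_fold}, \code{q_value}, \code{status}) into a
#' data.frame of per-gene two-condition records. \code{log2_fold} is the
#' log2 ratio of condition b over condition a; infinite fold changes (one
#' condition at zero) are preserved as signed infinities (\code{inf},
#' \code{-inf} and \code{1.79769e+308} sentinels are recognised).
#'
#' @param path path to the table.
#' @param dialect \code{"generic_tsv"} or \code{"cuffdiff_diff"}.
#' @return data.frame with columns \code{gene_id}, \code{fpkm_a},
#'   \code{fpkm_b}, \code{log2_fold}, \code{q_value}, \code{status}
#'   (\code{"tested"}/\code{"not_tested"}).
#' @export
readDETable <- function(path, dialect = c("generic_tsv", "cuffdiff_diff")) {
    dialect <- match.arg(dialect)
    df <- .read_tsv(path)
    if (dialect == "cuffdiff_diff") {
        gene_col <- if ("gene" %in% colnames(df)) "gene" else "gene_id"
        .require_cols(df, c(gene_col, "value_1", "value_2",
                            "log2(fold_change)", "q_value", "status"), path)
        out <- data.frame(gene_id = df[[gene_col]],
                          fpkm_a = df$value_1, fpkm_b = df$value_2,
                          log2_fold = df[["log2(fold_change)"]],
                          q_value = df$q_value,
                          status = ifelse(df$status == "OK",
                                          "tested", "not_tested"),
                          stringsAsFactors = FALSE)
    } else {
        .require_cols(df, c("gene_id", "fpkm_a", "fpkm_b", "log2_fold",
                            "q_value", "status"), path)
        out <- df[c("gene_id", "fpkm_a", "fpkm_b", "log2_fold",
                    "q_value", "status")]
    }
    .num <- function(x, col) {
        x <- tolower(x)
        x[x %in% c("inf", "+inf", "infinity")] <- "Inf"
        x[x %in% c("-inf", "-infinity")] <- "-Inf"
        v <- suppressWarnings(as.numeric(x))
        bad <- which(is.na(v) & !is.na(x))
        if (length(bad))
            stop("format error in ", path, ": malformed numeric field ", col,
                 " at row(s) ", paste(bad + 1L, collapse = ", "),
                 " counting the header")
        ## Cuffdiff prints DBL_MAX for infinite fold changes
        v[abs(v) >= 1.7976e308] <- sign(v[abs(v) >= 1.7976e308]) * Inf
        v
    }
    out$fpkm_a <- .num(out$fpkm_a, "fpkm_a")
    out$fpkm_b <- .num(out$fpkm_b, "fpkm_b")
    out$log2_fold <- .num(out$log2_fold, "log2_fold")
    out$q_value <- .num(out$q_value, "q_value")
    if (any(out$fpkm_a < 0) || any(out$fpkm_b < 0))
        stop("value error in ", path, ": negative FPKM")
    if (any(out$q_value < 0 | out$q_value > 1))
        stop("value error in ", path, ": q_value outside [0, 1]")
    chk <- out$fpkm_a > 0 & out$fpkm_b > 0
    dev <- abs(out$log2_fold[chk] - log2(out$fpkm_b[chk] / out$fpkm_a[chk]))
    if (any(dev > 1e-6 + 1e-9 * abs(out$log2_fold[chk])))
        warning("log2_fold inconsistent with condition FPKMs in ",
                sum(dev > 1e-6), " row(s)")
    out
}

#' Write a differential-expression table in the generic TSV dialect
#' @param de DE data.frame as returned by \code{\link{readDETable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDETable <- function(de, path) {
    out <- de
    for (col in c("fpkm_a", "fpkm_b", "log2_fold", "q_value"))
        out[[col]] <- sprintf("%.17g", de[[col]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
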