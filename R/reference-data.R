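#' Bundled reference replicate-correlation matrix
#'
#' Loads the package's example correlation matrix: pairwise Pearson
#' correlations of gene expression profiles for eight purified mouse cell
#' types (retinal ganglion cells, cortical neurons, astrocytes,
#' oligodendrocytes, microglia, endothelial cells, erythroid-committed
#' precursors and megakaryocyte-erythroid progenitors), two biological
#' replicates each. Useful as a realistic input for
#' \code{\link{meanWithinCellTypeCorrelation}}: replicates are highly
#' correlated within, but not between, cell types.
#'
#' @return list with \code{r} (16 x 16 symmetric correlation matrix) and
#'   \code{meta} (sample metadata data.frame).
#' @examples
#' ref <- referenceCorrelationMatrix()
#' meanWithinCellTypeCorrelation(ref$r, ref$meta)$mean
#' @export
referenceCorrelationMatrix <- function() {
    path <- system.file("extdata", "celltype_replicate_correlations.tsv",
                        package = "txglobals", mustWork = TRUE)
    df <- read.delim(path, check.names = FALSE)
    r <- as.matrix(df[, -1])
    rownames(r) <- df$sample_id
    meta <- readSampleMetadata(
        system.file("extdata", "celltype_samples.tsv",
                    package = "txglobals", mustWork = TRUE))
    list(r = r, meta = meta)
}
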