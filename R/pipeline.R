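## End-to-end orchestration: QC, threshold curves + clustering + group
## test, and DE summaries, each writing TSV/Newick/YAML outputs plus a
## manifest (config, seed, input checksums, versions) for reproducibility.

#' Build and validate a run configuration
#'
#' @param expression path to a transcript-level expression table, or an
#'   \linkS4class{FPKMExperiment} (gene tables are derived by isoform
#'   summation).
#' @param metadata path to a sample-metadata TSV, or a data.frame (optional
#'   when \code{expression} is an \code{FPKMExperiment}).
#' @param deTable optional path to a DE table, or a DE data.frame.
#' @param dialect expression table dialect (see
#'   \code{\link{readTrackingTable}}).
#' @param deDialect DE table dialect (see \code{\link{readDETable}}).
#' @param outDir output directory.
#' @param grid FPKM threshold grid.
#' @param bins FPKM bins for length-expression correlation.
#' @param normalization \code{"none"} or \code{"upper_quartile"}.
#' @param transform transform for correlations/profile clustering
#'   (\code{"log2p1"} or \code{"none"}).
#' @param minFpkm expression filter for profile clustering.
#' @param deCriteria list of DE filter settings (\code{histogram}:
#'   minFpkm/minFold/maxQ, \code{counts}: minFold/maxQ, \code{length}:
#'   minFpkm/minFold/maxQ/relTol).
#' @param nPerm permutations for the group curve test.
#' @param seed integer seed recorded in the manifest and used for the
#'   permutation draw.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(expression, metadata = NULL, deTable = NULL,
                      dialect = "generic_tsv", deDialect = "generic_tsv",
                      outDir = "txglobals_out",
                      grid = defaultThresholdGrid(),
                      bins = defaultFpkmBins(),
                      normalization = c("none", "upper_quartile"),
                      transform = c("log2p1", "none"),
                      minFpkm = 1,
                      deCriteria = list(
                          histogram = list(minFpkm = 5, minFold = 3, maxQ = 0.05),
                          counts = list(minFold = 3, maxQ = 0.05),
                          length = list(minFpkm = 1, minFold = 2, maxQ = 0.05,
                                        relTol = 0.01)),
                      nPerm = 999, seed = 1) {
    normalization <- match.arg(normalization)
    transform <- match.arg(transform)
    for (p in c(if (is.character(expression)) expression,
                if (is.character(metadata)) metadata,
                if (is.character(deTable)) deTable))
        if (!file.exists(p)) stop("config error: path does not exist: ", p)
    structure(list(expression = expression, metadata = metadata,
                   deTable = deTable, dialect = dialect,
                   deDialect = deDialect, outDir = outDir, grid = grid,
                   bins = bins, normalization = normalization,
                   transform = transform, minFpkm = minFpkm,
                   deCriteria = deCriteria, nPerm = nPerm,
                   seed = as.integer(seed)),
              class = "runConfig")
}

.load_expression <- function(cfg) {
    if (is(cfg$expression, "FPKMExperiment")) {
        tx <- cfg$expression
    } else {
        meta <- if (is.data.frame(cfg$metadata)) cfg$metadata
                else readSampleMetadata(cfg$metadata)
        tx <- readTrackingTable(cfg$expression, meta, dialect = cfg$dialect,
                                level = "transcript")
    }
    if (cfg$normalization == "upper_quartile")
        tx <- upperQuartileNormalize(tx)
    tx
}

.load_de <- function(cfg) {
    if (is.null(cfg$deTable)) stop("config error: no DE table provided")
    if (is.data.frame(cfg$deTable)) cfg$deTable
    else readDETable(cfg$deTable, dialect = cfg$deDialect)
}

.write_manifest <- function(cfg, outDir, step, extra = list()) {
    paths <- Filter(is.character,
                    list(expression = cfg$expression,
                         metadata = cfg$metadata, deTable = cfg$deTable))
    checksums <- lapply(paths, function(p) unname(tools::md5sum(p)))
    cfg_flat <- cfg
    cfg_flat$expression <- if (is.character(cfg$expression)) cfg$expression
                           else "<in-memory FPKMExperiment>"
    cfg_flat$metadata <- if (is.character(cfg$metadata)) cfg$metadata
                         else if (is.null(cfg$metadata)) NULL
                         else "<in-memory data.frame>"
    cfg_flat$deTable <- if (is.character(cfg$deTable)) cfg$deTable
                        else if (is.null(cfg$deTable)) NULL
                        else "<in-memory data.frame>"
    cfg_flat$bins <- apply(cfg$bins, 1, function(b)
        sprintf("(%g, %g]", b[1], b[2]))
    man <- c(list(step = step, seed = cfg$seed,
                  package_version = as.character(utils::packageVersion("txglobals")),
                  r_version = as.character(getRversion()),
                  input_checksums = checksums,
                  config = cfg_flat[setdiff(names(cfg_flat), "deCriteria")],
                  de_criteria = cfg$deCriteria),
             extra)
    yaml::write_yaml(man, file.path(outDir, paste0("manifest_", step, ".yaml")))
}

#' Run replicate-correlation quality control
#'
#' Computes the sample-by-sample Pearson correlation matrix (on the
#' configured transform of gene-level FPKM) and the mean within-cell-type
#' replicate correlation; writes the lower-triangle matrix TSV, a summary
#' YAML and a manifest.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with \code{correlation} (matrix) and \code{within}
#'   (within-type summary), invisibly.
#' @export
runQC <- function(cfg) {
    tx <- .load_expression(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    m <- geneLevelFromTranscripts(tx)
    r <- replicateCorrelationMatrix(m, transform = cfg$transform)
    within <- meanWithinCellTypeCorrelation(r, sampleInfo(m))
    writeCorrelationMatrix(r, file.path(cfg$outDir, "correlation_matrix.tsv"))
    yaml::write_yaml(list(mean_within_cell_type = within$mean,
                          per_cell_type = as.list(within$per_cell_type)),
                     file.path(cfg$outDir, "within_type_correlation.yaml"))
    .write_manifest(cfg, cfg$outDir, "qc")
    invisible(list(correlation = r, within = within))
}

#' Run the threshold-curve analyses
#'
#' Emits expressed-gene count, mean-transcript-length and
#' genes-per-transcript ratio curves (tidy TSV), the length-expression
#' binned correlations, the cell-type dendrogram on count curves (Newick +
#' k = 2 cut TSV; skipped with a warning for fewer than 2 cell types), the
#' high/low group ratio curve and the permutation group test (when groups
#' are assigned), plus a seed-stamped manifest.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list of computed objects, invisibly.
#' @export
runCurves <- function(cfg) {
    tx <- .load_expression(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    gene <- geneLevelFromTranscripts(tx)
    counts <- expressedGeneCounts(gene, cfg$grid)
    ratio <- transcriptsPerGeneRatio(tx, cfg$grid)
    lens <- meanTranscriptLengthCurve(tx, cfg$grid)
    lcor <- lengthExpressionCorrelation(tx, cfg$bins)
    writeCurves(counts, file.path(cfg$outDir, "gene_counts.tsv"),
                file.path(cfg$outDir, "gene_counts_per_sample.tsv"))
    writeCurves(ratio, file.path(cfg$outDir, "genes_per_transcript_ratio.tsv"))
    writeCurves(lens, file.path(cfg$outDir, "mean_tx_length.tsv"))
    lc <- data.frame(bin_lo = lcor@binLo, bin_hi = lcor@binHi,
                     lcor@perSample, check.names = FALSE)
    write.table(lc, file.path(cfg$outDir, "length_expression_correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(counts = counts, ratio = ratio, lengths = lens,
                length_correlation = lcor)
    n_ct <- ncol(cellTypeMeans(counts))
    if (n_ct >= 2L) {
        dend <- clusterThresholdCurves(counts)
        exportNewick(dend, file.path(cfg$outDir, "celltype_dendrogram.nwk"))
        cut2 <- cutK(dend, 2)
        write.table(data.frame(cell_type = names(cut2), cluster = cut2),
                    file.path(cfg$outDir, "celltype_clusters_k2.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$dendrogram <- dend
        out$clusters_k2 <- cut2
    } else {
        warning("single cell type: clustering skipped")
    }
    groups <- cellTypeGroups(sampleInfo(tx))
    if (all(c("high", "low") %in% groups)) {
        grat <- groupRatioCurve(counts, groups)
        write.table(data.frame(threshold = cfg$grid, ratio = unname(grat)),
                    file.path(cfg$outDir, "group_ratio_curve.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        test <- curveGroupTest(counts, groups, method = "permutation",
                               nPerm = cfg$nPerm, seed = cfg$seed)
        test_f <- curveGroupTest(counts, groups, method = "rm_anova_f")
        yaml::write_yaml(list(permutation = test, rm_anova = test_f),
                         file.path(cfg$outDir, "group_test.yaml"))
        out$group_ratio <- grat
        out$group_test <- test
        out$group_test_f <- test_f
    }
    .write_manifest(cfg, cfg$outDir, "curves")
    invisible(out)
}

#' Run the DE summary analyses
#'
#' Emits the fold-change histogram, the enriched-DE-count curves with their
#' high/low ratio, and the DE vs not-DE transcript-length comparison, plus
#' a manifest. An empty DE table yields zero-count outputs with a warning.
#'
#' @param cfg a \code{\link{runConfig}} with a DE table.
#' @return list of computed objects, invisibly.
#' @export
runDESummary <- function(cfg) {
    tx <- .load_expression(cfg)
    de <- .load_de(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    if (!nrow(de)) warning("empty DE table: outputs will be zero counts")
    crit <- cfg$deCriteria
    hist <- do.call(deFoldChangeHistogram, c(list(de = de), crit$histogram))
    write.table(hist, file.path(cfg$outDir, "de_fold_change_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gene <- geneLevelFromTranscripts(tx)
    out <- list(histogram = hist)
    groups <- cellTypeGroups(sampleInfo(tx))
    if (all(c("high", "low") %in% groups) && nrow(de)) {
        cnts <- do.call(enrichedDECountsByThreshold,
                        c(list(de = de, m = gene, grid = cfg$grid),
                          crit$counts))
        ps <- perSampleCurves(cnts$curves)
        write.table(data.frame(threshold = cfg$grid, ps,
                               ratio = unname(cnts$ratio),
                               check.names = FALSE),
                    file.path(cfg$outDir, "enriched_de_counts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$de_counts <- cnts
    }
    lenc <- try(do.call(deLengthComparison,
                        c(list(de = de, tx = tx), crit$length)), silent = TRUE)
    if (!inherits(lenc, "try-error")) {
        yaml::write_yaml(lenc, file.path(cfg$outDir, "de_length_comparison.yaml"))
        out$length_comparison <- lenc
    } else {
        warning("DE length comparison skipped: ",
                attr(lenc, "condition")$message)
    }
    .write_manifest(cfg, cfg$outDir, "de_summary")
    invisible(out)
}

#' Run the full pipeline
#'
#' \code{\link{runQC}}, \code{\link{runCurves}} and (when a DE table is
#' configured) \code{\link{runDESummary}}, in order.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with the three step results, invisibly.
#' @export
runAll <- function(cfg) {
    out <- list(qc = runQC(cfg), curves = runCurves(cfg))
    if (!is.null(cfg$deTable)) out$de_summary <- runDESummary(cfg)
    invisible(out)
}
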