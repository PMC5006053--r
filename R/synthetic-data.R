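## Calibrated generator of multi-cell-type transcript-level FPKM tables,
## metadata and DE tables with the statistical structure the analysis
## assumes: a two-component log-normal expression mixture with a target
## fraction of highly expressed genes per cell type, lineage-shared
## high-expression programs, Poisson isoform counts with Dirichlet
## splitting of gene FPKM, and multiplicative log-normal replicate noise.

#' Specify one synthetic cell type
#'
#' @param name cell type name.
#' @param pHigh target fraction of genes with FPKM >= the generator's high
#'   cutoff (default 20 FPKM) in this cell type.
#' @param isoformMean mean number of expressed isoforms per expressed gene
#'   (>= 1); isoform counts are 1 + Poisson(isoformMean - 1).
#' @param lineage lineage label; cell types sharing a lineage share a
#'   fraction rho of their highly expressed gene identities, giving the
#'   correlated expression programs real developmental lineages show.
#' @param group optional \code{"high"}/\code{"low"} group label.
#' @param highScale multiplicative shift of this cell type's high
#'   expression component (its high genes centre on highScale times the
#'   config's high-component median); the mixing weight is recalibrated so
#'   the pHigh target still holds. Values above 1 plant asymmetric
#'   enrichment: the cell type's highly expressed genes sit further above
#'   any fixed FPKM threshold.
#' @return list of class \code{cellTypeSpec}.
#' @export
cellTypeSpec <- function(name, pHigh, isoformMean = 1.6, lineage = name,
                         group = "unassigned", highScale = 1) {
    if (pHigh < 0 || pHigh > 1) stop("pHigh must lie in [0, 1]")
    if (isoformMean < 1) stop("isoformMean must be >= 1")
    if (highScale <= 0) stop("highScale must be positive")
    structure(list(name = name, pHigh = pHigh, isoformMean = isoformMean,
                   lineage = lineage, group = group, highScale = highScale),
              class = "cellTypeSpec")
}

#' Generator configuration
#'
#' Defines the synthetic study design. Gene mean FPKMs follow a mixture of
#' two log-normals — a low component (muLo, sigmaLo) and a high component
#' (muHi, sigmaHi) — whose mixing weight is calibrated per cell type so
#' that the expected fraction of genes at or above \code{highCutoff}
#' equals that cell type's \code{pHigh} target. Replicates of a cell type
#' share gene means and isoform splits and differ only by per-gene
#' multiplicative log-normal noise of scale \code{sigmaRep}. Transcript
#' lengths are log-normal, bounded to [200, 100000] bp. Each gene's FPKM is
#' split over its expressed isoforms by a symmetric Dirichlet with
#' concentration \code{alphaSplit}.
#'
#' @param cellTypes list of \code{\link{cellTypeSpec}}s.
#' @param nGenes genes in the shared annotation (one universe of features
#'   across all cell types, as a cross-sample matrix requires).
#' @param replicates biological replicates per cell type.
#' @param highCutoff FPKM cutoff defining "highly expressed" (default 20).
#' @param muLo,sigmaLo log-scale location/scale of the low component.
#' @param muHi,sigmaHi log-scale location/scale of the high component.
#' @param sigmaRep replicate noise SD on the log scale (0.25 puts
#'   within-cell-type replicate correlations in the ~0.95 regime).
#' @param rho fraction of a cell type's high-gene identities drawn from its
#'   lineage's shared program, in [0, 1].
#' @param muLen,sigmaLen log-scale location/scale of transcript lengths.
#' @param alphaSplit symmetric Dirichlet concentration for isoform splits.
#' @return list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(cellTypes, nGenes = 5000, replicates = 2,
                            highCutoff = 20,
                            muLo = log(1.5), sigmaLo = 1.0,
                            muHi = log(60), sigmaHi = 0.8,
                            sigmaRep = 0.25, rho = 0.6,
                            muLen = log(2000), sigmaLen = 0.7,
                            alphaSplit = 1.0) {
    bad <- character()
    if (!length(cellTypes)) bad <- c(bad, "cellTypes")
    if (nGenes < 1) bad <- c(bad, "nGenes")
    if (replicates < 1) bad <- c(bad, "replicates")
    if (highCutoff <= 0) bad <- c(bad, "highCutoff")
    for (s in c("sigmaLo", "sigmaHi", "sigmaRep", "sigmaLen"))
        if (get(s) <= 0) bad <- c(bad, s)
    if (rho < 0 || rho > 1) bad <- c(bad, "rho")
    if (alphaSplit <= 0) bad <- c(bad, "alphaSplit")
    if (length(bad))
        stop("invalid generator config field(s): ", paste(bad, collapse = ", "))
    names(cellTypes) <- vapply(cellTypes, `[[`, character(1), "name")
    structure(list(cellTypes = cellTypes, nGenes = as.integer(nGenes),
                   replicates = as.integer(replicates),
                   highCutoff = highCutoff,
                   muLo = muLo, sigmaLo = sigmaLo,
                   muHi = muHi, sigmaHi = sigmaHi,
                   sigmaRep = sigmaRep, rho = rho,
                   muLen = muLen, sigmaLen = sigmaLen,
                   alphaSplit = alphaSplit),
              class = "generatorConfig")
}

#' Standard two-group, three-lineage study design
#'
#' Eight cell types with two replicates each, split into a low group (four
#' cell types at \code{pLow} target fraction of highly expressed genes) and
#' a high group (four at \code{pHigh}), spread over three developmental
#' lineages. When \code{couple} is \code{TRUE}, each cell type's mean
#' expressed isoform count rises linearly with its pHigh target
#' (isoformMean = 1 + 6 pHigh), planting the association between splicing
#' activity and the proportion of highly expressed genes as a recoverable
#' effect rather than a generator artifact.
#'
#' @param pLow,pHigh group targets for the fraction of genes >= 20 FPKM.
#' @param couple couple isoformMean to the pHigh target.
#' @param gradient when \code{TRUE}, spread the per-cell-type targets over
#'   \code{seq(pLow, pHigh, length.out = 8)} instead of two flat groups,
#'   giving well-separated across-cell-type ranks.
#' @param highScaleHigh \code{highScale} applied to the high group's cell
#'   types (default 1; values above 1 plant asymmetric enrichment for the
#'   DE summary analyses).
#' @param lineages lineage label per cell type (length 8). The default
#'   spreads the eight cell types over three lineages crossing the group
#'   boundary; passing the group labels themselves gives two
#'   group-coherent expression programs instead.
#' @param ... passed on to \code{\link{generatorConfig}}.
#' @return A \code{generatorConfig}.
#' @export
twoGroupConfig <- function(pLow = 0.10, pHigh = 0.15, couple = FALSE,
                           gradient = FALSE, highScaleHigh = 1,
                           lineages = c("neural", "neural", "neural", "neural",
                                        "myeloid", "myeloid",
                                        "erythroid", "erythroid"), ...) {
    stopifnot(length(lineages) == 8L)
    groups <- c("low", "low", "low", "low", "high", "high", "high", "high")
    p <- if (gradient) seq(pLow, pHigh, length.out = 8)
         else rep(c(pLow, pHigh), each = 4)
    specs <- lapply(seq_len(8), function(i)
        cellTypeSpec(sprintf("CT%d", i), pHigh = p[i],
                     isoformMean = if (couple) 1 + 6 * p[i] else 1.6,
                     lineage = lineages[i], group = groups[i],
                     highScale = if (groups[i] == "high") highScaleHigh else 1))
    generatorConfig(specs, ...)
}

## mixing weight giving expected fraction >= cutoff equal to the target
.calibrated_weight <- function(sp, cfg) {
    mu_hi <- cfg$muHi + log(sp$highScale)
    p_lo <- 1 - plnorm(cfg$highCutoff, cfg$muLo, cfg$sigmaLo)
    p_hi <- 1 - plnorm(cfg$highCutoff, mu_hi, cfg$sigmaHi)
    w <- (sp$pHigh - p_lo) / (p_hi - p_lo)
    if (w < 0 || w > 1)
        stop("pHigh target ", sp$pHigh, " is outside the range attainable ",
             "by the mixture components [", signif(p_lo, 3), ", ",
             signif(p_hi, 3), "]")
    w
}

#' Generate a synthetic multi-cell-type dataset
#'
#' Deterministic under a fixed seed (fixed generation order). Replicates of
#' a cell type share gene means and isoform splits and differ only by
#' replicate noise; lineage-mates share a fraction rho of their
#' high-expression gene identities. The realized per-cell-type fraction of
#' genes at or above the high cutoff tracks the pHigh target to within
#' about +/- 0.02 at 5000 or more genes.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param seed integer seed.
#' @return list with \code{tx} (transcript-level
#'   \linkS4class{FPKMExperiment}), \code{meta} (sample metadata
#'   data.frame) and \code{truth} (ground truth: per-cell-type realized
#'   pHigh and realized mean isoforms per expressed gene, group labels, the
#'   true per-gene mean FPKM matrix, true group means and per-gene DE
#'   status between groups at fold >= 2).
#' @export
generateDataset <- function(cfg, seed) {
    stopifnot(inherits(cfg, "generatorConfig"))
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

    nG <- cfg$nGenes
    specs <- cfg$cellTypes
    cts <- names(specs)
    gene_ids <- sprintf("G%05d", seq_len(nG))

    ## lineage-shared high-program orderings: one random priority per lineage
    lineages <- unique(vapply(specs, `[[`, character(1), "lineage"))
    lineage_prio <- lapply(lineages, function(l) sample.int(nG))
    names(lineage_prio) <- lineages

    true_mean <- matrix(0, nG, length(cts), dimnames = list(gene_ids, cts))
    iso_k <- matrix(0L, nG, length(cts), dimnames = list(gene_ids, cts))
    high_flag <- matrix(FALSE, nG, length(cts), dimnames = list(gene_ids, cts))
    for (ct in cts) {
        sp <- specs[[ct]]
        w <- .calibrated_weight(sp, cfg)
        n_hi <- round(w * nG)
        n_shared <- round(cfg$rho * n_hi)
        shared <- head(lineage_prio[[sp$lineage]], n_shared)
        rest <- setdiff(sample.int(nG), shared)
        hi_idx <- c(shared, head(rest, n_hi - n_shared))
        hi <- logical(nG); hi[hi_idx] <- TRUE
        high_flag[, ct] <- hi
        m <- numeric(nG)
        m[hi] <- rlnorm(sum(hi), cfg$muHi + log(sp$highScale), cfg$sigmaHi)
        m[!hi] <- rlnorm(sum(!hi), cfg$muLo, cfg$sigmaLo)
        true_mean[, ct] <- m
        iso_k[, ct] <- 1L + rpois(nG, sp$isoformMean - 1)
    }

    ## shared annotation: each gene carries max-over-cell-types isoforms
    K <- apply(iso_k, 1, max)
    tx_gene <- rep(seq_len(nG), K)
    tx_rank <- sequence(K)
    tx_ids <- sprintf("%s.%d", gene_ids[tx_gene], tx_rank)
    tx_len <- pmin(pmax(round(rlnorm(length(tx_ids), cfg$muLen, cfg$sigmaLen)),
                        200), 100000)

    ## per cell type: Dirichlet split of gene FPKM over its expressed isoforms
    tx_true <- matrix(0, length(tx_ids), length(cts),
                      dimnames = list(tx_ids, cts))
    for (ct in cts) {
        k <- iso_k[, ct]
        gam <- rgamma(sum(k), shape = cfg$alphaSplit)
        gidx <- rep(seq_len(nG), k)
        prop <- gam / rep(rowsum(gam, gidx)[, 1], k)
        expressed <- tx_rank <= k[tx_gene]
        tx_true[expressed, ct] <- true_mean[gidx, ct] * prop
    }

    ## replicates: per-gene multiplicative log-normal noise
    reps <- cfg$replicates
    sample_ids <- as.vector(t(outer(cts, seq_len(reps),
                                    function(a, b) paste0(a, "_r", b))))
    vals <- matrix(0, length(tx_ids), length(sample_ids),
                   dimnames = list(tx_ids, sample_ids))
    for (ct in cts) for (r in seq_len(reps)) {
        noise <- exp(rnorm(nG, 0, cfg$sigmaRep))
        vals[, paste0(ct, "_r", r)] <- tx_true[, ct] * noise[tx_gene]
    }

    meta <- data.frame(
        sample_id = sample_ids,
        cell_type = rep(cts, each = reps),
        replicate = rep(seq_len(reps), length(cts)),
        group = rep(vapply(specs, `[[`, character(1), "group"), each = reps),
        stringsAsFactors = FALSE)
    tx <- FPKMExperiment(vals, geneId = gene_ids[tx_gene], length = tx_len,
                         meta = meta, level = "transcript")

    ## realized quantities, recomputable from the emitted tables
    gene_rep <- rowsum(vals, factor(gene_ids[tx_gene], levels = gene_ids),
                       reorder = FALSE)
    realized_p <- vapply(cts, function(ct) {
        cols <- paste0(ct, "_r", seq_len(reps))
        mean(rowMeans(gene_rep[, cols, drop = FALSE]) >= cfg$highCutoff)
    }, numeric(1))
    realized_iso <- colMeans(iso_k)
    groups <- vapply(specs, `[[`, character(1), "group")
    truth <- list(
        cell_types = cts,
        groups = groups,
        realized_p_high = realized_p,
        realized_isoforms_per_gene = realized_iso,
        target_p_high = vapply(specs, `[[`, numeric(1), "pHigh"),
        target_isoform_mean = vapply(specs, `[[`, numeric(1), "isoformMean"),
        true_gene_mean = true_mean,
        high_cutoff = cfg$highCutoff,
        seed = seed)
    if (all(c("high", "low") %in% groups)) {
        gm_lo <- rowMeans(true_mean[, groups == "low", drop = FALSE])
        gm_hi <- rowMeans(true_mean[, groups == "high", drop = FALSE])
        truth$group_mean_low <- gm_lo
        truth$group_mean_high <- gm_hi
        truth$de_status <- pmax(gm_hi / gm_lo, gm_lo / gm_hi) >= 2
    }
    list(tx = tx, meta = meta, truth = truth)
}

#' Generate a DE table from ground truth
#'
#' Per gene: the two condition means are the generator's true per-cell-type
#' gene means averaged within the low (condition a) and high (condition b)
#' groups, \code{log2_fold} is log2(b/a), and the q-value is planted —
#' uniform on [0, 0.01] for genes that are DE in truth (true group-mean
#' fold >= 2) and uniform on [0.05, 1] otherwise. q-values are planted,
#' not computed from a test: the downstream consumers only need calibrated
#' filter behaviour, not a differential-expression model.
#'
#' @param truth ground-truth list from \code{\link{generateDataset}} (must
#'   carry group assignments).
#' @param seed integer seed for the planted q-values.
#' @return DE data.frame (see \code{\link{readDETable}} for columns).
#' @export
generateDETable <- function(truth, seed) {
    if (is.null(truth$de_status))
        stop("ground truth has no group assignment; use a two-group config")
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed, kind = "Mersenne-Twister")
    n <- length(truth$de_status)
    q <- runif(n, 0.05, 1)
    q[truth$de_status] <- runif(sum(truth$de_status), 0, 0.01)
    data.frame(gene_id = names(truth$group_mean_low),
               fpkm_a = unname(truth$group_mean_low),
               fpkm_b = unname(truth$group_mean_high),
               log2_fold = unname(log2(truth$group_mean_high /
                                       truth$group_mean_low)),
               q_value = q,
               status = "tested",
               stringsAsFactors = FALSE)
}

#' Write a generated dataset to files
#'
#' Emits the transcript table in the generic TSV dialect, a
#' Cufflinks-tracking-style copy, the metadata TSV, and the ground truth as
#' YAML (matrices flattened to per-cell-type lists).
#'
#' @param dataset list from \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "isoforms.tsv")
    writeTrackingTable(dataset$tx, p1)
    p2 <- file.path(dir, "isoforms.fpkm_tracking")
    v <- fpkm(dataset$tx)
    rd <- SummarizedExperiment::rowData(dataset$tx)
    df <- data.frame(tracking_id = rownames(dataset$tx),
                     gene_id = rd$gene_id, length = rd$length,
                     check.names = FALSE)
    for (s in colnames(v)) df[[paste0(s, "_FPKM")]] <- sprintf("%.17g", v[, s])
    write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(dir, "samples.tsv")
    writeSampleMetadata(dataset$meta, p3)
    p4 <- file.path(dir, "truth.yaml")
    tr <- dataset$truth
    tr$true_gene_mean <- lapply(as.data.frame(tr$true_gene_mean), identity)
    tr$de_status <- as.logical(tr$de_status)
    yaml::write_yaml(tr, p4, precision = 15)
    invisible(c(p1, p2, p3, p4))
}
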