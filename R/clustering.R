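## Agglomerative clustering with uncentered Pearson similarity and centroid
## linkage (Gene Cluster 3.0 semantics), plus k-cut and export utilities.

#' Uncentered Pearson similarity
#'
#' Sum(x*y) / sqrt(Sum(x^2) * Sum(y^2)): the Pearson formula without mean
#' centering, i.e. the cosine of the angle between the vectors about the
#' origin. Scale-free but origin-sensitive; lies in [-1, 1].
#'
#' @param x,y equal-length numeric vectors; neither may be all-zero.
#' @return similarity in [-1, 1].
#' @export
uncenteredPearson <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    sx <- sum(x^2); sy <- sum(y^2)
    if (sx == 0 || sy == 0)
        stop("undefined similarity: all-zero vector")
    sum(x * y) / sqrt(sx * sy)
}

.sim_fun <- function(similarity) {
    switch(similarity,
        uncentered_pearson = uncenteredPearson,
        pearson = function(x, y) {
            if (sd(x) == 0 || sd(y) == 0)
                stop("undefined similarity: zero-variance profile")
            cor(x, y)
        },
        stop("unknown similarity: ", similarity))
}

#' Hierarchical clustering with centroid linkage
#'
#' Agglomerative clustering of item profiles (matrix rows): at each step the
#' pair of active clusters with maximal similarity (minimal 1 - similarity
#' distance) is merged; the merged cluster's profile is the unweighted
#' arithmetic mean of its member leaves' profiles, and similarities to the
#' new cluster are recomputed against that centroid. Ties on similarity are
#' broken deterministically by the lexicographically smallest pair of
#' cluster creation indices. Merge heights (1 - similarity) are recorded as
#' computed; centroid linkage permits non-monotonic inversions and these
#' are preserved in the output.
#'
#' @param items numeric matrix, one row per item (rownames = item ids).
#' @param similarity \code{"uncentered_pearson"} (default) or
#'   \code{"pearson"}.
#' @return A \linkS4class{CentroidDendrogram}.
#' @seealso \code{\link{cutK}}, \code{\link{exportNewick}}
#' @export
centroidLinkageCluster <- function(items,
                                   similarity = c("uncentered_pearson", "pearson")) {
    similarity <- match.arg(similarity)
    items <- as.matrix(items)
    n <- nrow(items)
    if (n < 2L) stop("need at least 2 items")
    if (is.null(rownames(items))) rownames(items) <- paste0("item", seq_len(n))
    zero <- rowSums(items^2) == 0
    if (similarity == "uncentered_pearson" && any(zero))
        stop("degenerate all-zero profile for item(s): ",
             paste(rownames(items)[zero], collapse = ", "))
    simf <- .sim_fun(similarity)

    ## active clusters keyed by creation index: leaves 1..n, merges n+1..2n-1
    members <- c(as.list(seq_len(n)), vector("list", n - 1L))
    centroid <- rbind(items, matrix(NA_real_, n - 1L, ncol(items)))
    active <- seq_len(n)
    sim <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        sim[i, j] <- sim[j, i] <- simf(items[i, ], items[j, ])

    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    node_id <- integer(2L * n - 1L)  # creation index -> hclust node code
    node_id[seq_len(n)] <- -seq_len(n)
    for (step in seq_len(n - 1L)) {
        best <- c(NA_integer_, NA_integer_); best_s <- -Inf
        for (ai in seq_len(length(active) - 1L)) {
            for (bi in (ai + 1L):length(active)) {
                pa <- min(active[ai], active[bi])
                pb <- max(active[ai], active[bi])
                s <- sim[pa, pb]
                if (s > best_s + 1e-12) {
                    best_s <- s; best <- c(pa, pb)
                } else if (s >= best_s - 1e-12 &&
                           (pa < best[1] ||
                            (pa == best[1] && pb < best[2]))) {
                    best_s <- max(best_s, s); best <- c(pa, pb)
                }
            }
        }
        a <- best[1]; b <- best[2]
        new_idx <- n + step
        members[[new_idx]] <- c(members[[a]], members[[b]])
        centroid[new_idx, ] <- colMeans(items[members[[new_idx]], , drop = FALSE])
        merge[step, ] <- sort(c(node_id[a], node_id[b]))
        height[step] <- 1 - best_s
        node_id[new_idx] <- step
        active <- c(setdiff(active, c(a, b)), new_idx)
        for (other in active[-length(active)])
            sim[new_idx, other] <- sim[other, new_idx] <-
                simf(centroid[new_idx, ], centroid[other, ])
    }
    d <- new("CentroidDendrogram", labels = rownames(items), merge = merge,
             height = height,
             centroids = centroid[n + seq_len(n - 1L), , drop = FALSE],
             similarity = similarity, order = .leaf_order(merge, n))
    d
}

## display order: left-to-right leaf traversal of the merge tree
.leaf_order <- function(merge, n) {
    if (n == 1L) return(1L)
    rec <- function(node) {
        if (node < 0L) return(-node)
        c(rec(merge[node, 1]), rec(merge[node, 2]))
    }
    as.integer(rec(nrow(merge)))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 last merges and returns the resulting k groups.
#' Cluster labels 1..k are assigned in order of each group's first leaf in
#' the original item order, making the labelling invariant to item
#' permutation up to relabelling.
#'
#' @param d a \linkS4class{CentroidDendrogram}.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return named integer vector, item -> cluster label.
#' @export
cutK <- function(d, k) {
    n <- length(d@labels)
    if (k < 1L || k > n) stop("k must be between 1 and the leaf count")
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    node_root <- integer(n - 1L)
    keep <- seq_len(n - k)
    for (s in keep) {
        kids <- d@merge[s, ]
        roots <- vapply(kids, function(ch)
            if (ch < 0L) find(-ch) else find(node_root[ch]), integer(1))
        parent[roots[2]] <- roots[1]
        node_root[s] <- roots[1]
    }
    comp <- vapply(seq_len(n), find, integer(1))
    labels <- match(comp, unique(comp))
    setNames(labels, d@labels)
}

#' Cluster samples on their expression profiles
#'
#' Filters genes expressed at \code{minFpkm} or above in at least one
#' sample, applies the chosen transform (default log2(FPKM + 1)), and
#' clusters the sample columns with centroid linkage and uncentered Pearson
#' similarity.
#'
#' @param m a gene-level \linkS4class{FPKMExperiment} with >= 2 samples.
#' @param minFpkm expression filter (inclusive; default 1 FPKM).
#' @param transform \code{"log2p1"} (default) or \code{"none"}.
#' @param similarity passed to \code{\link{centroidLinkageCluster}}.
#' @return A \linkS4class{CentroidDendrogram} over samples.
#' @export
clusterExpressionProfiles <- function(m, minFpkm = 1,
                                      transform = c("log2p1", "none"),
                                      similarity = "uncentered_pearson") {
    transform <- match.arg(transform)
    if (ncol(m) < 2L) stop("need at least 2 samples")
    f <- filterExpressed(m, minFpkm, "any_sample")
    v <- fpkm(f)
    if (transform == "log2p1") v <- log2(v + 1)
    centroidLinkageCluster(t(v), similarity = similarity)
}

#' Cluster cell types on their threshold curves
#'
#' Clusters cell types on their per-cell-type mean statistic-vs-threshold
#' vectors (e.g. expressed-gene counts from
#' \code{\link{expressedGeneCounts}}) with centroid linkage and uncentered
#' Pearson similarity. A k = 2 cut of the result gives the segregation of
#' cell types into high and low proportion of highly expressed genes.
#'
#' @param c a \linkS4class{ThresholdCurveSet}.
#' @param similarity passed to \code{\link{centroidLinkageCluster}}.
#' @return A \linkS4class{CentroidDendrogram} over cell types.
#' @export
clusterThresholdCurves <- function(c, similarity = "uncentered_pearson") {
    prof <- t(c@ctMean)
    if (anyNA(prof))
        stop("curves contain flagged (NA) points; restrict the grid first")
    centroidLinkageCluster(prof, similarity = similarity)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences between a node and its children
#' (leaves sit at height 0); centroid-linkage inversions may yield negative
#' branch lengths, which are written as computed.
#'
#' @param d a \linkS4class{CentroidDendrogram}.
#' @param path optional output path; when \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string, invisibly when \code{path} is given.
#' @export
exportNewick <- function(d, path = NULL) {
    h <- d@height
    rec <- function(node, parent_h) {
        if (node < 0L)
            return(sprintf("%s:%.10g", d@labels[-node], parent_h))
        kids <- d@merge[node, ]
        sprintf("(%s,%s):%.10g", rec(kids[1], h[node]), rec(kids[2], h[node]),
                parent_h - h[node])
    }
    n <- nrow(d@merge)
    str <- if (n == 0L) {
        sprintf("(%s:0);", d@labels[1])
    } else {
        kids <- d@merge[n, ]
        sprintf("(%s,%s);", rec(kids[1], h[n]), rec(kids[2], h[n]))
    }
    if (is.null(path)) return(str)
    writeLines(str, path)
    invisible(str)
}

#' Export a dendrogram in Cluster 3.0-style GTR/CDT table layout
#'
#' Writes \code{<prefix>.gtr} (one row per merge: node id, two child ids
#' and the similarity at the merge) and \code{<prefix>.cdt} (the item
#' profiles reordered by the dendrogram's leaf order).
#'
#' @param d a \linkS4class{CentroidDendrogram}.
#' @param profiles items x variables matrix used for the clustering (rownames
#'   must match the dendrogram labels).
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
exportClusterTables <- function(d, profiles, prefix) {
    id_of <- function(code)
        if (code < 0L) sprintf("ITEM%dX", -code) else sprintf("NODE%dX", code)
    gtr <- data.frame(
        NODEID = sprintf("NODE%dX", seq_len(nrow(d@merge))),
        LEFT = vapply(d@merge[, 1], id_of, character(1)),
        RIGHT = vapply(d@merge[, 2], id_of, character(1)),
        CORRELATION = sprintf("%.10g", 1 - d@height))
    gtr_path <- paste0(prefix, ".gtr")
    write.table(gtr, gtr_path, sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- d@order
    cdt <- data.frame(GID = sprintf("ITEM%dX", ord),
                      NAME = d@labels[ord],
                      profiles[d@labels[ord], , drop = FALSE],
                      check.names = FALSE)
    cdt_path <- paste0(prefix, ".cdt")
    write.table(cdt, cdt_path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(gtr_path, cdt_path))
}
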