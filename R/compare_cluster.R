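#' Classify differential-expression calls across the two cell states
#'
#' Partitions genes called up (or down) in at least one state contrast into
#' the six cross-condition categories: regulated in both states, in the
#' self-renewing state only, or in the senescent state only, per direction.
#' A gene called up in one state and down in the other lands in both its
#' up-only and down-only categories and is additionally flagged as
#' discordant.
#'
#' @param sr,sen `fc_de` results from [call_contrast()] for the SR and SEN
#'   contrasts, computed over the same gene universe.
#' @return An object of class `fc_categories`: a list with `sets` (named
#'   list of the six gene-id sets), `counts`, `proportions` (of the
#'   universe), `discordant` (gene ids) and `universe_size`.
#' @export
classify_de_genes <- function(sr, sen) {
  stopifnot(inherits(sr, "fc_de"), inherits(sen, "fc_de"))
  if (!setequal(sr$gene_id, sen$gene_id)) {
    stopf("classification error: the two contrasts cover different gene universes")
  }
  up_sr <- sr$gene_id[sr$call == "up"]
  dn_sr <- sr$gene_id[sr$call == "down"]
  up_sen <- sen$gene_id[sen$call == "up"]
  dn_sen <- sen$gene_id[sen$call == "down"]
  sets <- list(
    up_both = intersect(up_sr, up_sen),
    up_SR_only = setdiff(up_sr, up_sen),
    up_SEN_only = setdiff(up_sen, up_sr),
    down_both = intersect(dn_sr, dn_sen),
    down_SR_only = setdiff(dn_sr, dn_sen),
    down_SEN_only = setdiff(dn_sen, dn_sr)
  )
  sets <- lapply(sets, sort)
  n_univ <- length(unique(sr$gene_id))
  structure(
    list(sets = sets,
         counts = lengths(sets),
         proportions = lengths(sets) / n_univ,
         discordant = sort(union(intersect(up_sr, dn_sen),
                                 intersect(dn_sr, up_sen))),
         universe_size = n_univ),
    class = "fc_categories"
  )
}

#' @export
print.fc_categories <- function(x, ...) {
  cat(sprintf("cross-condition DE categories over %d genes\n", x$universe_size))
  for (nm in names(x$sets)) {
    cat(sprintf("  %-14s %5d (%.1f%%)\n", nm, x$counts[[nm]],
                100 * x$proportions[[nm]]))
  }
  if (length(x$discordant) > 0L) {
    cat(sprintf("  discordant     %5d\n", length(x$discordant)))
  }
  invisible(x)
}

#' Pairwise distances between condition expression profiles
#'
#' Computes a symmetric condition-by-condition distance matrix from
#' normalized expression profiles: `1 - correlation` of `log2(e + epsilon)`
#' profiles (Spearman by default, robust to the heavy-tailed normalized
#' values), or Euclidean distance of the log profiles.
#'
#' @param expr Normalized expression matrix (genes by libraries).
#' @param method `"spearman"`, `"pearson"` or `"euclidean"`.
#' @param epsilon Pseudo-expression added before the log to admit zeros.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
condition_distance_matrix <- function(expr,
                                      method = c("spearman", "pearson",
                                                 "euclidean"),
                                      epsilon = 1e-6) {
  method <- match.arg(method)
  if (!is.matrix(expr) || nrow(expr) < 2L) {
    stopf("need a matrix of >= 2 genes to compare condition profiles")
  }
  logv <- log2(expr + epsilon)
  const <- apply(logv, 2, function(v) sd(v) == 0)
  if (any(const)) {
    stopf("degenerate correlation: constant expression profile in library %s",
          paste(colnames(expr)[const], collapse = ", "))
  }
  d <- if (method == "euclidean") {
    as.matrix(dist(t(logv)))
  } else {
    1 - cor(logv, method = method)
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering of the condition distance matrix
#' (average linkage by default). Libraries are ordered lexicographically
#' before clustering so that ties resolve deterministically.
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param linkage Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An [stats::hclust] object.
#' @seealso [dendrogram_newick()], [outlier_condition()]
#' @export
cluster_conditions <- function(distances, linkage = "average") {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stopf("distance matrix must be square")
  }
  if (max(abs(distances - t(distances))) > 1e-8) {
    stopf("distance matrix must be symmetric")
  }
  ord <- order(colnames(distances))
  d <- distances[ord, ord]
  hclust(as.dist(d), method = linkage)
}

#' Export a condition dendrogram as Newick text
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Outlier condition of a dendrogram
#'
#' Returns the label of the leaf that joins the tree last, when the final
#' agglomeration merges a singleton into the cluster of all remaining
#' conditions; `NA` when the final merge joins two multi-leaf clusters
#' (no single outlier).
#'
#' @param hc An [stats::hclust] object.
#' @return A character scalar or `NA`.
#' @export
outlier_condition <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  last <- hc$merge[nrow(hc$merge), ]
  if (any(last < 0)) {
    hc$labels[-last[last < 0][1L]]
  } else {
    NA_character_
  }
}

#' Plotting-ready table of grouped gene expression
#'
#' Orders genes by cross-condition category (up in both, up SR-only,
#' up SEN-only, down in both, down SR-only, down SEN-only) and, within each
#' group, by decreasing mean normalized expression, and returns the gene by
#' condition expression values alongside the group label.
#'
#' @param categories An `fc_categories` object.
#' @param expr Normalized expression matrix covering the categorized genes.
#' @return A data frame with columns `gene_id`, `group` and one column per
#'   library.
#' @export
heatmap_groups <- function(categories, expr) {
  stopifnot(inherits(categories, "fc_categories"), is.matrix(expr))
  blocks <- lapply(names(categories$sets), function(nm) {
    genes <- intersect(categories$sets[[nm]], rownames(expr))
    if (length(genes) == 0L) {
      return(NULL)
    }
    genes <- genes[order(rowMeans(expr[genes, , drop = FALSE]),
                         decreasing = TRUE)]
    data.frame(gene_id = genes, group = nm,
               expr[genes, , drop = FALSE],
               check.names = FALSE, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) {
    out <- data.frame(gene_id = character(0), group = character(0),
                      stringsAsFactors = FALSE)
    for (lib in colnames(expr)) out[[lib]] <- numeric(0)
    return(out)
  }
  do.call(rbind, blocks)
}
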