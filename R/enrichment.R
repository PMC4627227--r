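#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation of a differentially
#' expressed gene list within a gene universe, using the one-sided
#' hypergeometric upper tail: the probability of an overlap at least as
#' large as observed when the DE list were drawn at random from the
#' universe. Sets are intersected with the universe first, and sets with
#' fewer than `min_set_size` universe genes are skipped (a pathway must
#' contain multiple testable genes). q-values are Benjamini-Hochberg
#' adjusted p-values across all tested sets of the call.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of all testable gene ids (typically the
#'   genes surviving the low-expression filter).
#' @param gene_sets Named list of character vectors (see
#'   [read_gene_sets()]).
#' @param direction Optional label (`"up"`/`"down"`) carried into the
#'   result.
#' @param state_scope Optional label (`"SR_only"`/`"SEN_only"`/`"both"`)
#'   carried into the result.
#' @param min_set_size Minimum universe-intersected set size (default 2).
#' @return A data frame sorted by p-value with columns `set_name`,
#'   `direction`, `state_scope`, `k` (overlap), `K` (set size in universe),
#'   `n` (DE-list size), `N` (universe size), `p_value`, `q_value`, and a
#'   list column `overlap_genes`.
#' @examples
#' universe <- paste0("g", 1:20)
#' sets <- list(P1 = paste0("g", 1:5))
#' enrich_gene_sets(paste0("g", 1:5), universe, sets) # p = 1/choose(20, 5)
#' @export
enrich_gene_sets <- function(de_genes, universe, gene_sets,
                             direction = NA_character_,
                             state_scope = NA_character_,
                             min_set_size = 2L) {
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  if (!all(de_genes %in% universe)) {
    stopf("enrichment error: DE genes outside the universe (e.g. %s)",
          setdiff(de_genes, universe)[1L])
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    if (K < min_set_size) {
      return(NULL)
    }
    overlap <- intersect(members, de_genes)
    k <- length(overlap)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(set_name = nm, k = k, K = K, p_value = p, overlap = sort(overlap))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set_name = character(0), direction = character(0),
                      state_scope = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      overlap_genes = I(list()), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    set_name = vapply(rows, `[[`, character(1), "set_name"),
    direction = direction, state_scope = state_scope,
    k = vapply(rows, `[[`, integer(1), "k"),
    K = vapply(rows, `[[`, integer(1), "K"),
    n = n, N = N,
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$overlap_genes <- I(lapply(rows, `[[`, "overlap"))
  res[order(res$p_value, res$set_name), , drop = FALSE]
}

#' Build the shared-gene pathway network
#'
#' Nodes are the pathways enriched at `q_value <= q_threshold`, weighted by
#' their number of differentially expressed genes; an (undirected) edge
#' connects two pathways when they share at least `min_shared_genes`
#' differentially expressed genes, weighted by the shared-gene count.
#'
#' @param enrichments Enrichment table from [enrich_gene_sets()] (one
#'   direction/scope block; set names must be unique).
#' @param q_threshold FDR threshold for node inclusion (default 0.25).
#' @param min_shared_genes Minimum shared DE genes for an edge (default 1).
#' @return An undirected igraph object with vertex attributes
#'   `de_gene_count` and `q_value` and edge attributes `weight` (shared
#'   count) and `shared_genes` (semicolon-joined ids).
#' @export
build_pathway_network <- function(enrichments, q_threshold = 0.25,
                                  min_shared_genes = 1L) {
  keep <- enrichments[enrichments$q_value <= q_threshold, , drop = FALSE]
  if (anyDuplicated(keep$set_name)) {
    stopf("network error: duplicate pathway names; build one network per enrichment block")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(keep) > 0L) {
    g <- igraph::add_vertices(g, nrow(keep), name = keep$set_name,
                              de_gene_count = as.integer(keep$k),
                              q_value = keep$q_value)
  }
  if (nrow(keep) >= 2L) {
    pairs <- combn(nrow(keep), 2L)
    froms <- integer(0); tos <- integer(0)
    weights <- integer(0); shared <- character(0)
    for (idx in seq_len(ncol(pairs))) {
      i <- pairs[1L, idx]; j <- pairs[2L, idx]
      ov <- intersect(keep$overlap_genes[[i]], keep$overlap_genes[[j]])
      if (length(ov) >= min_shared_genes) {
        froms <- c(froms, i); tos <- c(tos, j)
        weights <- c(weights, length(ov))
        shared <- c(shared, paste(sort(ov), collapse = ";"))
      }
    }
    if (length(froms) > 0L) {
      g <- igraph::add_edges(g, rbind(froms, tos),
                             weight = weights, shared_genes = shared)
    }
  }
  g
}

#' Summarize a pathway network
#'
#' @param network An igraph object from [build_pathway_network()].
#' @return A list with `n_nodes`, `n_edges`, `degree` (named integer
#'   vector), `n_components` and `component_sizes`.
#' @export
network_summary <- function(network) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L,
                degree = setNames(integer(0), character(0)),
                n_components = 0L, component_sizes = integer(0)))
  }
  comps <- igraph::components(network)
  list(n_nodes = igraph::vcount(network),
       n_edges = igraph::ecount(network),
       degree = igraph::degree(network),
       n_components = comps$no,
       component_sizes = as.integer(comps$csize))
}
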