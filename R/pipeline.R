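#' Run the full four-condition analysis pipeline
#'
#' Convenience driver chaining the pipeline stages on a generated (or
#' assembled) experiment: spike-in QC, low-expression filtering, anchored
#' normalization, the two within-state differential-expression contrasts
#' (IL-2+ vs IL-2- in SR and in SEN), cross-condition classification,
#' condition clustering and, when gene sets are supplied, per-direction
#' over-representation and the shared-gene pathway network.
#'
#' @param experiment An `fc_experiment` from [generate_experiment()], or a
#'   list with at least `counts`, `annotation` and (optionally) `spikein`.
#' @param config An [run_config()].
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @return A list of class `fc_analysis` with elements `qc`, `filtered`,
#'   `removed`, `scaling`, `normalized`, `de_sr`, `de_sen`, `categories`,
#'   `distances`, `dendrogram`, and (when `gene_sets` is given)
#'   `enrichment` (per direction and state scope) and `networks` (per
#'   direction).
#' @export
analyze_experiment <- function(experiment, config = run_config(),
                               gene_sets = NULL) {
  counts <- experiment$counts
  annotation <- experiment$annotation
  qc <- NULL
  if (!is.null(experiment$spikein) &&
      sum(is_spikein_id(rownames(counts), config$spikein_pattern)) >= 3L) {
    qc <- ercc_qc(counts, experiment$spikein, r_floor = config$qc_r_floor)
  }
  flt <- filter_low_expression(counts, config$cpm_threshold,
                               config$filter_scope, config$spikein_pattern)
  kept <- flt$retained
  spike <- is_spikein_id(rownames(kept), config$spikein_pattern)
  gene_counts <- kept[!spike, , drop = FALSE]

  scaling <- compute_actb_scaling(gene_counts, config$actb_gene_id)
  normalized <- normalize_expression(gene_counts, annotation, scaling)

  de_sr <- call_contrast(kept, de_contrast("SR_IL2minus", "SR_IL2plus",
                                           "SR: IL-2+ vs IL-2-"), config)
  de_sen <- call_contrast(kept, de_contrast("SEN_IL2minus", "SEN_IL2plus",
                                            "SEN: IL-2+ vs IL-2-"), config)
  categories <- classify_de_genes(de_sr, de_sen)
  distances <- condition_distance_matrix(normalized)
  dendro <- cluster_conditions(distances)

  out <- list(qc = qc, filtered = kept, removed = flt$removed,
              scaling = scaling, normalized = normalized,
              de_sr = de_sr, de_sen = de_sen, categories = categories,
              distances = distances, dendrogram = dendro)

  if (!is.null(gene_sets)) {
    universe <- rownames(gene_counts)
    enr <- list()
    for (dir in c("up", "down")) {
      for (scope in c("both", "SR_only", "SEN_only")) {
        set_nm <- paste(dir, scope, sep = "_")
        enr[[set_nm]] <- enrich_gene_sets(categories$sets[[set_nm]],
                                          universe, gene_sets,
                                          direction = dir,
                                          state_scope = scope)
      }
    }
    pooled <- list(
      up = unique(unlist(categories$sets[c("up_both", "up_SR_only",
                                           "up_SEN_only")])),
      down = unique(unlist(categories$sets[c("down_both", "down_SR_only",
                                             "down_SEN_only")]))
    )
    networks <- lapply(names(pooled), function(dir) {
      e <- enrich_gene_sets(pooled[[dir]], universe, gene_sets,
                            direction = dir, state_scope = "pooled")
      build_pathway_network(e, q_threshold = config$fdr_threshold,
                            min_shared_genes = config$min_shared_genes)
    })
    names(networks) <- names(pooled)
    out$enrichment <- enr
    out$networks <- networks
  }
  structure(out, class = "fc_analysis")
}
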