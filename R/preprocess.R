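#' ERCC spike-in quality control
#'
#' Compares observed spike-in counts against their expected concentrations
#' on the log-log scale, per library: Pearson correlation, fitted slope and
#' intercept of `log2(observed + 1)` on `log2(expected concentration)`.
#' Libraries whose correlation falls below `r_floor` are flagged.
#'
#' @param counts Count matrix containing spike-in rows (other rows are
#'   ignored).
#' @param spikein Spike-in table with columns `species_id`, `length`,
#'   `expected_concentration` (see [spikein_table()]).
#' @param r_floor Minimum acceptable Pearson correlation (default 0.9).
#' @return A data frame with one row per library: `library_id`,
#'   `n_species`, `pearson_r`, `slope`, `intercept`, `flagged`.
#' @export
ercc_qc <- function(counts, spikein, r_floor = 0.9) {
  assert_count_matrix(counts)
  if (any(spikein$expected_concentration <= 0)) {
    stopf("spike-in table error: expected concentrations must be positive")
  }
  if (anyDuplicated(spikein$species_id)) {
    stopf("spike-in table error: duplicate species ids")
  }
  species <- intersect(spikein$species_id, rownames(counts))
  if (length(species) < 3L) {
    stopf("spike-in QC requires >= 3 spike-in species with observed counts (found %d)",
          length(species))
  }
  x <- log2(spikein$expected_concentration[match(species, spikein$species_id)])
  out <- lapply(colnames(counts), function(lib) {
    obs <- counts[species, lib]
    if (sd(obs) == 0) {
      stopf("degenerate spike-in fit in library '%s': all observed counts equal", lib)
    }
    y <- log2(obs + 1)
    fit <- lm(y ~ x)
    r <- cor(x, y)
    data.frame(library_id = lib, n_species = length(species),
               pearson_r = r, slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               flagged = r < r_floor, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Remove lowly expressed genes by counts per million
#'
#' CPM for gene i in library j is `c_ij / total_j * 1e6`, where `total_j`
#' is the library's total gene count excluding spike-in species (spike-in
#' content reflects dilution, not biology). A gene is removed when its CPM
#' falls below `cpm_threshold` in every library (`scope = "any_library"`,
#' the default: retained if it clears the threshold anywhere) or in any
#' library (`scope = "all_libraries"`). The comparison is strict: CPM
#' exactly equal to the threshold is retained. Spike-in rows are exempt and
#' always retained.
#'
#' @param counts Count matrix.
#' @param cpm_threshold CPM threshold (default 1).
#' @param scope `"any_library"` or `"all_libraries"`.
#' @param spikein_pattern Regular expression identifying spike-in rows.
#' @return A list with `retained` (filtered count matrix, spike-ins last in
#'   original order) and `removed` (character vector of removed gene ids).
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  scope = c("any_library", "all_libraries"),
                                  spikein_pattern = "^ERCC-") {
  scope <- match.arg(scope)
  assert_count_matrix(counts)
  if (cpm_threshold < 0) stopf("cpm_threshold must be >= 0")
  spike <- is_spikein_id(rownames(counts), spikein_pattern)
  totals <- colSums(counts[!spike, , drop = FALSE])
  if (any(totals <= 0)) {
    stopf("library total(s) must be positive: %s",
          paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  cpm <- sweep(counts[!spike, , drop = FALSE], 2, totals, "/") * 1e6
  ok <- if (scope == "any_library") {
    rowSums(cpm >= cpm_threshold) > 0
  } else {
    rowSums(cpm >= cpm_threshold) == ncol(cpm)
  }
  keep_genes <- rownames(cpm)[ok]
  removed <- rownames(cpm)[!ok]
  retained <- counts[c(keep_genes, rownames(counts)[spike]), , drop = FALSE]
  list(retained = retained, removed = removed)
}

#' Beta-actin scaling factors
#'
#' The anchored normalization factor for library j is
#' `s_j = mean_k(c_ACTB,k) / c_ACTB,j`: the cross-library mean anchor count
#' divided by the library's own anchor count. After scaling, the anchor's
#' count is identical across libraries.
#'
#' @param counts Count matrix containing the anchor gene.
#' @param actb_gene_id Anchor gene identifier (default `"ACTB"`).
#' @return A data frame with columns `library_id`, `actb_count`, `factor`.
#' @examples
#' m <- matrix(c(100L, 300L), 1, dimnames = list("ACTB", c("A", "B")))
#' compute_actb_scaling(m) # factors 2 and 2/3
#' @export
compute_actb_scaling <- function(counts, actb_gene_id = "ACTB") {
  assert_count_matrix(counts)
  if (!actb_gene_id %in% rownames(counts)) {
    stopf("normalization error: anchor gene '%s' absent from the count matrix",
          actb_gene_id)
  }
  actb <- counts[actb_gene_id, ]
  zero <- names(actb)[actb <= 0]
  if (length(zero) > 0L) {
    stopf("normalization error: anchor gene '%s' has zero count in library %s",
          actb_gene_id, paste(zero, collapse = ", "))
  }
  data.frame(library_id = colnames(counts),
             actb_count = as.numeric(actb),
             factor = mean(actb) / as.numeric(actb),
             stringsAsFactors = FALSE)
}

#' Anchored, length-corrected expression normalization
#'
#' The normalized expression of gene i in library j is
#' `e_ij = c_ij * s_j / l_i`, with `s_j` the anchor scaling factor and
#' `l_i` the gene's total exon length. The anchor gene's normalized value
#' is constant across libraries by construction.
#'
#' @param counts Count matrix.
#' @param annotation Data frame with columns `gene_id` and `length`
#'   covering every row of `counts`.
#' @param scaling Scaling-factor table from [compute_actb_scaling()]
#'   covering every column of `counts`.
#' @return A numeric matrix of normalized expression values with the
#'   per-gene lengths attached as attribute `"gene_length"`.
#' @export
normalize_expression <- function(counts, annotation, scaling) {
  assert_count_matrix(counts)
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx)) {
    stopf("annotation error: no length for gene(s) %s",
          paste(utils::head(rownames(counts)[is.na(idx)], 5L), collapse = ", "))
  }
  lens <- annotation$length[idx]
  if (any(lens <= 0)) stopf("annotation error: non-positive gene length")
  sidx <- match(colnames(counts), scaling$library_id)
  if (anyNA(sidx)) {
    stopf("scaling does not cover library %s",
          paste(colnames(counts)[is.na(sidx)], collapse = ", "))
  }
  s <- scaling$factor[sidx]
  e <- sweep(counts, 2, s, "*") / lens
  attr(e, "gene_length") <- setNames(lens, rownames(counts))
  e
}
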