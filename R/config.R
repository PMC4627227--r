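#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline, with defaults mirroring
#' the published analysis: counts-per-million filter threshold 1, generalized
#' fold-change score cutoff 0.01 at the 0.01 posterior quantile, and a
#' beta-actin anchor gene. All output writers embed the effective
#' configuration as a reproducibility header.
#'
#' @param seed Integer seed recorded with the run and used for any
#'   stochastic step (e.g. the sampling path of the posterior score).
#' @param actb_gene_id Identifier of the beta-actin anchor gene used for
#'   normalization and (by default) effective library sizing.
#' @param cpm_threshold Counts-per-million threshold below which a gene is
#'   considered lowly expressed (strict: CPM exactly equal to the threshold
#'   is retained).
#' @param gfold_cutoff Score cutoff defining differential expression; a gene
#'   is called up when score >= cutoff and down when score <= -cutoff.
#' @param gfold_quantile Posterior quantile used for the conservative score
#'   (must lie in (0, 0.5)).
#' @param mc_draws Number of Monte-Carlo draws for the sampling path of the
#'   posterior score.
#' @param fdr_threshold q-value threshold for admitting a pathway into the
#'   pathway network.
#' @param min_shared_genes Minimum number of shared differentially expressed
#'   genes for a network edge.
#' @param filter_scope `"any_library"` retains a gene whose CPM clears the
#'   threshold in at least one library; `"all_libraries"` requires every
#'   library.
#' @param size_method Effective library size for the fold-change posterior:
#'   `"actb"` (anchor-gene counts, the default, consistent with the
#'   normalization) or `"total"` (total non-spike-in counts).
#' @param prior_shape Gamma prior shape added to observed counts in the
#'   posterior (1 = flat prior).
#' @param spikein_pattern Regular expression identifying spike-in species
#'   among row names.
#' @param qc_r_floor Minimum acceptable spike-in log-log Pearson correlation
#'   before a library is flagged.
#'
#' @return An object of class `fc_config` (a validated named list).
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$gfold_cutoff
#' @export
run_config <- function(seed = 1L,
                       actb_gene_id = "ACTB",
                       cpm_threshold = 1,
                       gfold_cutoff = 0.01,
                       gfold_quantile = 0.01,
                       mc_draws = 1e5,
                       fdr_threshold = 0.25,
                       min_shared_genes = 1L,
                       filter_scope = c("any_library", "all_libraries"),
                       size_method = c("actb", "total"),
                       prior_shape = 1,
                       spikein_pattern = "^ERCC-",
                       qc_r_floor = 0.9) {
  filter_scope <- match.arg(filter_scope)
  size_method <- match.arg(size_method)
  if (length(seed) != 1L || is.na(seed)) stopf("seed must be a single integer")
  if (cpm_threshold < 0) stopf("cpm_threshold must be >= 0")
  if (gfold_quantile <= 0 || gfold_quantile >= 0.5) {
    stopf("gfold_quantile must lie strictly between 0 and 0.5")
  }
  if (gfold_cutoff < 0) stopf("gfold_cutoff must be >= 0")
  if (mc_draws < 1) stopf("mc_draws must be >= 1")
  if (fdr_threshold < 0 || fdr_threshold > 1) {
    stopf("fdr_threshold must be a probability")
  }
  if (min_shared_genes < 1) stopf("min_shared_genes must be >= 1")
  if (prior_shape <= 0) stopf("prior_shape must be > 0")
  structure(
    list(
      seed = as.integer(seed),
      actb_gene_id = actb_gene_id,
      cpm_threshold = cpm_threshold,
      gfold_cutoff = gfold_cutoff,
      gfold_quantile = gfold_quantile,
      mc_draws = mc_draws,
      fdr_threshold = fdr_threshold,
      min_shared_genes = as.integer(min_shared_genes),
      filter_scope = filter_scope,
      size_method = size_method,
      prior_shape = prior_shape,
      spikein_pattern = spikein_pattern,
      qc_r_floor = qc_r_floor
    ),
    class = "fc_config"
  )
}

#' @export
print.fc_config <- function(x, ...) {
  cat("foldcall run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Comment lines embedding the effective configuration, prepended to every
# TSV the pipeline writes.
config_header <- function(config) {
  if (is.null(config)) {
    return(character(0))
  }
  stopifnot(inherits(config, "fc_config"))
  vals <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  c("# foldcall reproducibility header",
    sprintf("# %s=%s", names(vals), vals))
}
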