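#' Default differential-expression specification for the generator
#'
#' Six programmed regulation categories partitioned by direction and by the
#' cell state in which the priming treatment acts: up- or down-regulated in
#' both states, in the self-renewing (SR) state only, or in the senescent
#' (SEN) state only. The senescent response is modeled substantially
#' stronger (|log2FC| 4 vs 2), which makes the primed senescent library the
#' transcriptome-wide outlier condition.
#'
#' @return A data frame with columns `category`, `n`, `log2fc_SR`,
#'   `log2fc_SEN`.
#' @export
default_de_spec <- function() {
  data.frame(
    category = c("up_both", "up_SR_only", "up_SEN_only",
                 "down_both", "down_SR_only", "down_SEN_only"),
    n = c(200L, 100L, 100L, 100L, 50L, 50L),
    log2fc_SR = c(2, 2, 0, -2, -2, 0),
    log2fc_SEN = c(4, 0, 4, -4, 0, -4),
    stringsAsFactors = FALSE
  )
}

de_categories <- function() {
  c("up_both", "up_SR_only", "up_SEN_only",
    "down_both", "down_SR_only", "down_SEN_only")
}

validate_de_spec <- function(de_spec, n_assignable) {
  need <- c("category", "n", "log2fc_SR", "log2fc_SEN")
  if (!all(need %in% colnames(de_spec))) {
    stopf("de_spec must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(de_spec$category %in% de_categories()) ||
      anyDuplicated(de_spec$category)) {
    stopf("de_spec categories must be unique and drawn from: %s",
          paste(de_categories(), collapse = ", "))
  }
  if (!all(is.finite(de_spec$log2fc_SR)) || !all(is.finite(de_spec$log2fc_SEN))) {
    stopf("de_spec effect sizes must be finite")
  }
  if (sum(de_spec$n) > n_assignable) {
    stopf("design error: de_spec assigns %d genes but only %d are available",
          sum(de_spec$n), n_assignable)
  }
  # sign structure must match the category label
  sgn <- function(x) sign(x)
  for (i in seq_len(nrow(de_spec))) {
    cat_i <- de_spec$category[i]
    sr <- de_spec$log2fc_SR[i]
    sen <- de_spec$log2fc_SEN[i]
    ok <- switch(cat_i,
      up_both = sr > 0 && sen > 0,
      up_SR_only = sr > 0 && sen == 0,
      up_SEN_only = sr == 0 && sen > 0,
      down_both = sr < 0 && sen < 0,
      down_SR_only = sr < 0 && sen == 0,
      down_SEN_only = sr == 0 && sen < 0
    )
    if (de_spec$n[i] > 0L && !ok) {
      stopf("design error: effect signs for category '%s' are inconsistent", cat_i)
    }
  }
  invisible(de_spec)
}

#' Simulation design for a four-condition replicate-free experiment
#'
#' Defines the mean model of the synthetic-data generator: per-gene baseline
#' expression per unit length is drawn log-normal, multiplied by gene length
#' and the library's sequencing depth share; primed (IL-2+) libraries have
#' their means multiplied by `2^log2fc` of the state-specific programmed
#' effect. The beta-actin anchor receives a fixed fraction of the depth and
#' never carries an effect. Spike-in species are appended with
#' depth-proportional means from a log-uniform concentration ladder.
#'
#' @param n_genes Total number of genes, including the anchor.
#' @param gene_length_range Total-exon-length range (bp) for simulated genes.
#' @param library_depths Nominal per-library depth, in the order
#'   SR IL-2-, SR IL-2+, SEN IL-2-, SEN IL-2+.
#' @param actb_fraction Fraction of depth assigned to the anchor gene. The
#'   anchor is modeled as a highly expressed housekeeping gene, as the
#'   anchored normalization presumes.
#' @param spikein_fraction Fraction of depth assigned to spike-in species.
#' @param de_spec Data frame of programmed categories; see
#'   [default_de_spec()].
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline expression per unit length.
#' @param dispersion Gamma-Poisson overdispersion; 0 gives exactly Poisson
#'   counts.
#' @param n_spikein Number of spike-in species (the commercial ERCC mix has
#'   92).
#' @param spikein_length_range Spike-in length range in nt.
#' @param actb_length Anchor transcript length in bp.
#' @param seed Integer seed; the experiment is fully reproducible from it.
#' @return An object of class `fc_design`.
#' @export
simulation_design <- function(n_genes = 2000L,
                              gene_length_range = c(500, 5000),
                              library_depths = rep(2e6, 4),
                              actb_fraction = 0.02,
                              spikein_fraction = 0.01,
                              de_spec = default_de_spec(),
                              baseline_meanlog = 0,
                              baseline_sdlog = 1.2,
                              dispersion = 0,
                              n_spikein = 92L,
                              spikein_length_range = c(250, 2000),
                              actb_length = 1852L,
                              seed = 1L) {
  if (n_genes < 2L) stopf("design error: need at least 2 genes (anchor + 1)")
  if (length(library_depths) != 4L || any(library_depths <= 0)) {
    stopf("design error: library_depths must be 4 positive values")
  }
  if (actb_fraction <= 0 || spikein_fraction < 0 ||
      actb_fraction + spikein_fraction >= 1) {
    stopf("design error: depth fractions must be positive and sum below 1")
  }
  if (dispersion < 0) stopf("design error: dispersion must be >= 0")
  if (n_spikein < 1L) stopf("design error: n_spikein must be >= 1")
  if (diff(range(gene_length_range)) < 0 || min(gene_length_range) <= 0) {
    stopf("design error: invalid gene_length_range")
  }
  validate_de_spec(de_spec, n_assignable = n_genes - 1L)
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length_range = gene_length_range,
         library_depths = library_depths,
         actb_fraction = actb_fraction,
         spikein_fraction = spikein_fraction,
         de_spec = de_spec,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         dispersion = dispersion,
         n_spikein = as.integer(n_spikein),
         spikein_length_range = spikein_length_range,
         actb_length = as.integer(actb_length),
         seed = as.integer(seed)),
    class = "fc_design"
  )
}

#' Synthetic ERCC-style spike-in table
#'
#' Produces a table of spike-in species with lengths drawn uniformly from
#' `length_range` and expected concentrations on a log-uniform ladder
#' spanning five orders of magnitude (randomly assigned to species). The
#' defaults mirror the commercial ERCC mix: 92 species of 250-2000 nt.
#'
#' @param n_spikein Number of species.
#' @param length_range Length range in nt.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A data frame with columns `species_id`, `length`,
#'   `expected_concentration`.
#' @export
spikein_table <- function(n_spikein = 92L, length_range = c(250, 2000),
                          seed = 1L) {
  if (n_spikein < 1L) stopf("design error: n_spikein must be >= 1")
  if (diff(range(length_range)) < 0 || min(length_range) <= 0) {
    stopf("design error: empty or invalid spike-in length range")
  }
  with_seed(seed, {
    lens <- sample(seq(length_range[1L], length_range[2L]), n_spikein,
                   replace = TRUE)
    conc <- 10^seq(-1, 4, length.out = n_spikein)
    conc <- sample(conc)
    data.frame(
      species_id = sprintf("ERCC-%04d", seq_len(n_spikein)),
      length = as.integer(lens),
      expected_concentration = conc,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a four-condition replicate-free count experiment
#'
#' Draws gene-level counts for the four libraries (SR IL-2-, SR IL-2+,
#' SEN IL-2-, SEN IL-2+) from the design's mean model, with Poisson noise
#' (or a Gamma-Poisson mixture when `dispersion > 0`), and returns the
#' count matrix together with gene annotation, the spike-in table, the
#' ground-truth effect table and library metadata. The anchor gene is never
#' assigned a programmed effect.
#'
#' @param design An [simulation_design()] object.
#' @return An object of class `fc_experiment`: a list with elements
#'   `counts` (integer matrix, genes then spike-ins by 4 libraries),
#'   `annotation` (`gene_id`, `length` for genes and spike-ins),
#'   `spikein` (spike-in table), `truth` (`gene_id`, `true_log2fc_SR`,
#'   `true_log2fc_SEN`, `category`), `libraries` (library metadata) and
#'   `design`.
#' @examples
#' exp <- generate_experiment(simulation_design(n_genes = 50, n_spikein = 5))
#' dim(exp$counts)
#' table(exp$truth$category)
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "fc_design"))
  with_seed(design$seed, {
    ng <- design$n_genes - 1L # non-anchor genes
    gene_ids <- sprintf("G%05d", seq_len(ng))
    lens <- sample(seq(design$gene_length_range[1L],
                       design$gene_length_range[2L]), ng, replace = TRUE)
    baseline <- rlnorm(ng, design$baseline_meanlog, design$baseline_sdlog)

    # depth shares: anchor fixed, spike-ins fixed, genes split the rest
    gene_mass <- 1 - design$actb_fraction - design$spikein_fraction
    rel <- baseline * lens
    share <- rel / sum(rel) * gene_mass

    # programmed effects
    spec <- design$de_spec
    lfc_sr <- lfc_sen <- rep(0, ng)
    category <- rep("null", ng)
    if (sum(spec$n) > 0L) {
      idx <- sample(seq_len(ng), sum(spec$n))
      assign <- rep(seq_len(nrow(spec)), spec$n)
      lfc_sr[idx] <- spec$log2fc_SR[assign]
      lfc_sen[idx] <- spec$log2fc_SEN[assign]
      category[idx] <- spec$category[assign]
    }

    spike <- spikein_table(design$n_spikein, design$spikein_length_range,
                           seed = NULL)
    spike_rel <- spike$expected_concentration * spike$length
    spike_share <- spike_rel / sum(spike_rel) * design$spikein_fraction

    depths <- design$library_depths
    lib_ids <- c("SR_IL2minus", "SR_IL2plus", "SEN_IL2minus", "SEN_IL2plus")
    gene_means <- cbind(depths[1L] * share,
                        depths[2L] * share * 2^lfc_sr,
                        depths[3L] * share,
                        depths[4L] * share * 2^lfc_sen)
    actb_means <- depths * design$actb_fraction
    spike_means <- outer(spike_share, depths)
    means <- rbind(ACTB = actb_means, gene_means, spike_means)
    rownames(means) <- c("ACTB", gene_ids, spike$species_id)
    colnames(means) <- lib_ids

    counts <- if (design$dispersion > 0) {
      matrix(rnbinom(length(means), mu = means, size = 1 / design$dispersion),
             nrow = nrow(means), dimnames = dimnames(means))
    } else {
      matrix(rpois(length(means), means),
             nrow = nrow(means), dimnames = dimnames(means))
    }
    storage.mode(counts) <- "integer"

    annotation <- data.frame(
      gene_id = rownames(means),
      length = as.integer(c(design$actb_length, lens, spike$length)),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = c("ACTB", gene_ids),
      true_log2fc_SR = c(0, lfc_sr),
      true_log2fc_SEN = c(0, lfc_sen),
      category = c("null", category),
      stringsAsFactors = FALSE
    )
    libraries <- data.frame(
      library_id = lib_ids,
      state = c("SR", "SR", "SEN", "SEN"),
      treatment = c("IL2_minus", "IL2_plus", "IL2_minus", "IL2_plus"),
      total_mapped_counts = colSums(counts),
      stringsAsFactors = FALSE
    )
    structure(
      list(counts = counts, annotation = annotation, spikein = spike,
           truth = truth, libraries = libraries, design = design),
      class = "fc_experiment"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all tables of a generated experiment to a directory
#'
#' Emits `counts.tsv`, `annotation.tsv`, `spikein.tsv`, `truth.tsv` and
#' `libraries.tsv` in the same TSV dialect the readers accept.
#'
#' @param experiment An `fc_experiment`.
#' @param dir Output directory (created if absent).
#' @param config Optional [run_config()] for reproducibility headers.
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(experiment, dir, config = NULL) {
  stopifnot(inherits(experiment, "fc_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(experiment$counts, file.path(dir, "counts.tsv"), config)
  write_tsv_with_header <- function(df, path) {
    con <- file(path, "w")
    writeLines(config_header(config), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  write_tsv_with_header(experiment$annotation, file.path(dir, "annotation.tsv"))
  write_tsv_with_header(experiment$spikein, file.path(dir, "spikein.tsv"))
  write_tsv_with_header(experiment$truth, file.path(dir, "truth.tsv"))
  write_tsv_with_header(experiment$libraries, file.path(dir, "libraries.tsv"))
  invisible(dir)
}
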