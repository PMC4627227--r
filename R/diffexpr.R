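#' Posterior log2 fold-change quantiles between two unreplicated libraries
#'
#' Models each library's expression level as Poisson with a flat-prior Gamma
#' posterior: given count c, the rate satisfies lambda | c ~ Gamma(c +
#' `prior_shape`, 1), scaled by the effective library size. The posterior of
#' `log2((lambda_b / size_b) / (lambda_a / size_a))` is summarized by the
#' requested lower/upper quantiles and the median.
#'
#' Because the two rates are independent Gammas with a common rate
#' parameter, `lambda_b / (lambda_a + lambda_b)` is exactly
#' `Beta(c_b + prior, c_a + prior)`, so the analytic path evaluates the
#' quantiles in closed form via `qbeta`; the Monte-Carlo sampling path draws
#' the two Gamma variates directly. The two paths agree to within
#' Monte-Carlo error and the analytic path is deterministic.
#'
#' @param count_a,count_b Observed counts (baseline, treated).
#' @param size_a,size_b Effective library sizes (> 0).
#' @param quantile Tail probability for the lower/upper quantiles.
#' @param n_draws Monte-Carlo draws for the sampling path.
#' @param seed Seed for the sampling path (`NULL`: current stream).
#' @param method `"analytic"` (exact, default) or `"sampling"`.
#' @param prior_shape Gamma prior shape (1 = flat prior).
#' @return Named numeric vector `c(lower, upper, median)` in log2 units.
#' @examples
#' posterior_log2fc_quantiles(100, 400, 1, 1)
#' @export
posterior_log2fc_quantiles <- function(count_a, count_b, size_a, size_b,
                                       quantile = 0.01, n_draws = 1e5,
                                       seed = NULL,
                                       method = c("analytic", "sampling"),
                                       prior_shape = 1) {
  method <- match.arg(method)
  if (size_a <= 0 || size_b <= 0) stopf("library sizes must be > 0")
  if (count_a < 0 || count_b < 0) stopf("counts must be >= 0")
  if (quantile <= 0 || quantile >= 0.5) stopf("quantile must lie in (0, 0.5)")
  if (method == "analytic") {
    p <- qbeta(c(quantile, 1 - quantile, 0.5),
               count_b + prior_shape, count_a + prior_shape)
    vals <- log2(p / (1 - p)) + log2(size_a / size_b)
  } else {
    vals <- with_seed(seed, {
      la <- rgamma(n_draws, shape = count_a + prior_shape, rate = 1) / size_a
      lb <- rgamma(n_draws, shape = count_b + prior_shape, rate = 1) / size_b
      unname(quantile(log2(lb / la), c(quantile, 1 - quantile, 0.5)))
    })
  }
  setNames(vals, c("lower", "upper", "median"))
}

#' Generalized fold-change score
#'
#' A conservative signed posterior quantile of the log2 fold change between
#' two unreplicated libraries: the lower `quantile` of the posterior when it
#' is positive, the upper `1 - quantile` when it is negative, and 0 when the
#' central posterior interval contains no change. A gene is conventionally
#' called differentially expressed when the score magnitude reaches 0.01.
#'
#' @inheritParams posterior_log2fc_quantiles
#' @return A single signed score in log2 units.
#' @examples
#' gfold_score(100, 100, 1, 1) # 0: no evidence of change
#' gfold_score(100, 800, 1, 1) # strongly positive
#' @export
gfold_score <- function(count_a, count_b, size_a, size_b,
                        quantile = 0.01, n_draws = 1e5, seed = NULL,
                        method = c("analytic", "sampling"),
                        prior_shape = 1) {
  q <- posterior_log2fc_quantiles(count_a, count_b, size_a, size_b,
                                  quantile = quantile, n_draws = n_draws,
                                  seed = seed, method = method,
                                  prior_shape = prior_shape)
  if (q[["lower"]] > 0) {
    unname(q[["lower"]])
  } else if (q[["upper"]] < 0) {
    unname(q[["upper"]])
  } else {
    0
  }
}

# Vectorized analytic score used by call_contrast().
gfold_score_vec <- function(count_a, count_b, size_a, size_b,
                            quantile = 0.01, prior_shape = 1) {
  off <- log2(size_a / size_b)
  lo <- qbeta(quantile, count_b + prior_shape, count_a + prior_shape)
  hi <- qbeta(1 - quantile, count_b + prior_shape, count_a + prior_shape)
  L_lo <- log2(lo / (1 - lo)) + off
  L_hi <- log2(hi / (1 - hi)) + off
  ifelse(L_lo > 0, L_lo, ifelse(L_hi < 0, L_hi, 0))
}

#' Define a two-library contrast
#'
#' @param baseline_library,treated_library Library identifiers; fold changes
#'   are treated over baseline.
#' @param label Optional display label.
#' @return An object of class `fc_contrast`.
#' @export
de_contrast <- function(baseline_library, treated_library, label = NULL) {
  if (identical(baseline_library, treated_library)) {
    stopf("contrast error: the two libraries must differ")
  }
  structure(
    list(baseline_library = baseline_library,
         treated_library = treated_library,
         label = label %||% sprintf("%s vs %s", treated_library,
                                    baseline_library)),
    class = "fc_contrast"
  )
}

#' Call differential expression for one contrast
#'
#' Scores every (non-spike-in) gene of the count matrix with the analytic
#' generalized fold-change score and applies the `+/- gfold_cutoff` decision
#' rule: `up` when score >= cutoff, `down` when score <= -cutoff, otherwise
#' `unchanged`. Effective library sizes come from the anchor gene
#' (`size_method = "actb"`, consistent with the anchored normalization) or
#' from total non-spike-in counts (`"total"`).
#'
#' @param counts Count matrix (genes should already be filtered for low
#'   expression).
#' @param contrast An [de_contrast()] object.
#' @param config An [run_config()] object.
#' @return A data frame of class `fc_de` with columns `gene_id`, `score`,
#'   `log2fc_point` (log2 ratio of prior-posterior mean rates) and `call`,
#'   with the contrast label as attribute `"label"`. A summary of up/down
#'   counts is emitted as a message.
#' @export
call_contrast <- function(counts, contrast, config = run_config()) {
  assert_count_matrix(counts)
  stopifnot(inherits(contrast, "fc_contrast"), inherits(config, "fc_config"))
  libs <- c(contrast$baseline_library, contrast$treated_library)
  missing_lib <- setdiff(libs, colnames(counts))
  if (length(missing_lib) > 0L) {
    stopf("contrast error: unknown library %s",
          paste(missing_lib, collapse = ", "))
  }
  spike <- is_spikein_id(rownames(counts), config$spikein_pattern)
  genes <- rownames(counts)[!spike]
  sizes <- effective_sizes(counts, config)[libs]
  if (length(genes) == 0L) {
    res <- data.frame(gene_id = character(0), score = numeric(0),
                      log2fc_point = numeric(0), call = character(0),
                      stringsAsFactors = FALSE)
    return(structure(res, class = c("fc_de", "data.frame"),
                     label = contrast$label))
  }
  ca <- counts[genes, contrast$baseline_library]
  cb <- counts[genes, contrast$treated_library]
  score <- gfold_score_vec(ca, cb, sizes[1L], sizes[2L],
                           quantile = config$gfold_quantile,
                           prior_shape = config$prior_shape)
  pr <- config$prior_shape
  log2fc_point <- log2(((cb + pr) / sizes[2L]) / ((ca + pr) / sizes[1L]))
  call <- ifelse(score >= config$gfold_cutoff, "up",
                 ifelse(score <= -config$gfold_cutoff, "down", "unchanged"))
  message(sprintf("[%s] %d genes: %d up, %d down at |score| >= %g",
                  contrast$label, length(genes), sum(call == "up"),
                  sum(call == "down"), config$gfold_cutoff))
  res <- data.frame(gene_id = genes, score = unname(score),
                    log2fc_point = unname(log2fc_point), call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("fc_de", "data.frame"), label = contrast$label)
}

# Effective library sizes for the fold-change posterior.
effective_sizes <- function(counts, config) {
  if (config$size_method == "actb") {
    if (!config$actb_gene_id %in% rownames(counts)) {
      stopf("size error: anchor gene '%s' absent; use size_method = \"total\"",
            config$actb_gene_id)
    }
    sz <- counts[config$actb_gene_id, ]
    if (any(sz <= 0)) {
      stopf("size error: anchor gene '%s' has zero count in library %s",
            config$actb_gene_id,
            paste(colnames(counts)[sz <= 0], collapse = ", "))
    }
    sz
  } else {
    spike <- is_spikein_id(rownames(counts), config$spikein_pattern)
    colSums(counts[!spike, , drop = FALSE])
  }
}
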