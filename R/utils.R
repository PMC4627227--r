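# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# TRUE for rows of a count matrix that are spike-in species.
is_spikein_id <- function(ids, pattern = "^ERCC-") {
  grepl(pattern, ids)
}

assert_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("%s must be a numeric matrix", what)
  }
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stopf("%s must have gene row names and library column names", what)
  }
  if (anyNA(counts)) {
    stopf("%s contains NA values", what)
  }
  if (any(counts < 0)) {
    stopf("%s contains negative values", what)
  }
  invisible(counts)
}
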