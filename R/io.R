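#' Read a gene-by-library count table
#'
#' Expects a tab-separated file with a header row of library identifiers,
#' gene identifiers in the first column, and non-negative integer cells.
#' Lines starting with `#` (reproducibility headers) are skipped. Malformed
#' input is rejected with an error naming the offending row and column;
#' nothing is silently coerced.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with gene row names and library column names.
#' @seealso [write_count_table()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, dimnames = list(c("g1", "g2"), c("A", "B")))
#' write_count_table(m, tf)
#' identical(read_count_table(tf), m)
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stopf("count table format error: need a gene-id column plus >=1 library column in '%s'", path)
  }
  lib_ids <- colnames(df)[-1L]
  header_numeric <- suppressWarnings(!is.na(as.numeric(lib_ids)))
  if (all(header_numeric)) {
    stopf("count table format error: missing header row in '%s'", path)
  }
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stopf("count table error: duplicate gene id(s) %s in '%s'",
          paste(unique(dup), collapse = ", "), path)
  }
  mat <- matrix(NA_integer_, nrow = nrow(df), ncol = length(lib_ids),
                dimnames = list(gene_ids, lib_ids))
  for (j in seq_along(lib_ids)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad) > 0L) {
      stopf("count table parse error: non-integer cell '%s' at gene '%s', library '%s'",
            raw[bad[1L]], gene_ids[bad[1L]], lib_ids[j])
    }
    neg <- which(num < 0)
    if (length(neg) > 0L) {
      stopf("count table error: negative count at gene '%s', library '%s'",
            gene_ids[neg[1L]], lib_ids[j])
    }
    mat[, j] <- as.integer(num)
  }
  mat
}

#' Write a count table to TSV
#'
#' @param counts Integer matrix with gene row names and library column names.
#' @param path Output path.
#' @param config Optional [run_config()] whose parameters are embedded as a
#'   `#`-prefixed reproducibility header.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path, config = NULL) {
  assert_count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' genes, tab-separated. Duplicate members within a line are collapsed;
#' sets left empty are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @seealso [write_gene_sets()]
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(), names = character(0)))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || !nzchar(fields[1L])) {
      stopf("GMT parse error at line %d of '%s': need at least name and description", i, path)
    }
    nms[i] <- fields[1L]
    genes <- fields[-(1:2)]
    genes <- unique(genes[nzchar(genes)])
    sets[[i]] <- genes
  }
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    stopf("GMT error: duplicate gene-set name(s) %s in '%s'",
          paste(unique(dup), collapse = ", "), path)
  }
  names(sets) <- nms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d empty gene set(s): %s",
                    sum(empty), paste(nms[empty], collapse = ", ")),
            call. = FALSE)
    sets <- sets[!empty]
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)) || length(sets) == 0L)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pathway network to disk
#'
#' For `format = "edge_list_tsv"` two files are written: an edge table
#' (`pathway_a`, `pathway_b`, `shared_gene_count`, `shared_gene_ids`) at
#' `path` and a node table (`pathway`, `de_gene_count`, `q_value`) at
#' `node_path`. For `format = "graphml"` the graph is serialized as GraphML
#' (which cannot carry the comment header).
#'
#' @param network An igraph object from [build_pathway_network()].
#' @param path Output path for the edge list (or the GraphML file).
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @param node_path Node-table path; defaults to `path` with a `_nodes.tsv`
#'   suffix.
#' @param config Optional [run_config()] embedded as a header in the TSVs.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path,
                          format = c("edge_list_tsv", "graphml"),
                          node_path = NULL, config = NULL) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(network))
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  if (is.null(node_path)) {
    node_path <- paste0(sub("\\.tsv$", "", path), "_nodes.tsv")
  }
  edges <- network_edge_table(network)
  nodes <- network_node_table(network)
  for (job in list(list(f = path, d = edges), list(f = node_path, d = nodes))) {
    con <- file(job$f, "w")
    writeLines(config_header(config), con)
    write.table(job$d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read a pathway-network edge list written by [write_network()]
#'
#' @param path Path to the edge TSV.
#' @return A data frame with columns `pathway_a`, `pathway_b`,
#'   `shared_gene_count`, `shared_gene_ids`.
#' @export
read_network_edges <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer", "character"))
  expected <- c("pathway_a", "pathway_b", "shared_gene_count", "shared_gene_ids")
  if (!identical(colnames(df), expected)) {
    stopf("edge list format error in '%s': expected columns %s",
          path, paste(expected, collapse = ", "))
  }
  df
}

network_edge_table <- function(network) {
  if (igraph::ecount(network) == 0L) {
    return(data.frame(pathway_a = character(0), pathway_b = character(0),
                      shared_gene_count = integer(0),
                      shared_gene_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_data_frame(network, what = "edges")
  data.frame(pathway_a = el$from, pathway_b = el$to,
             shared_gene_count = as.integer(el$weight),
             shared_gene_ids = el$shared_genes,
             stringsAsFactors = FALSE)
}

network_node_table <- function(network) {
  if (igraph::vcount(network) == 0L) {
    return(data.frame(pathway = character(0), de_gene_count = integer(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  vs <- igraph::as_data_frame(network, what = "vertices")
  data.frame(pathway = vs$name, de_gene_count = as.integer(vs$de_gene_count),
             q_value = vs$q_value, stringsAsFactors = FALSE)
}
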