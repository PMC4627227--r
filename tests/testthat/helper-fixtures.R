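# Shared fixtures and independent oracles used across the suite.

# Small labelled count matrix.
make_counts <- function(values, genes, libs) {
  matrix(as.integer(values), nrow = length(genes),
         dimnames = list(genes, libs))
}

# Seeded random count matrix with an ACTB anchor row.
random_counts <- function(seed, n_genes = 30, n_libs = 4) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_libs, lambda = 200), nrow = n_genes,
              dimnames = list(c("ACTB", sprintf("g%03d", seq_len(n_genes - 1))),
                              paste0("L", seq_len(n_libs))))
  storage.mode(m) <- "integer"
  m
}

# Brute-force Monte-Carlo posterior-quantile oracle, independent of the
# package's analytic path.
mc_posterior_quantiles <- function(ca, cb, sa, sb, q = 0.01, n = 1e6,
                                   seed = 123) {
  set.seed(seed)
  la <- rgamma(n, ca + 1, 1) / sa
  lb <- rgamma(n, cb + 1, 1) / sb
  unname(quantile(log2(lb / la), c(q, 1 - q, 0.5)))
}

mc_gfold_score <- function(ca, cb, sa, sb, q = 0.01, n = 1e6, seed = 123) {
  v <- mc_posterior_quantiles(ca, cb, sa, sb, q, n, seed)
  if (v[1] > 0) v[1] else if (v[2] < 0) v[2] else 0
}

# Union-find connected-component oracle over an edge list of vertex ids.
union_find_components <- function(vertices, edges_from, edges_to) {
  parent <- setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    ra <- find(edges_from[i]); rb <- find(edges_to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(vertices, find, character(1))))
}

# Exhaustive hypergeometric upper-tail probability by summing the exact
# probability of every achievable overlap.
enum_hyper_tail <- function(k, K, N, n) {
  js <- seq(max(0, n - (N - K)), min(K, n))
  p_each <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(p_each[js >= k])
}
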