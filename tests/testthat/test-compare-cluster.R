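# Build an fc_de result directly from call vectors.
fake_de <- function(universe, up = character(0), down = character(0)) {
  structure(
    data.frame(gene_id = universe,
               score = ifelse(universe %in% up, 1,
                              ifelse(universe %in% down, -1, 0)),
               log2fc_point = 0, # unused by classification
               call = ifelse(universe %in% up, "up",
                             ifelse(universe %in% down, "down", "unchanged")),
               stringsAsFactors = FALSE),
    class = c("fc_de", "data.frame"), label = "fake"
  )
}

test_that("classification follows the Venn set algebra", {
  universe <- letters[1:6]
  sr <- fake_de(universe, up = c("a", "b"))
  sen <- fake_de(universe, up = c("b", "c"))
  cats <- classify_de_genes(sr, sen)
  expect_identical(cats$sets$up_both, "b")
  expect_identical(cats$sets$up_SR_only, "a")
  expect_identical(cats$sets$up_SEN_only, "c")
  expect_equal(cats$counts[["down_both"]], 0)
  expect_equal(cats$proportions[["up_both"]], 1 / 6)

  # empty calls give empty categories
  cats0 <- classify_de_genes(fake_de(universe), fake_de(universe))
  expect_true(all(cats0$counts == 0))

  # mismatched universes are rejected
  expect_error(classify_de_genes(sr, fake_de(letters[2:7])),
               "different gene universes")
})

test_that("discordant genes join both one-state sets and are flagged", {
  universe <- letters[1:5]
  sr <- fake_de(universe, up = "a")
  sen <- fake_de(universe, down = "a")
  cats <- classify_de_genes(sr, sen)
  expect_identical(cats$sets$up_SR_only, "a")
  expect_identical(cats$sets$down_SEN_only, "a")
  expect_identical(cats$discordant, "a")
  # up sets are pairwise disjoint, and likewise down sets
  up <- cats$sets[c("up_both", "up_SR_only", "up_SEN_only")]
  expect_equal(length(unlist(up)), length(unique(unlist(up))))
})

test_that("category counts are invariant to gene input order", {
  set.seed(14)
  universe <- sprintf("g%02d", 1:40)
  sr <- fake_de(universe, up = sample(universe, 10),
                down = sample(setdiff(universe, sprintf("g%02d", 1:10)), 5))
  sen <- fake_de(universe, up = sample(universe, 8))
  perm <- sample(seq_along(universe))
  sr_p <- sr[perm, ]
  class(sr_p) <- class(sr)
  cats1 <- classify_de_genes(sr, sen)
  cats2 <- classify_de_genes(sr_p, sen)
  expect_identical(cats1$sets, cats2$sets)
})

test_that("condition distances behave as 1 - Spearman on log profiles", {
  e <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(3, 2, 1))
  rownames(e) <- paste0("g", 1:3)
  d <- condition_distance_matrix(e)
  expect_equal(unname(d["A", "B"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["A", "C"]), 2, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  flat <- cbind(A = c(1, 1, 1), B = c(1, 2, 3))
  rownames(flat) <- paste0("g", 1:3)
  expect_error(condition_distance_matrix(flat), "degenerate.*A")
})

test_that("Spearman distances are invariant to monotone library transforms", {
  set.seed(9)
  for (i in 1:10) {
    e <- matrix(rlnorm(4 * 50, 2, 1), ncol = 4,
                dimnames = list(paste0("g", 1:50), paste0("L", 1:4)))
    d1 <- condition_distance_matrix(e)
    e2 <- e
    e2[, 2] <- e2[, 2]^1.7 # strictly monotone transform of one library
    d2 <- condition_distance_matrix(e2)
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("clustering merges identical conditions first and is label-stable", {
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  hc <- cluster_conditions(d)
  expect_equal(hc$height[1], 0)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("X", "Y"))
  expect_identical(outlier_condition(hc), "Z")

  # permuting the input order leaves the merge topology unchanged
  perm <- c(3, 1, 2)
  hc2 <- cluster_conditions(d[perm, perm])
  expect_identical(outlier_condition(hc2), "Z")
  expect_equal(sort(hc$height), sort(hc2$height))

  bad <- d
  bad[1, 2] <- 5
  expect_error(cluster_conditions(bad), "symmetric")
})

test_that("dendrograms export as Newick text", {
  d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  txt <- dendrogram_newick(cluster_conditions(d))
  expect_match(txt, "^\\(")
  expect_match(txt, "Z")
  tf <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(cluster_conditions(d), tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, c("X", "Y", "Z"))
})

test_that("heatmap tables group genes and preserve category sizes", {
  universe <- sprintf("g%02d", 1:20)
  sr <- fake_de(universe, up = universe[1:4], down = universe[11:13])
  sen <- fake_de(universe, up = universe[3:6])
  cats <- classify_de_genes(sr, sen)
  e <- matrix(rlnorm(20 * 4), ncol = 4,
              dimnames = list(universe, paste0("L", 1:4)))
  tab <- heatmap_groups(cats, e)
  expect_equal(unname(table(tab$group)[names(cats$sets[cats$counts > 0])]),
               unname(cats$counts[cats$counts > 0]),
               ignore_attr = TRUE)
  # within a group, mean expression is non-increasing
  for (grp in unique(tab$group)) {
    sub <- tab[tab$group == grp, -(1:2), drop = FALSE]
    expect_true(all(diff(rowMeans(as.matrix(sub))) <= 1e-12))
  }
  # empty categories give an empty table
  cats0 <- classify_de_genes(fake_de(universe), fake_de(universe))
  expect_equal(nrow(heatmap_groups(cats0, e)), 0)
})

test_that("programmed categories are recovered on a clean simulation", {
  spec <- default_de_spec()
  spec$n <- c(80L, 80L, 80L, 80L, 80L, 80L)
  spec$log2fc_SR <- c(3, 3, 0, -3, -3, 0)
  spec$log2fc_SEN <- c(4, 0, 4, -4, 0, -4)
  des <- simulation_design(n_genes = 1000, de_spec = spec, seed = 17)
  e <- generate_experiment(des)
  res <- suppressMessages(analyze_experiment(e, run_config(seed = 17)))
  tru <- split(e$truth$gene_id, e$truth$category)
  for (nm in names(res$categories$sets)) {
    jac <- length(intersect(res$categories$sets[[nm]], tru[[nm]])) /
      length(union(res$categories$sets[[nm]], tru[[nm]]))
    expect_gte(jac, 0.8)
  }
})
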