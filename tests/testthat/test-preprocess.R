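test_that("anchor scaling reproduces hand-computed factors", {
  m2 <- make_counts(c(100, 300), "ACTB", c("A", "B"))
  s2 <- compute_actb_scaling(m2)
  expect_equal(s2$factor, c(2, 2 / 3), tolerance = 1e-12)

  m3 <- make_counts(c(100, 200, 400), "ACTB", c("A", "B", "C"))
  s3 <- compute_actb_scaling(m3)
  expect_equal(round(s3$factor, 4), c(2.3333, 1.1667, 0.5833))

  meq <- make_counts(c(50, 50, 50), "ACTB", c("A", "B", "C"))
  expect_equal(compute_actb_scaling(meq)$factor, c(1, 1, 1))
})

test_that("missing or zero anchor raises a normalization error naming the library", {
  m <- make_counts(c(10, 0), "ACTB", c("A", "B"))
  expect_error(compute_actb_scaling(m), "zero count in library B")
  m2 <- make_counts(c(5, 6), "g1", c("A", "B"))
  expect_error(compute_actb_scaling(m2), "absent")
})

test_that("normalized expression applies e = c * s / l cellwise", {
  counts <- make_counts(c(500, 100, 250, 300), c("ACTB", "g1"), c("A", "B"))
  ann <- data.frame(gene_id = c("ACTB", "g1"), length = c(1000, 1))
  # identity when s = 1, l = 1
  s1 <- data.frame(library_id = c("A", "B"), actb_count = c(1, 1),
                   factor = c(1, 1))
  ann1 <- data.frame(gene_id = c("ACTB", "g1"), length = c(1, 1))
  e1 <- normalize_expression(counts, ann1, s1)
  expect_equal(unname(e1[, ]), unname(counts[, ] * 1.0))

  # direct evaluation: c = 500, s = 2, l = 1000 -> 1.0
  s2 <- data.frame(library_id = c("A", "B"), actb_count = c(500, 250),
                   factor = c(2, 4))
  e2 <- normalize_expression(counts, ann, s2)
  expect_equal(e2["ACTB", "A"], 1.0)

  # anchor row is constant and equals mean raw anchor count / length
  sc <- compute_actb_scaling(counts)
  e3 <- normalize_expression(counts, ann, sc)
  expect_equal(unname(e3["ACTB", "A"]), unname(e3["ACTB", "B"]))
  expect_equal(unname(e3["ACTB", "A"]), mean(counts["ACTB", ]) / 1000)

  expect_error(normalize_expression(counts, ann[1, ], sc), "annotation error")
})

test_that("anchored scaling conserves c_ACTB * s across libraries", {
  for (seed in 1:25) {
    m <- random_counts(seed)
    sc <- compute_actb_scaling(m)
    prod <- sc$actb_count * sc$factor
    expect_lt(max(abs(prod - mean(m["ACTB", ])) / mean(m["ACTB", ])), 1e-9)
  }
})

test_that("rescaling one library's counts rescales all normalized values by
           one common constant (relative structure is invariant)", {
  m <- random_counts(99)
  ann <- data.frame(gene_id = rownames(m), length = seq(100, by = 7,
                                                        length.out = nrow(m)))
  e <- normalize_expression(m, ann, compute_actb_scaling(m))
  m2 <- m
  m2[, 2] <- m2[, 2] * 3L
  e2 <- normalize_expression(m2, ann, compute_actb_scaling(m2))
  # the cross-library anchor mean picks up the rescaled library, so every
  # cell scales by the same factor mean'/mean; ratios are untouched
  ratio <- e2 / e
  expect_lt(diff(range(ratio)), 1e-9)
  expect_equal(e2[, 2] / e2[, 1], e[, 2] / e[, 1], tolerance = 1e-12)
})

test_that("CPM filter follows the strict < threshold rule and scope", {
  # all-zero gene removed
  m <- make_counts(c(0, 10, 990, # library A
                     0, 20, 1980), # library B
                   c("gz", "g1", "g2"), c("A", "B"))
  f <- filter_low_expression(m)
  expect_true("gz" %in% f$removed)

  # CPM exactly 1 is retained (strict "< 1 removed")
  m1 <- matrix(c(1L, 999999L, 1L, 999999L), nrow = 2,
               dimnames = list(c("g1", "g2"), c("A", "B")))
  f1 <- filter_low_expression(m1, cpm_threshold = 1)
  expect_true("g1" %in% rownames(f1$retained))

  # scope: CPM 5 in one library, 0 elsewhere
  m2 <- matrix(c(5L, 999995L, 0L, 1000000L, 0L, 1000000L, 0L, 1000000L),
               nrow = 2, dimnames = list(c("g1", "rest"),
                                         c("A", "B", "C", "D")))
  expect_true("g1" %in% rownames(filter_low_expression(m2,
                                                       scope = "any_library")$retained))
  expect_true("g1" %in% filter_low_expression(m2,
                                              scope = "all_libraries")$removed)
})

test_that("CPM filter exempts spike-ins and is idempotent", {
  m <- rbind(random_counts(12),
             make_counts(c(0, 0, 0, 0), "ERCC-0001", paste0("L", 1:4)))
  storage.mode(m) <- "integer"
  f1 <- filter_low_expression(m)
  expect_true("ERCC-0001" %in% rownames(f1$retained))
  f2 <- filter_low_expression(f1$retained)
  expect_identical(f2$retained, f1$retained)
  expect_length(f2$removed, 0)
})

test_that("spike-in QC recovers proportionality and flags shuffled libraries", {
  sp <- spikein_table(n_spikein = 20, seed = 6)
  # observed exactly proportional to expected, large counts
  obs <- matrix(as.integer(round(sp$expected_concentration * 1e3)), ncol = 1,
                dimnames = list(sp$species_id, "L1"))
  qc <- ercc_qc(obs, sp)
  expect_gt(qc$pearson_r, 0.999)
  expect_equal(qc$slope, 1, tolerance = 0.05)
  expect_false(qc$flagged)

  # permuted observations lose the relationship and get flagged
  set.seed(31)
  sp92 <- spikein_table(seed = 44)
  rs <- replicate(200, {
    shuffled <- matrix(as.integer(round(sample(sp92$expected_concentration) * 50)),
                       ncol = 1, dimnames = list(sp92$species_id, "L1"))
    ercc_qc(shuffled, sp92)$pearson_r
  })
  expect_lt(quantile(abs(rs), 0.99), 0.5)
  expect_true(all(rs < 0.9)) # every shuffled library is flagged

  # fewer than three species is a precondition error
  expect_error(ercc_qc(obs[1:2, , drop = FALSE], sp), ">= 3")
  # all-equal observations give a degenerate fit
  flat <- matrix(5L, nrow = 20, ncol = 1,
                 dimnames = list(sp$species_id, "L1"))
  expect_error(ercc_qc(flat, sp), "degenerate")
})
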