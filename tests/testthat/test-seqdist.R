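write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("read_fasta parses and normalizes", {
  aln <- read_fasta(write_tmp_fasta(c(">a", "ACGT", ">b", "ACGA")))
  expect_equal(dim(aln), c(2L, 4L))
  expect_equal(rownames(aln), c("a", "b"))

  low <- read_fasta(write_tmp_fasta(c(">x", "acgu")))
  expect_equal(unname(low[1, ]), c("A", "C", "G", "T"))
})

test_that("read_fasta rejects ragged and illegal input", {
  expect_error(read_fasta(write_tmp_fasta(c(">a", "ACGT", ">b", "ACG"))),
               "ragged")
  expect_error(read_fasta(write_tmp_fasta(c(">a", "ACXT"))), "illegal")
  expect_error(read_fasta(write_tmp_fasta(character(0))), "empty|parse")
})

test_that("haplotype collapsing keeps first occurrences and is idempotent", {
  aln <- new_alignment(matrix(c("A", "C", "G", "T",
                                "A", "C", "G", "T",
                                "A", "C", "G", "A"),
                              nrow = 3, byrow = TRUE,
                              dimnames = list(c("a", "b", "c"), NULL)))
  coll <- collapse_haplotypes(aln)
  expect_equal(rownames(coll$alignment), c("a", "c"))
  expect_equal(coll$map, list(a = c("a", "b"), c = "c"))

  again <- collapse_haplotypes(coll$alignment)
  expect_equal(again$alignment, coll$alignment)
  expect_equal(unname(lengths(again$map)), c(1L, 1L))

  # all-distinct input is untouched
  dd <- collapse_haplotypes(aln[c(1, 3), , drop = FALSE])
  expect_equal(nrow(dd$alignment), 2L)
})

test_that("p-distances match hand-computed values under pairwise deletion", {
  aln <- new_alignment(matrix(c("A", "C", "G", "T",
                                "A", "C", "G", "T",
                                "A", "C", "G", "A",
                                "A", "C", "N", "T"),
                              nrow = 4, byrow = TRUE,
                              dimnames = list(letters[1:4], NULL)))
  dm <- p_distance_matrix(aln)
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$d["a", "c"], 0.25)
  # N site excluded: ACNT vs ACGA -> 1 mismatch of 3 compared
  expect_equal(dm$d["c", "d"], 1 / 3)
  expect_equal(dm$sites["c", "d"], 3)
  # symmetry, zero diagonal, bounds
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(dm$d >= 0 & dm$d <= 1))
})

test_that("a pair with zero comparable sites yields NA with a warning", {
  aln <- new_alignment(matrix(c("A", "N", "N", "C"), nrow = 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), NULL)))
  expect_warning(dm <- p_distance_matrix(aln), "zero comparable")
  expect_true(is.na(dm$d["a", "b"]))
})

test_that("p-distances agree with the ape reference on simulated data", {
  sim <- simulate_gmyc_tree(4, 3, seed = 3)
  aln <- simulate_sequences(sim$tree, length = 300, seed = 3)
  dm <- p_distance_matrix(aln)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    strsplit(apply(aln, 1, paste, collapse = ""), "")), model = "raw",
    pairwise.deletion = TRUE))
  expect_equal(dm$d[rownames(ref), colnames(ref)], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("collapsing preserves the set of distinct pairwise distances", {
  sim <- simulate_gmyc_tree(3, 4, seed = 11)
  aln <- simulate_sequences(sim$tree, length = 120, seed = 11)
  dup <- rbind(aln, aln[1:3, ])
  rownames(dup) <- c(rownames(aln), paste0("dup", 1:3))
  dup <- new_alignment(unclass(dup))
  coll <- collapse_haplotypes(dup)
  d_full <- p_distance_matrix(dup)$d
  d_coll <- p_distance_matrix(coll$alignment)$d
  expect_setequal(round(unique(d_full[upper.tri(d_full)]), 12),
                  round(unique(c(0, d_coll[upper.tri(d_coll)])), 12))
})

test_that("partition summary matches hand pooling on a toy 2-species set", {
  aln <- new_alignment(matrix(c("A", "A", "A", "A",
                                "A", "A", "A", "C",
                                "G", "G", "G", "G",
                                "G", "G", "G", "C"),
                              nrow = 4, byrow = TRUE,
                              dimnames = list(c("a1", "a2", "b1", "b2"),
                                              NULL)))
  dm <- p_distance_matrix(aln)
  sm <- partition_distance_summary(
    dm, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  # intra pairs: 0.25, 0.25; inter pairs: 1, 1, 0.75, 1
  expect_equal(sm$intra_max, 0.25)
  expect_equal(sm$intra_p95, 0.25)
  expect_equal(sm$inter_min, 0.75)
  expect_equal(sm$inter_max, 1)
  expect_equal(sm$per_species$n, c(2L, 2L))

  # two species of identical clones
  cl <- new_alignment(matrix(c("A", "A", "A", "A",
                               "A", "A", "A", "A",
                               "A", "C", "A", "A"),
                             nrow = 3, byrow = TRUE,
                             dimnames = list(c("x1", "x2", "y1"), NULL)))
  sm2 <- partition_distance_summary(
    p_distance_matrix(cl), c(x1 = "X", x2 = "X", y1 = "Y"))
  expect_equal(sm2$intra_max, 0)
  expect_equal(sm2$inter_min, 0.25)

  expect_error(partition_distance_summary(dm, c(a1 = "A")), "unassigned")
})

test_that("mean p-distance grows with tree depth on JC simulations", {
  depths <- seq(0.01, 0.4, length.out = 10)
  means <- vapply(seq_along(depths), function(i) {
    tr <- parse_newick(sprintf("(A:%g,B:%g);", depths[i], depths[i]))
    aln <- simulate_sequences(tr, length = 400, seed = 100 + i)
    p_distance_matrix(aln)$d[1, 2]
  }, numeric(1))
  expect_gt(cor(depths, means, method = "spearman"), 0)
})
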