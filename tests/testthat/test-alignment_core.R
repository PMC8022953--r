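write_fasta <- function(ids, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

test_that("reading an aligned FASTA validates shape, ids and alphabet", {
  p <- write_fasta(c("a", "b"), c("AAAA", "AAAA"))
  aln <- read_operon_alignment(p, "16S", c("a", "b"))
  expect_s3_class(aln, "operon_alignment")
  expect_equal(aln$n_columns, 4L)
  expect_equal(nrow(aln$mat), 2L)

  ops <- paste0("rrn", c("A", "B", "C", "D", "E", "G", "H"))
  p <- write_fasta(rev(ops), rep("ACGT", 7))  # file order arbitrary
  aln <- read_operon_alignment(p, "16S", ops)
  expect_identical(aln$operon_ids, ops)
  expect_identical(rownames(aln$mat), ops)

  p <- write_fasta(c("a", "b"), c("ACGTACGTAC", "ACGTACGTA"))
  expect_error(read_operon_alignment(p, "16S", c("a", "b")),
               "alignment-shape")
  p <- write_fasta(c("a", "b"), c("ACGT", "ACGT"))
  expect_error(read_operon_alignment(p, "16S", c("a", "c")), "identity")
  p <- write_fasta(c("a", "a", "b"), c("ACGT", "ACGT", "ACGT"))
  expect_error(read_operon_alignment(p, "16S", c("a", "b")), "identity")
  p <- write_fasta(c("a", "b"), c("ACXT", "ACGT"))
  expect_error(read_operon_alignment(p, "16S", c("a", "b")), "alphabet")
})

test_that("lowercase and U are normalized; N needs the load option", {
  aln <- toy_aln(c("acgu", "ACGT"))
  expect_identical(as.vector(aln$mat[1L, ]), c("A", "C", "G", "T"))
  expect_error(toy_aln(c("ACGN", "ACGT")), "alphabet")
  aln <- operon_alignment(c("ACGN", "ACGT"), "16S", c("a", "b"),
                          allow_N = TRUE)
  expect_equal(heterologous_sites(aln)$positions, integer(0))  # N column excluded
})

test_that("heterologous sites are exactly the polymorphic columns", {
  aln <- toy_aln(c("ACGTAC", "ACGTAC", "ACGTAC"))
  expect_length(heterologous_sites(aln)$positions, 0L)

  aln <- toy_aln(c("ACGTAC", "ACCTAC", "ACGTAT"))
  hs <- heterologous_sites(aln)
  expect_equal(hs$positions, c(3L, 6L))
  expect_identical(as.vector(hs$alleles_at[, "3"]), c("G", "C", "G"))

  # gap vs base is a real (5th) state: indels between copies are indexed
  aln <- toy_aln(c("AC-TAC", "ACGTAC"))
  expect_equal(heterologous_sites(aln)$positions, 3L)
})

test_that("heterologous_sites is empty iff all rows are identical", {
  withr::with_seed(5, {
    for (i in 1:20) {
      inst <- random_small_instance()
      hs <- heterologous_sites(inst$ancestor)
      identical_rows <- all(apply(inst$ancestor$mat, 2L,
                                  function(col) length(unique(col)) == 1L))
      expect_identical(length(hs$positions) == 0L, identical_rows)
    }
  })
})

test_that("pairwise identity uses alignment length as denominator", {
  aln <- toy_aln(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(mean_pairwise_identity(aln)$mean, 100)

  aln <- toy_aln(c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(mean_pairwise_identity(aln)$mean, 90)

  # two aligned gaps match; gap vs base mismatches
  aln <- toy_aln(c("AC--ACGTAC", "AC--ACGTAT"))
  expect_equal(mean_pairwise_identity(aln)$mean, 90)
  aln <- toy_aln(c("AC-TACGTAC", "ACTTACGTAC"))
  expect_equal(mean_pairwise_identity(aln)$mean, 90)
})

test_that("identity matrix is symmetric with unit diagonal, invariant to row order", {
  withr::with_seed(11, {
    inst <- random_small_instance(n_copies = 4L)
    idm <- mean_pairwise_identity(inst$ancestor)
    expect_equal(idm$matrix, t(idm$matrix))
    expect_equal(unname(diag(idm$matrix)), rep(100, 4))
    expect_true(all(idm$matrix >= 0 & idm$matrix <= 100))

    perm <- c(3L, 1L, 4L, 2L)
    aln2 <- operon_alignment(inst$ancestor$mat[perm, ], "toy",
                             inst$ancestor$operon_ids[perm])
    expect_equal(mean_pairwise_identity(aln2)$mean, idm$mean)
  })
})

test_that("identity over concatenated regions is the length-weighted average", {
  withr::with_seed(3, {
    a <- random_small_instance(n_copies = 3L, n_columns = 20L)$ancestor
    b_mat <- random_small_instance(n_copies = 3L, n_columns = 50L)$ancestor$mat
    b <- operon_alignment(b_mat, region_id = "toy2",
                          operon_ids = a$operon_ids)
    ia <- mean_pairwise_identity(a)$mean
    ib <- mean_pairwise_identity(b)$mean
    iab <- mean_pairwise_identity(list(a, b))$mean
    expect_equal(iab, (20 * ia + 50 * ib) / 70)
  })
})

test_that("region maps resolve paths and load ordered alignments", {
  dir <- withr::local_tempdir()
  ops <- c("rrnA", "rrnB")
  writeLines(paste0(">", rev(ops), "\n", c("ACGT", "ACGA")),
             file.path(dir, "r16.fasta"))
  writeLines(c("operons: [rrnA, rrnB]",
               "regions:",
               "  - region_id: 16S",
               "    path: r16.fasta",
               "    type: gene"),
             file.path(dir, "map.yaml"))
  map <- read_region_map(file.path(dir, "map.yaml"))
  alns <- load_region_alignments(map)
  expect_named(alns, "16S")
  expect_identical(alns[["16S"]]$operon_ids, ops)
  expect_identical(unname(alns[["16S"]]$mat["rrnA", 4L]), "A")
})
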