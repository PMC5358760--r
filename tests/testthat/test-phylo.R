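test_that("percent identity distances follow the gap rule", {
  expect_equal(percent_identity_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(percent_identity_distance(c(a = "ACGT", b = "ACGA"))["a", "b"], 25)

  aln <- c(a = "AC-T", b = "ACGT")
  expect_equal(percent_identity_distance(aln, "pairwise_deletion")["a", "b"], 0)
  expect_equal(percent_identity_distance(aln, "count_as_mismatch")["a", "b"], 25)

  # columns gapped in both sequences are never compared
  aln2 <- c(a = "A--T", b = "A-GT")
  expect_equal(percent_identity_distance(aln2, "count_as_mismatch")["a", "b"],
               100 * (1 - 2 / 3))
})

test_that("a pair with no comparable columns names the offenders", {
  aln <- c(x = "AC--", y = "--GT", z = "ACGT")
  expect_error(percent_identity_distance(aln), "x.*y")
})

test_that("malformed alignments are rejected", {
  expect_error(percent_identity_distance(c(a = "ACGT")), "at least 2")
  expect_error(percent_identity_distance(c(a = "ACGT", b = "ACG")),
               "equal length")
})

test_that("three-taxon closed form is reproduced exactly", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  for (i in 1:30) {
    ad <- random_additive(sample(4:8, 1), seed = 700 + i)
    tr <- neighbor_joining(ad$dm)
    expect_equal(phangorn::RF.dist(tr, ad$tree), 0, label = paste("case", i))
    back <- stats::cophenetic(tr)[rownames(ad$dm), colnames(ad$dm)]
    expect_lt(max(abs(back - ad$dm)), 1e-9, label = paste("case", i))
  }
})

test_that("NJ agrees with exhaustive least squares on 5-taxon additive input", {
  for (i in 1:10) {
    ad <- random_additive(5, seed = 800 + i)
    tr <- neighbor_joining(ad$dm)
    best <- ls_best_topology(ad$dm)
    expect_equal(phangorn::RF.dist(tr, best), 0, label = paste("case", i))
  }
})

test_that("NJ agrees with an independent implementation on noisy input", {
  set.seed(81)
  ad <- random_additive(7, seed = 81)
  noisy <- ad$dm + matrix(stats::runif(49, 0, 0.2), 7, 7)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  tr <- neighbor_joining(noisy)
  ref <- ape::nj(as.dist(noisy))
  expect_equal(phangorn::RF.dist(tr, ref), 0)
})

test_that("equidistant taxa give a valid deterministic tree", {
  dm <- matrix(5, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(dm) <- 0
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, letters[1:5])
  expect_true(all(t1$edge.length >= 0))
})

test_that("negative branch lengths are clamped and logged", {
  # a non-additive matrix known to produce a negative NJ branch
  dm <- matrix(c(0, 1, 10, 10,
                 1, 0, 10, 10,
                 10, 10, 0, 0.1,
                 10, 10, 0.1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(dm)
  expect_true(all(tr$edge.length >= 0))
  cl <- attr(tr, "clamped")
  if (!is.null(cl)) expect_true(all(cl$original < 0))
})

test_that("invalid distance matrices are rejected", {
  dm <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(dm), "at least 3")
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- matrix(c(0, -1, 2, -1, 0, 4, 2, 4, 0), 3, 3)
  expect_error(neighbor_joining(neg), "non-negative")
})

test_that("alignment readers and Newick round-trip are lossless", {
  dir <- withr::local_tempdir()
  fam <- simulate_element_family(rand_dna(60, seed = 82), n = 5,
                                 divergence = 0.1, seed = 82)
  fa <- file.path(dir, "aln.fa")
  Biostrings::writeXStringSet(fam, fa)
  aln <- read_alignment(fa)
  expect_length(aln, 5)
  expect_identical(unname(nchar(aln)), rep(60L, 5))

  dm <- percent_identity_distance(aln)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  tr <- neighbor_joining(dm)
  p1 <- file.path(dir, "t1.nwk"); p2 <- file.path(dir, "t2.nwk")
  write_newick(tr, p1)
  write_newick(read_newick(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  tsv <- file.path(dir, "dm.tsv")
  write_distance_tsv(dm, tsv)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), dm, ignore_attr = TRUE)
})
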