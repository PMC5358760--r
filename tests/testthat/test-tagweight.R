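test_that("uniform scheme splits weight c/m over matches", {
  ts <- make_tag_set(4, list(list(start = c(100L, 5000L))))
  pl <- assign_weights(ts, "uniform")
  expect_equal(pl$weight, c(2, 2))

  # enumeration: total weight equals the sum of multiplicities
  ts <- make_tag_set(c(6, 2, 2),
                     list(list(start = c(100L, 2000L, 9000L)),
                          list(start = 500L),
                          list(start = c(3000L, 7000L))))
  pl <- assign_weights(ts, "uniform")
  expect_equal(sum(pl$weight), 10)
})

test_that("EM converges to the unique-coverage fixed point", {
  # two repeat copies whose unique flanking coverage is 9:1
  ts <- make_tag_set(c(9, 1, 10),
                     list(list(start = 900L),
                          list(start = 5900L),
                          list(start = c(1000L, 6000L))))
  pl <- assign_weights(ts, "em")
  w <- pl$weight[pl$tag_id == 3]
  expect_equal(w, c(9, 1), tolerance = 1e-6)
  expect_equal(sum(pl$weight), 20)
})

test_that("EM with no unique tags warns and falls back to uniform", {
  ts <- make_tag_set(8, list(list(start = c(100L, 5000L))))
  expect_warning(pl <- assign_weights(ts, "em"), "uniform")
  expect_equal(pl$weight, c(4, 4))
})

test_that("a tag with an empty match list is an error", {
  ts <- make_tag_set(c(2, 3), list(list(start = 100L), list(start = 200L)))
  ts$matches <- ts$matches[ts$matches$tag_id != 2, ]
  expect_error(assign_weights(ts, "uniform"), "empty match list")
})

test_that("weight conservation holds for random tag sets under both schemes", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50
    cvals <- sample(1:6, n, replace = TRUE)
    mlist <- lapply(seq_len(n), function(i) {
      m <- sample(1:4, 1)
      list(start = sort(sample.int(90000L, m)))
    })
    ts <- make_tag_set(cvals, mlist)
    for (scheme in c("uniform", "em")) {
      pl <- assign_weights(ts, scheme)
      expect_equal(sum(pl$weight), sum(cvals), tolerance = 1e-9)
      # per-tag conservation, not just in aggregate
      per <- rowsum(pl$weight, pl$tag_id)
      expect_equal(as.numeric(per), as.numeric(cvals), tolerance = 1e-9)
    }
  }
})

test_that("when every tag maps uniquely both schemes equal plain pileup", {
  set.seed(32)
  ts <- make_tag_set(sample(1:4, 30, replace = TRUE),
                     lapply(1:30, function(i) list(start = i * 100L)))
  pu <- assign_weights(ts, "uniform")
  pe <- assign_weights(ts, "em")
  expect_identical(pu$weight, as.numeric(ts$tags$c))
  expect_identical(pe$weight, pu$weight)
})

test_that("coverage binning prorates placements and conserves mass", {
  pl1 <- data.frame(contig = "c1", start = 20L, end = 30L, strand = "+",
                    tag_id = 1L, weight = 1)
  cov <- build_coverage(pl1, c(c1 = 100L), bin_size = 10)
  expect_equal(cov$bins$c1, c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))

  pl2 <- data.frame(contig = "c1", start = 25L, end = 35L, strand = "+",
                    tag_id = 1L, weight = 2)
  cov <- build_coverage(pl2, c(c1 = 100L), bin_size = 10)
  expect_equal(cov$bins$c1[3:4], c(1, 1))

  set.seed(33)
  ts <- make_tag_set(sample(1:5, 40, replace = TRUE),
                     lapply(1:40, function(i)
                       list(start = sample.int(9000L, sample(1:3, 1)))))
  pl <- assign_weights(ts, "uniform")
  cov <- build_coverage(pl, c(c1 = 100000L), bin_size = 10)
  expect_equal(sum(cov$bins$c1), sum(ts$tags$c) * 36 / 10, tolerance = 1e-9)
  expect_equal(cov$total_weight, sum(ts$tags$c))
})

test_that("bedGraph write/read round-trips the track", {
  set.seed(34)
  ts <- make_tag_set(sample(1:3, 20, replace = TRUE),
                     lapply(1:20, function(i) list(start = i * 400L)))
  cov <- build_coverage(assign_weights(ts, "uniform"), c(c1 = 100000L))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, path)
  back <- read_bedgraph(path, contig_lengths = cov$contig_lengths)
  expect_equal(back$bins$c1, cov$bins$c1, tolerance = 1e-6)
  expect_equal(back$bin_size, cov$bin_size)
  expect_equal(back$tag_length, cov$tag_length)
})

test_that("conservation report flags exact weight conservation", {
  ts <- make_tag_set(c(3, 5), list(list(start = c(10L, 600L)),
                                   list(start = 2000L)))
  pl <- assign_weights(ts, "uniform")
  path <- withr::local_tempfile(fileext = ".json")
  rep <- conservation_report(ts, pl, path)
  expect_true(rep$conserved)
  expect_equal(jsonlite::read_json(path)$sum_weights, 8)
})

test_that("SAM input reconstructs multiplicity and match counts", {
  seq1 <- rand_dna(36, seed = 35)
  seq2 <- rand_dna(36, seed = 36)
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:10000",
    sprintf("r1\t0\tc1\t101\t255\t36M\t*\t0\t0\t%s\t%s\tNH:i:1", seq1, strrep("I", 36)),
    sprintf("r2\t0\tc1\t101\t255\t36M\t*\t0\t0\t%s\t%s\tNH:i:1", seq1, strrep("I", 36)),
    sprintf("r3\t0\tc1\t501\t255\t36M\t*\t0\t0\t%s\t%s\tNH:i:2", seq2, strrep("I", 36)),
    sprintf("r3\t256\tc1\t901\t255\t36M\t*\t0\t0\t%s\t%s\tNH:i:2", seq2, strrep("I", 36))
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  ts <- read_tags_bam(path)
  expect_equal(nrow(ts$tags), 2)
  t1 <- ts$tags[ts$tags$seq == seq1, ]
  t2 <- ts$tags[ts$tags$seq == seq2, ]
  expect_equal(t1$c, 2); expect_equal(t1$m, 1)
  expect_equal(t2$c, 1); expect_equal(t2$m, 2)
})
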