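test_that("zero-divergence repeat copies are byte-identical to the consensus", {
  cons <- rand_dna(300, seed = 10)
  spec <- genome_spec(contigs = c(chr1 = 20000L),
                      repeat_families = list(list(name = "f", consensus = cons,
                                                  copy_number = 3L,
                                                  divergence = 0)),
                      seed = 10)
  g <- generate_genome(spec)
  expect_equal(nrow(g$repeats), 3)
  for (i in 1:3) {
    got <- as.character(Biostrings::subseq(g$sequences[["chr1"]],
                                           g$repeats$start[i] + 1,
                                           g$repeats$end[i]))
    expect_identical(got, cons)
  }
})

test_that("same spec and seed reproduce genome and manifest bit-exactly", {
  spec <- example_genome_spec("polr3e_like", seed = 77)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$manifest, g2$manifest)
})

test_that("copy divergence matches the binomial expectation", {
  cons <- rand_dna(260, seed = 11)
  fam <- simulate_element_family(cons, n = 100, divergence = 0.1, seed = 11)
  ident <- vapply(as.character(fam), function(s) {
    mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]])
  }, numeric(1))
  # per-base substitution at p = 0.1 -> mean identity 90%, binomial sd
  exp_mean <- 0.9
  sd_mean <- sqrt(0.1 * 0.9 / 260) / sqrt(100)
  expect_lt(abs(mean(ident) - exp_mean), 3 * sd_mean)
})

test_that("element family respects planted boxes and trivial cases", {
  cons <- rand_dna(150, seed = 12)
  one <- simulate_element_family(cons, n = 1, divergence = 0, seed = 1)
  expect_identical(as.character(one)[[1]], cons)

  fam <- simulate_element_family(cons, n = 20, divergence = 0.05,
                                 plant_boxes = list(a_box = "TGGCTTAGTACG",
                                                    spacer = 25,
                                                    b_box = "GTTCGAATC"),
                                 seed = 3)
  hits <- lapply(as.character(fam), scan_promoters, model = strict_mir_model())
  expect_true(all(vapply(hits, nrow, integer(1)) >= 1))
  expect_true(all(vapply(hits, function(h) 25 %in% h$spacer, logical(1))))
})

test_that("ground-truth manifest records every planted feature", {
  spec <- example_genome_spec("funnel", seed = 13)
  g <- generate_genome(spec)
  expect_identical(g$manifest$pol3_units, spec$pol3_units)
  expect_equal(nrow(g$manifest$roadblocks), nrow(spec$roadblocks))
  expect_equal(nrow(g$manifest$genes), length(spec$genes))
  # resolved windows abut the unit boundary facing the host TSS ('+' hosts)
  u <- spec$pol3_units[g$manifest$roadblocks$unit, ]
  expect_equal(g$manifest$roadblocks$window_end, u$start)
  expect_equal(g$manifest$roadblocks$window_start, u$start - 200L)
})

test_that("overlapping same-strand planted units are rejected", {
  units <- data.frame(contig = "chr1", start = c(100L, 150L),
                      end = c(250L, 300L), strand = "+", fold = c(2, 2))
  expect_error(genome_spec(contigs = c(chr1 = 1000L), pol3_units = units),
               "overlapping")
  units$strand <- c("+", "-")
  expect_silent(genome_spec(contigs = c(chr1 = 1000L), pol3_units = units))
})

test_that("tag simulation conserves depth and maps repeats to all copies", {
  g <- generate_genome(example_genome_spec("multimap", seed = 14))
  ts <- simulate_chip_tags(g, "input", depth = 2e4, seed = 14)
  expect_equal(sum(ts$tags$c), 2e4)
  expect_equal(nrow(ts$sources), 2e4)
  expect_identical(unname(tabulate(ts$matches$tag_id,
                                   nbins = nrow(ts$tags))), ts$tags$m)

  # a tag drawn wholly inside one of the 3 identical copies matches 3 times
  rep1 <- g$repeats[1, ]
  inside <- ts$sources$start >= rep1$start &
    ts$sources$end <= rep1$end & ts$sources$contig == rep1$contig
  expect_gt(sum(inside), 0)
  seqs_inside <- unique(with(ts$sources[inside, ], {
    v <- Biostrings::Views(g$sequences[[rep1$contig]], start + 1, end)
    as.character(v)
  }))
  ids <- ts$tags$tag_id[!is.na(match(ts$tags$seq, seqs_inside)) |
                          !is.na(match(ts$tags$seq,
                                       as.character(Biostrings::reverseComplement(
                                         Biostrings::DNAStringSet(seqs_inside)))))]
  expect_true(all(ts$tags$m[ids] == 3))
})

test_that("tag length longer than the shortest contig is an error", {
  g <- generate_genome(genome_spec(contigs = c(tiny = 30L), seed = 1))
  expect_error(simulate_chip_tags(g, "input", depth = 10, tag_length = 36),
               "shortest contig")
})

test_that("fold-1 IP is indistinguishable from input by KS", {
  spec <- genome_spec(contigs = c(chrK = 30000L),
                      pol3_units = data.frame(contig = "chrK", start = 10000L,
                                              end = 10150L, strand = "+",
                                              fold = 1),
                      seed = 15)
  g <- generate_genome(spec)
  ip <- simulate_chip_tags(g, "pol3_ip", depth = 3e4, seed = 21)
  inp <- simulate_chip_tags(g, "input", depth = 3e4, seed = 22)
  cov_ip <- build_coverage(assign_weights(ip, "uniform"), g$contig_lengths)
  cov_in <- build_coverage(assign_weights(inp, "uniform"), g$contig_lengths)
  ks <- suppressWarnings(stats::ks.test(cov_ip$bins$chrK, cov_in$bins$chrK))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted enrichment is recovered at the stated fold", {
  g <- generate_genome(example_genome_spec("occupancy", seed = 16))
  cov <- simulate_tracks(g, c("pol3_ip", "input"), depth = 1e5, seed = 16)
  u <- g$pol3_units[g$pol3_units$fold == 8, ]
  ipm <- pol3roadblock:::locus_mass(cov$pol3_ip, u$contig, u$start, u$end) /
    cov$pol3_ip$total_weight
  inm <- pol3roadblock:::locus_mass(cov$input, u$contig, u$start, u$end) /
    cov$input$total_weight
  expect_lt(abs(ipm / inm - 8) / 8, 0.25)
})

test_that("genome and tag writers round-trip", {
  g <- generate_genome(example_genome_spec("polr3e_like", seed = 17))
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(as.character(fa), as.character(g$sequences))
  gff <- rtracklayer::import(paths[["gff3"]])
  genes <- gff[gff$type == "gene"]
  expect_equal(GenomicRanges::start(genes) - 1L, g$genes$start)
  expect_equal(GenomicRanges::end(genes), g$genes$end)

  ts <- simulate_chip_tags(g, "input", depth = 1000, seed = 17)
  tp <- file.path(dir, "tags.tsv")
  write_tags(ts, tp)
  back <- read_tags(tp)
  expect_equal(back$tags$c, ts$tags$c)
  expect_equal(back$tags$m, ts$tags$m)
  expect_equal(back$matches[, c("contig", "start", "end", "strand")],
               ts$matches[, c("contig", "start", "end", "strand")],
               ignore_attr = TRUE)

  fq <- file.path(dir, "tags.fastq")
  write_tags_fastq(ts, fq)
  expect_equal(length(readLines(fq)), 4 * sum(ts$tags$c))
})
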