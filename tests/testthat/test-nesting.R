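genes_fix <- data.frame(id = "g1", contig = "c1", start = 500L, end = 5000L,
                        strand = "+", tss = 500L, tes = 5000L,
                        stringsAsFactors = FALSE)

test_that("containment plus strand comparison defines nesting events", {
  peak <- data.frame(contig = "c1", start = 1000L, end = 1100L, strand = "-")
  ev <- find_nested(peak, genes_fix)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$orientation, "antisense")
  expect_equal(ev$gene_id, "g1")

  sense <- find_nested(data.frame(contig = "c1", start = 1000L, end = 1100L,
                                  strand = "+"), genes_fix)
  expect_equal(sense$orientation, "sense")
})

test_that("peaks straddling boundaries or in the promoter are excluded", {
  straddle <- data.frame(contig = "c1", start = 4950L, end = 5050L, strand = "+")
  expect_equal(nrow(find_nested(straddle, genes_fix)), 0)
  promoter <- data.frame(contig = "c1", start = 600L, end = 700L, strand = "+")
  expect_equal(nrow(find_nested(promoter, genes_fix)), 0)
  # and on a minus-strand host the exclusion flips to the high end
  genes_m <- transform(genes_fix, strand = "-", tss = 5000L, tes = 500L)
  expect_equal(nrow(find_nested(data.frame(contig = "c1", start = 4800L,
                                           end = 4900L, strand = "+"),
                                genes_m)), 0)
  expect_equal(find_nested(data.frame(contig = "c1", start = 1000L,
                                      end = 1100L, strand = "+"),
                           genes_m)$orientation, "antisense")
})

test_that("a peak without strand uses the fallback or errors", {
  peak <- data.frame(contig = "c1", start = 1000L, end = 1100L,
                     strand = NA, id = "p1")
  expect_error(find_nested(peak, genes_fix), "no strand")
  ev <- find_nested(peak, genes_fix, fallback_strand = c(p1 = "-"))
  expect_equal(ev$orientation, "antisense")
})

test_that("the archetypal nested-MIR arrangement yields one antisense event", {
  g <- generate_genome(example_genome_spec("polr3e_like", seed = 51))
  ev <- find_nested(g$pol3_units, g$genes)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_id, "mir_intron1")
  expect_equal(ev$orientation, "antisense")
  # the tRNA-class unit upstream of the TSS is not nested
  expect_false("trna_upstream" %in% ev$peak_id)
})

test_that("cross-confirmation matches summits within the distance cutoff", {
  peaks <- data.frame(contig = "c1",
                      start = seq(1000L, 4600L, by = 400L))
  peaks$end <- peaks$start + 100L
  peaks$strand <- "+"
  big_gene <- transform(genes_fix, end = 10000L, tes = 10000L)
  ev <- find_nested(peaks, big_gene)
  expect_equal(nrow(ev), 10)

  all_conf <- cross_confirm(ev, peaks)
  expect_true(all(all_conf$cross_confirmed))
  none <- cross_confirm(ev, peaks[0, ])
  expect_false(any(none$cross_confirmed))

  shared <- peaks[1:7, ]
  seven <- cross_confirm(ev, shared, max_summit_distance = 200)
  expect_equal(sum(seven$cross_confirmed), 7)
})

test_that("roadblock fold and significance behave on engineered tracks", {
  # gene body bins at 10; window [4800, 5000) of unit [5000, 5150)
  gene <- data.frame(id = "g", contig = "c1", start = 0L, end = 10000L,
                     strand = "+", tss = 0L, tes = 10000L)
  ev <- find_nested(data.frame(contig = "c1", start = 5000L, end = 5150L,
                               strand = "-"), gene)
  flat <- make_track(list(c1 = rep(10, 1000)))
  call_flat <- detect_roadblocks(flat, ev, gene)
  expect_equal(call_flat$fold, 1, tolerance = 0.05)
  expect_gt(call_flat$p, 0.05)
  expect_equal(call_flat$window_start, 4800)
  expect_equal(call_flat$window_end, 5000)

  bins <- rep(10, 1000); bins[481:500] <- 50
  hot <- make_track(list(c1 = bins))
  call_hot <- detect_roadblocks(hot, ev, gene)
  expect_equal(call_hot$fold, 5)
  expect_lt(call_hot$p, 1e-6)

  # minus-strand host: window flips to the unit's high side
  gene_m <- transform(gene, strand = "-", tss = 10000L, tes = 0L)
  ev_m <- find_nested(data.frame(contig = "c1", start = 5000L, end = 5150L,
                                 strand = "-"), gene_m)
  call_m <- detect_roadblocks(flat, ev_m, gene_m)
  expect_equal(call_m$window_start, 5150)
  expect_equal(call_m$window_end, 5350)
})

test_that("zero background flags the call unclassified", {
  gene <- data.frame(id = "g", contig = "c1", start = 0L, end = 10000L,
                     strand = "+", tss = 0L, tes = 10000L)
  ev <- find_nested(data.frame(contig = "c1", start = 5000L, end = 5150L,
                               strand = "+"), gene)
  zero <- make_track(list(c1 = rep(0, 1000)), total_weight = 1)
  call <- detect_roadblocks(zero, ev, gene)
  expect_equal(call$flag, "zero_background")
  expect_equal(call$classification, "unclassified")
  expect_true(is.na(call$fold))
})

test_that("NELF logic separates internal TSSs from roadblocks", {
  gene <- data.frame(id = "g", contig = "c1", start = 0L, end = 10000L,
                     strand = "+", tss = 0L, tes = 10000L)
  ev <- find_nested(data.frame(contig = "c1", start = 5000L, end = 5150L,
                               strand = "+"), gene)
  bins <- rep(10, 1000); bins[481:500] <- 50
  pol2 <- make_track(list(c1 = bins))
  call <- detect_roadblocks(pol2, ev, gene)

  nelf_flat <- make_track(list(c1 = c(rep(50, 20), rep(0, 980))),
                          total_weight = 278)
  dsif_hot <- make_track(list(c1 = {
    b <- c(rep(50, 20), rep(0, 980)); b[481:500] <- 50; b }),
    total_weight = 556)
  out <- classify_accumulation(call, nelf = nelf_flat, dsif = dsif_hot)
  expect_equal(out$classification, "roadblock")

  nelf_hot <- dsif_hot
  out2 <- classify_accumulation(call, nelf = nelf_hot, dsif = dsif_hot)
  expect_equal(out2$classification, "putative_internal_TSS")

  out3 <- classify_accumulation(call, nelf = NULL)
  expect_equal(out3$classification, "unclassified")
})

test_that("sense and antisense pileups are detected alike", {
  g <- generate_genome(example_genome_spec("funnel", seed = 52))
  cov <- simulate_tracks(g, c("pol2"), depth = 1e5, seed = 52)
  ev <- find_nested(g$pol3_units, g$genes)
  calls <- detect_roadblocks(cov$pol2, ev, g$genes)
  sig <- calls$q < 0.05
  expect_true(all(sig[calls$orientation == "sense"]))
  expect_true(all(sig[calls$orientation == "antisense"]))
})

test_that("funnel stage counts are non-increasing and empty input is safe", {
  g <- generate_genome(example_genome_spec("funnel", seed = 53))
  cov <- simulate_tracks(g, c("pol3_ip", "input", "pol2"), depth = 5e4,
                         seed = 53)
  f <- run_funnel(g$pol3_units, g$genes, cov$pol3_ip, cov$input, cov$pol2,
                  second_peakset = g$pol3_units[1:6, ])
  cnt <- f$counts
  expect_true(cnt["confirmed"] <= cnt["peaks"])
  expect_true(cnt["nested"] <= cnt["confirmed"])
  expect_true(cnt["cross_confirmed"] <= cnt["nested"])
  expect_true(cnt["roadblocks"] <= cnt["cross_confirmed"])
  expect_equal(unname(cnt["cross_confirmed"]), 6)

  f0 <- run_funnel(data.frame(), g$genes, cov$pol3_ip, cov$input, cov$pol2)
  expect_true(all(f0$counts == 0))

  # no Pol II track: roadblock stages skipped, not failed
  f_skip <- run_funnel(g$pol3_units, g$genes, cov$pol3_ip, cov$input)
  expect_true("detect_roadblock" %in% f_skip$skipped)
  expect_true(is.na(f_skip$counts["roadblocks"]))
})
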