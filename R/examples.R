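#' Ready-made synthetic study designs
#'
#' Deterministic genome specifications covering the situations the package
#' is built to analyse. Coordinates are fixed arithmetic; only sequence
#' content and tag sampling are random (controlled by `seed`).
#'
#' \describe{
#'   \item{funnel}{10 Pol II genes (8 kb, body level 1 tag/bp, TSS pausing
#'     fold 10) each hosting one 150 bp Pol III unit (IP fold 8, alternating
#'     sense/antisense), every unit backed by a fold-3, 200 bp Pol II pileup
#'     just 5' of it in the host's orientation.}
#'   \item{funnel_null}{the matched null: identical layout, no pileups.}
#'   \item{nelf}{as `funnel`, but the pileups of the first five units also
#'     carry NELF signal, emulating unannotated internal TSSs; the other
#'     five are pure roadblocks.}
#'   \item{null_calibration}{20 genes x 10 nested units each (200 events),
#'     no pileups, for type-I error calibration of the roadblock test.}
#'   \item{occupancy}{four 150 bp Pol III units at IP folds 1, 2, 4 and 8 on
#'     a gene-free contig, for occupancy-score recovery.}
#'   \item{multimap}{a 3-copy zero-divergence 300 bp repeat family in 60 kb
#'     of background, so multi-mapping is real and family totals have a
#'     planted truth.}
#'   \item{polr3e_like}{one Pol II gene with an antisense MIR-class unit in
#'     its 5' region (with a fold-3 pileup) and a tRNA-class unit upstream
#'     of the TSS, mirroring the archetypal nested-MIR arrangement.}
#' }
#'
#' @param kind One of the designs above.
#' @param seed Integer seed stored in the specification.
#' @return A [genome_spec()].
#' @export
example_genome_spec <- function(kind = c("funnel", "funnel_null", "nelf",
                                         "null_calibration", "occupancy",
                                         "multimap", "polr3e_like"),
                                seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("funnel", "funnel_null", "nelf")) {
    n <- 10L
    genes <- lapply(seq_len(n), function(i)
      gene_model(sprintf("gene%02d", i), "chrS",
                 tss = 2000L + (i - 1L) * 10000L,
                 tes = 10000L + (i - 1L) * 10000L,
                 strand = "+", tss_peak_fold = 10, body_level = 1))
    units <- new_intervals(
      contig = rep("chrS", n),
      start = 2000L + (seq_len(n) - 1L) * 10000L + 5000L,
      end = 2000L + (seq_len(n) - 1L) * 10000L + 5150L,
      strand = rep(c("+", "-"), length.out = n),
      fold = rep(8, n), class = rep("SINE", n))
    rb <- switch(kind,
      funnel = data.frame(unit = seq_len(n), fold = 3, width = 200L,
                          nelf = FALSE),
      nelf = data.frame(unit = seq_len(n), fold = 3, width = 200L,
                        nelf = rep(c(TRUE, FALSE), each = 5)),
      funnel_null = NULL)
    genome_spec(contigs = c(chrS = 102000L), genes = genes,
                pol3_units = units, roadblocks = rb, seed = seed)
  } else if (kind == "null_calibration") {
    n_genes <- 20L
    genes <- lapply(seq_len(n_genes), function(i)
      gene_model(sprintf("gene%02d", i), "chrN",
                 tss = 1000L + (i - 1L) * 10000L,
                 tes = 9000L + (i - 1L) * 10000L,
                 strand = "+", tss_peak_fold = 10, body_level = 1))
    pos <- unlist(lapply(seq_len(n_genes), function(i)
      1000L + (i - 1L) * 10000L + 1000L + (0:9) * 600L))
    units <- new_intervals(
      contig = rep("chrN", length(pos)), start = pos, end = pos + 150L,
      strand = rep(c("+", "-"), length.out = length(pos)),
      fold = rep(8, length(pos)), class = rep("SINE", length(pos)))
    genome_spec(contigs = c(chrN = 200000L), genes = genes,
                pol3_units = units, seed = seed)
  } else if (kind == "occupancy") {
    units <- new_intervals(
      contig = rep("chrO", 4), start = c(5000L, 15000L, 25000L, 35000L),
      end = c(5150L, 15150L, 25150L, 35150L), strand = rep("+", 4),
      fold = c(1, 2, 4, 8), class = rep("SINE", 4))
    units$id <- sprintf("unit_fold%d", c(1, 2, 4, 8))
    genome_spec(contigs = c(chrO = 40000L), pol3_units = units, seed = seed)
  } else if (kind == "multimap") {
    consensus <- with_seed(derive_seed(seed, 99),
                           paste(sample(c("A", "C", "G", "T"), 300,
                                        replace = TRUE), collapse = ""))
    genome_spec(contigs = c(chrM = 60000L),
                repeat_families = list(list(name = "fam1",
                                            consensus = consensus,
                                            copy_number = 3L,
                                            divergence = 0,
                                            strands = "+")),
                seed = seed)
  } else { # polr3e_like
    genes <- list(gene_model("hostA", "chrP", tss = 2000L, tes = 10000L,
                             strand = "+", tss_peak_fold = 10, body_level = 1))
    units <- new_intervals(
      contig = c("chrP", "chrP"), start = c(3200L, 1500L),
      end = c(3350L, 1600L), strand = c("-", "-"),
      fold = c(8, 8), class = c("MIR", "tRNA"))
    units$id <- c("mir_intron1", "trna_upstream")
    genome_spec(contigs = c(chrP = 15000L), genes = genes, pol3_units = units,
                roadblocks = data.frame(unit = 1L, fold = 3, width = 200L,
                                        nelf = FALSE),
                seed = seed)
  }
}

#' Simulate the standard track bundle for a synthetic genome
#'
#' Convenience wrapper: simulates the requested tracks, assigns weights and
#' builds coverage, with per-track sub-seeds derived from the genome seed so
#' the whole bundle is reproducible.
#'
#' @param genome A `synthetic_genome`.
#' @param tracks Character vector of track kinds to simulate.
#' @param depth Named or scalar total tag count per track.
#' @param tag_length Tag length in bp.
#' @param bin_size Coverage bin size in bp.
#' @param scheme Weighting scheme (see [assign_weights()]).
#' @param seed Base seed (defaults to the genome's spec seed).
#' @return A named list of `coverage_track`s; the raw `tag_set`s are
#'   attached as `attr(, "tag_sets")`.
#' @export
simulate_tracks <- function(genome, tracks = c("pol3_ip", "input", "pol2"),
                            depth = 1e5, tag_length = 36L, bin_size = 10L,
                            scheme = "uniform", seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  seed <- seed %||% genome$spec$seed
  if (is.null(names(depth))) depth <- stats::setNames(rep(depth[1],
                                                          length(tracks)), tracks)
  tag_sets <- list()
  out <- list()
  for (k in seq_along(tracks)) {
    tk <- tracks[k]
    ts <- simulate_chip_tags(genome, tk, depth = depth[[tk]],
                             tag_length = tag_length,
                             seed = derive_seed(seed, k))
    pl <- assign_weights(ts, scheme = scheme)
    out[[tk]] <- build_coverage(pl, genome$contig_lengths,
                                bin_size = bin_size)
    tag_sets[[tk]] <- ts
  }
  attr(out, "tag_sets") <- tag_sets
  out
}
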