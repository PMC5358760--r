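#' Describe a Pol II gene model for the synthetic genome
#'
#' A gene is defined by its transcription start site (TSS) and transcription
#' end site (TES) in 0-based coordinates; on the minus strand the TSS is the
#' numerically larger position. The expected Pol II ChIP signal over the gene
#' is a flat body level plus a promoter-proximal pausing peak at the TSS.
#'
#' @param id Gene identifier.
#' @param contig Contig name.
#' @param tss,tes Transcription start / end site, 0-based. `tss < tes` on
#'   `+`, `tss > tes` on `-`.
#' @param strand `"+"` or `"-"`.
#' @param exons Optional list of `c(start, end)` 0-based half-open intervals
#'   within the gene span; defaults to a single exon covering the span.
#' @param tss_peak_fold Pol II pausing-peak enrichment over body level
#'   (fold, >= 1) within the first 200 bp downstream of the TSS.
#' @param body_level Relative expected Pol II tag density over the gene body
#'   (tags per bp, > 0); densities are scaled to the requested sequencing
#'   depth at simulation time.
#' @return A `gene_model` list.
#' @export
gene_model <- function(id, contig, tss, tes, strand,
                       exons = NULL, tss_peak_fold = 10, body_level = 1) {
  stopifnot(strand %in% c("+", "-"), tss_peak_fold >= 1, body_level > 0)
  if (strand == "+" && tss >= tes) stop("gene ", id, ": tss must precede tes on '+'")
  if (strand == "-" && tss <= tes) stop("gene ", id, ": tss must follow tes on '-'")
  start <- min(tss, tes); end <- max(tss, tes)
  if (is.null(exons)) exons <- list(c(start, end))
  for (ex in exons) {
    if (ex[1] < start || ex[2] > end) stop("gene ", id, ": exon outside [tss, tes]")
  }
  structure(list(id = as.character(id), contig = as.character(contig),
                 tss = as.integer(tss), tes = as.integer(tes),
                 strand = strand, start = as.integer(start), end = as.integer(end),
                 exons = exons, tss_peak_fold = tss_peak_fold,
                 body_level = body_level),
            class = "gene_model")
}

#' Specify a synthetic genome with planted structure
#'
#' The specification drives [generate_genome()] and
#' [simulate_chip_tags()]: it plants near-identical repeat families (so
#' multi-mapping is real), Pol II gene models with TSS pausing peaks,
#' Pol III-occupied units with a chosen IP enrichment, and Pol II pileups
#' ("roadblocks") just 5' -- in the host gene's direction of travel -- of
#' nested Pol III units. Identical spec + seed reproduces all outputs
#' bit-exactly.
#'
#' @param contigs Named integer vector of contig lengths in bp.
#' @param repeat_families List of lists with fields `name`, `consensus`
#'   (DNA string), `copy_number` (>= 1), `divergence` (per-base substitution
#'   probability in \[0, 1\]) and optional `strands` (vector recycled over
#'   copies, default `"+"`).
#' @param genes List of [gene_model()] objects.
#' @param pol3_units `data.frame` with columns `contig`, `start`, `end`,
#'   `strand`, `fold` (IP enrichment over input background, >= 1) and
#'   optionally `class` (`"SINE"`, `"tRNA"`, `"MIR"`, `"other"`; default
#'   `"SINE"`) and `id`.
#' @param roadblocks `data.frame` with columns `unit` (row index into
#'   `pol3_units`), `fold` (Pol II pileup enrichment over gene body, >= 1),
#'   and optionally `width` (bp, default 200) and `nelf` (logical: also plant
#'   NELF signal in the pileup window, emulating an unannotated internal TSS
#'   rather than a roadblock; default `FALSE`).
#' @param seed Integer seed controlling all randomness downstream.
#' @return A validated `genome_spec` object.
#' @export
genome_spec <- function(contigs, repeat_families = list(), genes = list(),
                        pol3_units = NULL, roadblocks = NULL, seed = 1L) {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be a named vector of lengths")
  contigs <- vapply(contigs, as.integer, integer(1))
  if (any(contigs <= 0)) stop("contig lengths must be positive")

  for (fam in repeat_families) {
    stopifnot(!is.null(fam$consensus), !is.null(fam$copy_number))
    if (fam$copy_number < 1) stop("repeat family copy_number must be >= 1")
    div <- fam$divergence %||% 0
    if (div < 0 || div > 1) stop("repeat divergence must lie in [0, 1]")
  }
  for (g in genes) {
    if (!inherits(g, "gene_model")) stop("genes must be gene_model objects")
    if (!g$contig %in% names(contigs)) stop("gene ", g$id, ": unknown contig")
    if (g$start < 0 || g$end > contigs[[g$contig]])
      stop("gene ", g$id, ": outside contig bounds")
  }

  if (is.null(pol3_units)) {
    pol3_units <- new_intervals(fold = numeric(), class = character(),
                                id = character())
  } else {
    pol3_units <- as.data.frame(pol3_units, stringsAsFactors = FALSE)
    if (is.null(pol3_units$class)) pol3_units$class <- "SINE"
    if (is.null(pol3_units$id))
      pol3_units$id <- sprintf("pol3_unit_%02d", seq_len(nrow(pol3_units)))
    stopifnot(all(c("contig", "start", "end", "strand", "fold") %in%
                    names(pol3_units)))
    if (any(pol3_units$fold < 1)) stop("pol3 unit folds must be >= 1")
    bad <- !pol3_units$contig %in% names(contigs) |
      pol3_units$start < 0 | pol3_units$end > contigs[pol3_units$contig]
    if (any(bad)) stop("pol3 units outside contig bounds: ",
                       paste(which(bad), collapse = ", "))
    .check_same_strand_overlap(pol3_units, "pol3 units")
  }

  if (is.null(roadblocks)) {
    roadblocks <- data.frame(unit = integer(), fold = numeric(),
                             width = integer(), nelf = logical())
  } else {
    roadblocks <- as.data.frame(roadblocks, stringsAsFactors = FALSE)
    if (is.null(roadblocks$width)) roadblocks$width <- 200L
    if (is.null(roadblocks$nelf)) roadblocks$nelf <- FALSE
    stopifnot(all(c("unit", "fold") %in% names(roadblocks)))
    if (any(roadblocks$fold < 1)) stop("roadblock folds must be >= 1")
    if (any(roadblocks$unit < 1 | roadblocks$unit > nrow(pol3_units)))
      stop("roadblock refers to a pol3 unit that does not exist")
  }

  structure(list(contigs = contigs, repeat_families = repeat_families,
                 genes = genes, pol3_units = pol3_units,
                 roadblocks = roadblocks, seed = as.integer(seed)),
            class = "genome_spec")
}

.check_same_strand_overlap <- function(iv, what) {
  if (nrow(iv) < 2) return(invisible())
  for (s in unique(iv$strand)) {
    sub <- iv[iv$strand == s, , drop = FALSE]
    if (nrow(sub) < 2) next
    gr <- intervals_to_granges(sub)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(hits) > 0)
      stop("overlapping planted ", what, " on strand ", s,
           " at rows ", paste(unique(S4Vectors::queryHits(hits)), collapse = ","))
  }
  invisible()
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Synthetic genome specification\n")
  cat(sprintf("  contigs: %d (%s bp total)\n", length(x$contigs),
              format(sum(x$contigs), big.mark = ",")))
  cat(sprintf("  repeat families: %d | genes: %d | Pol III units: %d | roadblocks: %d\n",
              length(x$repeat_families), length(x$genes),
              nrow(x$pol3_units), nrow(x$roadblocks)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
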