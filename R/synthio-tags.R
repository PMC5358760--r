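#' Simulate a ChIP-seq tag set from a synthetic genome
#'
#' Draws single-end, fixed-length tags from a track-specific sampling density:
#' \describe{
#'   \item{input}{uniform over the genome.}
#'   \item{pol3_ip}{uniform background plus each planted Pol III unit enriched
#'     at its stated fold.}
#'   \item{pol2}{gene-body level plus the TSS pausing peak plus the planted
#'     roadblock pileup just 5' (in the host gene's orientation) of each
#'     nested Pol III unit; zero outside genes.}
#'   \item{nelf}{TSS pausing peaks, plus pileup windows flagged as carrying
#'     NELF (emulating an unannotated internal TSS).}
#'   \item{dsif}{TSS pausing peaks plus all roadblock pileup windows.}
#' }
#' Each drawn tag is then mapped back to \emph{all} genomic positions whose
#' sequence matches it exactly (both strands), producing the match list
#' \eqn{m}; identical tag sequences are collapsed into a multiplicity
#' \eqn{c}. The originally drawn placements are retained in `$sources` as
#' ground truth.
#'
#' @param genome A `synthetic_genome` from [generate_genome()].
#' @param track_kind One of `"pol3_ip"`, `"input"`, `"pol2"`, `"nelf"`,
#'   `"dsif"`.
#' @param depth Total number of tags to draw.
#' @param tag_length Tag length in bp (must not exceed the shortest contig).
#' @param seed Integer seed.
#' @return A `tag_set` list: `tags` (tag_id, seq, c, m), `matches` (tag_id,
#'   contig, start, end, strand; 0-based half-open), `sources` (drawn
#'   placements, one row per tag before collapsing), `tag_length`,
#'   `track_kind`, `depth`, `contig_lengths`.
#' @export
simulate_chip_tags <- function(genome, track_kind = c("pol3_ip", "input",
                                                      "pol2", "nelf", "dsif"),
                               depth, tag_length = 36L, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"), depth > 0)
  track_kind <- match.arg(track_kind)
  tag_length <- as.integer(tag_length)
  if (tag_length > min(genome$contig_lengths))
    stop("tag_length (", tag_length, ") exceeds the shortest contig (",
         min(genome$contig_lengths), " bp)")

  dens <- .track_density(genome, track_kind)
  with_seed(seed, {
    src <- .sample_tag_starts(dens, genome$contig_lengths, depth, tag_length)
    src$strand <- sample(c("+", "-"), depth, replace = TRUE)
    src$end <- src$start + tag_length

    seqs <- character(depth)
    for (ctg in unique(src$contig)) {
      i <- which(src$contig == ctg)
      v <- Biostrings::Views(genome$sequences[[ctg]],
                             start = src$start[i] + 1L, end = src$end[i])
      seqs[i] <- as.character(v)
    }
    neg <- src$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

    uniq <- unique(seqs)
    idx <- match(seqs, uniq)
    cc <- tabulate(idx, nbins = length(uniq))

    matches <- .exact_matches(uniq, genome$sequences)
    m <- tabulate(matches$tag_id, nbins = length(uniq))
    if (any(m == 0)) stop("internal error: a drawn tag found no exact match")

    structure(list(
      tags = data.frame(tag_id = seq_along(uniq), seq = uniq, c = cc, m = m,
                        stringsAsFactors = FALSE),
      matches = matches,
      sources = src,
      tag_length = tag_length, track_kind = track_kind, depth = depth,
      contig_lengths = genome$contig_lengths
    ), class = "tag_set")
  })
}

# Per-bp relative sampling weight for tag start positions, rasterized per
# contig. Patches are applied in increasing priority, later patches
# overriding earlier ones.
.track_density <- function(genome, track_kind) {
  lens <- genome$contig_lengths
  dens <- lapply(lens, function(L) numeric(L))
  g <- genome$genes
  rb <- genome$roadblocks

  paint <- function(dens, contig, start, end, w) {
    start <- max(0L, start); end <- min(length(dens[[contig]]), end)
    if (end > start) dens[[contig]][(start + 1):end] <- w
    dens
  }
  tss_region <- function(gi) {
    if (gi$strand == "+") c(gi$tss, gi$tss + 200L) else c(gi$tss - 200L, gi$tss)
  }

  if (track_kind == "input") {
    for (ctg in names(dens)) dens[[ctg]][] <- 1
  } else if (track_kind == "pol3_ip") {
    for (ctg in names(dens)) dens[[ctg]][] <- 1
    u <- genome$pol3_units
    for (i in seq_len(nrow(u)))
      dens <- paint(dens, u$contig[i], u$start[i], u$end[i], u$fold[i])
  } else if (track_kind == "pol2") {
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      dens <- paint(dens, gi$contig, gi$start, gi$end, gi$body_level)
    }
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      tr <- tss_region(gi)
      dens <- paint(dens, gi$contig, tr[1], tr[2],
                    gi$body_level * gi$tss_peak_fold)
    }
    for (i in seq_len(nrow(rb))) {
      host <- g[g$id == rb$host_gene[i], ]
      dens <- paint(dens, rb$contig[i], rb$window_start[i], rb$window_end[i],
                    host$body_level * rb$fold[i])
    }
  } else if (track_kind %in% c("nelf", "dsif")) {
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      tr <- tss_region(gi)
      dens <- paint(dens, gi$contig, tr[1], tr[2],
                    gi$body_level * gi$tss_peak_fold)
    }
    for (i in seq_len(nrow(rb))) {
      if (track_kind == "nelf" && !isTRUE(rb$nelf[i])) next
      host <- g[g$id == rb$host_gene[i], ]
      dens <- paint(dens, rb$contig[i], rb$window_start[i], rb$window_end[i],
                    host$body_level * rb$fold[i])
    }
  }
  dens
}

.sample_tag_starts <- function(dens, lens, depth, tag_length) {
  # restrict to valid start positions so tags never run off the contig
  valid <- lapply(names(dens), function(ctg) {
    v <- dens[[ctg]]
    v[seq_len(min(length(v), lens[[ctg]] - tag_length + 1L))]
  })
  names(valid) <- names(dens)
  mass <- vapply(valid, sum, numeric(1))
  if (sum(mass) <= 0)
    stop("sampling density is identically zero for this track")
  n_per <- as.vector(stats::rmultinom(1, depth, prob = mass))
  out <- vector("list", length(valid))
  for (k in seq_along(valid)) {
    if (n_per[k] == 0) next
    starts <- sample.int(length(valid[[k]]), n_per[k], replace = TRUE,
                         prob = valid[[k]]) - 1L
    out[[k]] <- data.frame(contig = names(valid)[k], start = starts,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res[sample.int(nrow(res)), , drop = FALSE]  # shuffle contig blocks
}

# All exact genomic matches of the given equal-length tag sequences, both
# strands, via an Aho-Corasick dictionary scan.
.exact_matches <- function(tag_seqs, sequences) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(tag_seqs))
  w <- nchar(tag_seqs[1])
  out <- list()
  for (ctg in names(sequences)) {
    subj <- sequences[[ctg]]
    L <- length(subj)
    fwd <- Biostrings::matchPDict(pd, subj)
    n_f <- S4Vectors::elementNROWS(fwd)
    if (sum(n_f) > 0) {
      ir <- unlist(fwd)
      out[[length(out) + 1]] <- data.frame(
        tag_id = rep(seq_along(n_f), n_f),
        contig = ctg,
        start = IRanges::start(ir) - 1L,
        end = IRanges::end(ir),
        strand = "+", stringsAsFactors = FALSE)
    }
    rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
    n_r <- S4Vectors::elementNROWS(rev)
    if (sum(n_r) > 0) {
      ir <- unlist(rev)
      out[[length(out) + 1]] <- data.frame(
        tag_id = rep(seq_along(n_r), n_r),
        contig = ctg,
        start = L - IRanges::end(ir),
        end = L - IRanges::start(ir) + 1L,
        strand = "-", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$tag_id, res$contig, res$start), , drop = FALSE]
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("ChIP tag set (%s): %d tags drawn, %d unique sequences\n",
              x$track_kind, x$depth, nrow(x$tags)))
  multi <- sum(x$tags$m > 1)
  cat(sprintf("  tag length %d bp | multi-mapping sequences: %d (%.1f%%)\n",
              x$tag_length, multi, 100 * multi / nrow(x$tags)))
  invisible(x)
}
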