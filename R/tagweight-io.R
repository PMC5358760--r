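#' Write a coverage track as bedGraph
#'
#' Bins are written as fixed-width bedGraph intervals with six-decimal
#' weights; zero bins are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%d tag_length=%d total_weight=%.6f",
                     track$bin_size, track$tag_length, track$total_weight), con)
  bs <- track$bin_size
  for (ctg in names(track$bins)) {
    v <- track$bins[[ctg]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    starts <- (nz - 1L) * bs
    ends <- pmin(nz * bs, track$contig_lengths[[ctg]])
    writeLines(sprintf("%s\t%d\t%d\t%.6f", ctg, starts, ends, v[nz]), con)
  }
  invisible(path)
}

#' Read a bin-aligned bedGraph written by [write_bedgraph()]
#'
#' @param path bedGraph path.
#' @param contig_lengths Named contig lengths; recovered from the data extent
#'   when omitted (bins beyond the last non-zero bin are then lost).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, contig_lengths = NULL) {
  first <- readLines(path, n = 1)
  meta <- regmatches(first,
    regexec("bin_size=(\\d+) tag_length=(\\d+) total_weight=([0-9.eE+-]+)", first))[[1]]
  if (length(meta) != 4)
    stop("not a pol3roadblock bedGraph (missing bin_size/tag_length header)")
  bs <- as.integer(meta[2]); tl <- as.integer(meta[3]); tw <- as.numeric(meta[4])
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("contig", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(split(df$end, df$contig), max, numeric(1))
  }
  bins <- lapply(contig_lengths, function(L) numeric(ceiling(L / bs)))
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, ]
    bins[[ctg]][sub$start %/% bs + 1L] <- sub$value
  }
  structure(list(bins = bins, bin_size = bs, tag_length = tl,
                 total_weight = tw, contig_lengths = contig_lengths),
            class = "coverage_track")
}

#' Conservation report for a weighting run
#'
#' Verifies that the total assigned weight equals the total sequencing
#' multiplicity and optionally writes the report as JSON.
#'
#' @param tags A `tag_set`.
#' @param placements Output of [assign_weights()].
#' @param path Optional JSON output path.
#' @return A list with `sum_multiplicity`, `sum_weights` and `conserved`.
#' @export
conservation_report <- function(tags, placements, path = NULL) {
  rep <- list(sum_multiplicity = sum(tags$tags$c),
              sum_weights = sum(placements$weight))
  rep$conserved <- isTRUE(all.equal(rep$sum_multiplicity, rep$sum_weights,
                                    tolerance = 1e-9))
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  rep
}

#' Read tags from SAM/BAM alignments
#'
#' Multiplicity `c` is reconstructed by collapsing identical read sequences
#' (reverse-complemented to the sequenced strand first, so a read and its
#' minus-strand alignment collapse together); the match count `m` comes from
#' the `NH` tag when present and otherwise from the number of collapsed
#' alignment records per sequence.
#'
#' @param path SAM or BAM file (SAM files are converted in a temporary
#'   directory; requires the Rsamtools package).
#' @return A `tag_set` (without ground-truth sources).
#' @export
read_tags_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_tags_bam() requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "qwidth"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$pos)
  if (n == 0) stop("no mapped alignments in ", path)
  seqs <- as.character(b$seq)
  neg <- as.character(b$strand) == "-"
  seqs[neg] <- revcomp(seqs[neg])

  aln <- data.frame(seq = seqs, qname = b$qname,
                    contig = as.character(b$rname),
                    start = b$pos - 1L, end = b$pos - 1L + b$qwidth,
                    strand = as.character(b$strand),
                    nh = if (is.null(b$tag$NH)) NA_integer_ else b$tag$NH,
                    stringsAsFactors = FALSE)
  key <- factor(aln$seq, levels = unique(aln$seq))
  # one alignment record per (sequence, location); distinct read names with
  # the same sequence contribute multiplicity
  loc <- paste(aln$seq, aln$contig, aln$start, aln$strand)
  first_at_loc <- !duplicated(loc)
  cc <- tapply(aln$qname, key, function(q) length(unique(q)))
  matches <- aln[first_at_loc, c("contig", "start", "end", "strand")]
  matches$tag_id <- as.integer(key[first_at_loc])
  m_collapsed <- tabulate(matches$tag_id, nbins = nlevels(key))
  nh <- tapply(aln$nh, key, function(x) x[1])
  m <- ifelse(is.na(nh), m_collapsed, pmax(nh, m_collapsed))
  structure(list(
    tags = data.frame(tag_id = seq_len(nlevels(key)), seq = levels(key),
                      c = as.integer(cc), m = as.integer(m),
                      stringsAsFactors = FALSE),
    matches = matches[order(matches$tag_id), c("tag_id", "contig", "start",
                                               "end", "strand")],
    sources = NULL,
    tag_length = as.integer(stats::median(aln$end - aln$start)),
    track_kind = "unknown", depth = sum(cc), contig_lengths = NULL
  ), class = "tag_set")
}
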