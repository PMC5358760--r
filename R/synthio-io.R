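#' Write a synthetic genome to disk
#'
#' Writes the contig sequences as FASTA, the gene models and planted features
#' as GFF3 (1-based closed on write), the Pol III units as BED6, and the
#' ground-truth manifest as JSON.
#'
#' @param genome A `synthetic_genome`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_genome <- function(genome, outdir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             gff3 = file.path(outdir, "annotation.gff3"),
             bed = file.path(outdir, "pol3_units.bed"),
             manifest = file.path(outdir, "manifest.json"))

  Biostrings::writeXStringSet(genome$sequences, paths[["fasta"]])

  feats <- list()
  g <- genome$genes
  if (nrow(g) > 0)
    feats$gene <- new_intervals(g$contig, g$start, g$end, g$strand,
                                type = "gene", ID = g$id)
  u <- genome$pol3_units
  if (nrow(u) > 0)
    feats$unit <- new_intervals(u$contig, u$start, u$end, u$strand,
                                type = "pol3_unit", ID = u$id)
  r <- genome$repeats
  if (nrow(r) > 0)
    feats$rep <- new_intervals(r$contig, r$start, r$end, r$strand,
                               type = "repeat_copy", ID = r$copy_id)
  ann <- do.call(rbind, feats)
  gr <- intervals_to_granges(ann)
  S4Vectors::mcols(gr)$type <- ann$type
  S4Vectors::mcols(gr)$ID <- ann$ID
  rtracklayer::export(gr, paths[["gff3"]], format = "gff3")

  if (nrow(u) > 0) {
    bed <- intervals_to_granges(u)
    names(bed) <- u$id
    S4Vectors::mcols(bed)$score <- u$fold
    rtracklayer::export(bed, paths[["bed"]], format = "bed")
  }

  jsonlite::write_json(genome$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Write / read a tag set in the tab-separated tag dialect
#'
#' One row per collapsed tag:
#' `tag_id  multiplicity  n_matches  match1;match2;...` where each match is
#' formatted `contig:start-end:strand` in 0-based half-open coordinates.
#'
#' @param tags A `tag_set`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_tags <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  mm <- tags$matches
  match_str <- vapply(split(sprintf("%s:%d-%d:%s", mm$contig, mm$start,
                                    mm$end, mm$strand),
                            factor(mm$tag_id, levels = tags$tags$tag_id)),
                      paste, character(1), collapse = ";")
  df <- data.frame(tag_id = tags$tags$tag_id,
                   multiplicity = tags$tags$c,
                   n_matches = tags$tags$m,
                   matches = unname(match_str),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @param tag_length Tag length (recovered from the matches when omitted).
#' @param contig_lengths Optional named vector of contig lengths.
#' @return For `read_tags()`, a `tag_set` (without sequences or ground-truth
#'   sources).
#' @export
read_tags <- function(path, tag_length = NULL, contig_lengths = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  parts <- strsplit(df$matches, ";", fixed = TRUE)
  n <- lengths(parts)
  if (!all(n == df$n_matches))
    stop("tag file is inconsistent: n_matches does not equal the match list length")
  flat <- unlist(parts)
  mm <- regmatches(flat, regexec("^([^:]+):(\\d+)-(\\d+):([+-])$", flat))
  bad <- vapply(mm, length, integer(1)) != 5
  if (any(bad)) stop("malformed match field: ", flat[which(bad)[1]])
  matches <- data.frame(
    tag_id = rep(df$tag_id, n),
    contig = vapply(mm, `[`, character(1), 2),
    start = as.integer(vapply(mm, `[`, character(1), 3)),
    end = as.integer(vapply(mm, `[`, character(1), 4)),
    strand = vapply(mm, `[`, character(1), 5),
    stringsAsFactors = FALSE)
  if (is.null(tag_length)) tag_length <- matches$end[1] - matches$start[1]
  structure(list(
    tags = data.frame(tag_id = df$tag_id, seq = NA_character_,
                      c = df$multiplicity, m = df$n_matches,
                      stringsAsFactors = FALSE),
    matches = matches, sources = NULL, tag_length = tag_length,
    track_kind = "unknown", depth = sum(df$multiplicity),
    contig_lengths = contig_lengths
  ), class = "tag_set")
}

#' Write tags as unaligned FASTQ
#'
#' One record per sequenced tag (multiplicities expanded), with uniform
#' placeholder base qualities; useful for feeding the synthetic tags to
#' external tools.
#'
#' @param tags A `tag_set` carrying sequences.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_tags_fastq <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  if (all(is.na(tags$tags$seq))) stop("tag set carries no sequences")
  idx <- rep(seq_len(nrow(tags$tags)), tags$tags$c)
  ids <- sprintf("@tag_%d_%d", tags$tags$tag_id[idx],
                 sequence(tags$tags$c))
  qual <- strrep("I", tags$tag_length)
  lines <- as.vector(rbind(ids, tags$tags$seq[idx], "+", qual))
  writeLines(lines, path)
  invisible(path)
}
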