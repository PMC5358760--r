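# Internal coordinate convention: 0-based half-open [start, end) intervals on
# named contigs (BED style). Conversion to 1-based closed coordinates happens
# only at GRanges/GFF3 boundaries.

new_intervals <- function(contig = character(), start = integer(),
                          end = integer(), strand = NULL, ...) {
  if (is.null(strand)) strand <- rep("*", length(start))
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(end < start)) stop("interval end < start")
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand), ...,
             stringsAsFactors = FALSE)
}

intervals_to_granges <- function(x) {
  s <- ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  GenomicRanges::GRanges(x$contig,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit integer range
# so downstream set.seed() calls are portable.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
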