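#' Define a type-2 Pol III internal promoter model
#'
#' Type-2 Pol III promoters are gene-internal and consist of an A box and a
#' B box, bound by TFIIIC, with the B box downstream of the A box at a
#' constrained spacer. Boxes are given either as IUPAC consensus strings
#' with a mismatch budget, or as position weight matrices with a minimum
#' score. The shipped defaults are the community-standard tRNA-derived
#' consensus boxes.
#'
#' @param a_box,b_box IUPAC consensus strings, or matrices (rows A,C,G,T)
#'   interpreted as PWMs.
#' @param spacer_range `c(min, max)` spacer in bp, measured from the base
#'   after the A box's last position to the base before the B box's first
#'   position (0-based half-open, i.e. `b_start - a_end`).
#' @param max_mismatches Allowed mismatches per consensus box (`N` in the
#'   subject never matches).
#' @param min_score Minimum PWM score (fraction of the maximum, e.g.
#'   `"80%"`), for PWM boxes.
#' @return A `promoter_model` object.
#' @export
promoter_model <- function(a_box = "TRGCNNARYNNG", b_box = "GTTCRANNC",
                           spacer_range = c(20L, 40L), max_mismatches = 2L,
                           min_score = "80%") {
  stopifnot(length(spacer_range) == 2, spacer_range[1] <= spacer_range[2])
  for (b in list(a_box, b_box)) {
    if (is.character(b) && nchar(b) == 0) stop("empty promoter box")
  }
  structure(list(a_box = a_box, b_box = b_box,
                 spacer_range = as.integer(spacer_range),
                 max_mismatches = as.integer(max_mismatches),
                 min_score = min_score),
            class = "promoter_model")
}

#' @rdname promoter_model
#' @details `strict_mir_model()` is the preset used for MIR elements: same
#'   boxes, spacer constrained to 25-26 bp as observed across mammalian
#'   MIR copies at the *Polr3e* locus.
#' @export
strict_mir_model <- function(a_box = "TRGCNNARYNNG", b_box = "GTTCRANNC",
                             max_mismatches = 2L) {
  promoter_model(a_box = a_box, b_box = b_box, spacer_range = c(25L, 26L),
                 max_mismatches = max_mismatches)
}

#' @export
print.promoter_model <- function(x, ...) {
  fmt <- function(b) if (is.matrix(b)) sprintf("PWM[%d bp]", ncol(b)) else b
  cat(sprintf("Type-2 Pol III promoter model: A box %s, B box %s, spacer %d-%d bp\n",
              fmt(x$a_box), fmt(x$b_box), x$spacer_range[1], x$spacer_range[2]))
  invisible(x)
}

# mismatch count of `box` (IUPAC) at every start of `chars`; subject N never
# matches any box position
.box_mismatches <- function(chars, box) {
  w <- nchar(box)
  n <- length(chars) - w + 1
  if (n < 1) return(integer(0))
  codes <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(box, "")[[1]]], "")
  mm <- integer(n)
  for (j in seq_len(w)) {
    ok <- chars[j:(j + n - 1)] %in% codes[[j]]
    mm <- mm + !ok
  }
  mm
}

# starts (0-based) and width of passing box hits on the forward axis of `seq`
.box_hits <- function(seq_chars, seq_str, box, model) {
  if (is.matrix(box)) {
    w <- ncol(box)
    hits <- Biostrings::matchPWM(box, Biostrings::DNAString(seq_str),
                                 min.score = model$min_score)
    list(start = IRanges::start(hits) - 1L, width = w)
  } else {
    mm <- .box_mismatches(seq_chars, box)
    list(start = which(mm <= model$max_mismatches) - 1L, width = nchar(box))
  }
}

#' Scan a sequence for type-2 Pol III internal promoters
#'
#' Enumerates all (A box, B box) pairs on both strands where each box passes
#' its threshold, the B box lies downstream of the A box on the hit strand,
#' the boxes do not overlap, and the spacer satisfies the model range.
#' Coordinates are reported 0-based half-open on the forward axis of the
#' input sequence; on the minus strand the A box is therefore the
#' numerically rightmost box.
#'
#' @param sequence A DNA string over `A,C,G,T,N` (or a
#'   [Biostrings::DNAString]).
#' @param model A [promoter_model()].
#' @return A data.frame of hits: `strand`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `spacer`, `a_mismatches`, `b_mismatches`.
#' @export
scan_promoters <- function(sequence, model = promoter_model()) {
  seq_str <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", seq_str)) stop("sequence must be over {A,C,G,T,N}")
  L <- nchar(seq_str)
  empty <- data.frame(strand = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), spacer = integer(),
                      a_mismatches = integer(), b_mismatches = integer(),
                      stringsAsFactors = FALSE)
  out <- list(empty)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_str else revcomp(seq_str)
    chars <- strsplit(s, "")[[1]]
    a <- .box_hits(chars, s, model$a_box, model)
    b <- .box_hits(chars, s, model$b_box, model)
    if (length(a$start) == 0 || length(b$start) == 0) next
    a_mm <- if (!is.matrix(model$a_box))
      .box_mismatches(chars, model$a_box)[a$start + 1] else rep(NA_integer_, length(a$start))
    b_mm <- if (!is.matrix(model$b_box))
      .box_mismatches(chars, model$b_box)[b$start + 1] else rep(NA_integer_, length(b$start))
    pairs <- expand.grid(ai = seq_along(a$start), bi = seq_along(b$start))
    sp <- b$start[pairs$bi] - (a$start[pairs$ai] + a$width)
    # overlapping boxes are rejected regardless of the configured range
    keep <- sp >= max(model$spacer_range[1], 0L) & sp <= model$spacer_range[2]
    if (!any(keep)) next
    pairs <- pairs[keep, , drop = FALSE]
    sp <- sp[keep]
    a0 <- a$start[pairs$ai]; a1 <- a0 + a$width
    b0 <- b$start[pairs$bi]; b1 <- b0 + b$width
    if (strand == "-") {
      # map hit-strand coordinates back to the forward axis
      tmp_a0 <- L - a1; tmp_a1 <- L - a0
      tmp_b0 <- L - b1; tmp_b1 <- L - b0
      a0 <- tmp_a0; a1 <- tmp_a1; b0 <- tmp_b0; b1 <- tmp_b1
    }
    out[[length(out) + 1]] <- data.frame(
      strand = strand, a_start = a0, a_end = a1, b_start = b0, b_end = b1,
      spacer = sp, a_mismatches = a_mm[pairs$ai], b_mismatches = b_mm[pairs$bi],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$a_start, res$b_start), , drop = FALSE]
}

#' Classify elements as carrying a potentially functional type-2 promoter
#'
#' An element is potentially functional when at least one (A box, B box)
#' pair passes both box thresholds and the spacer constraint.
#'
#' @param sequences A character vector or [Biostrings::DNAStringSet] of
#'   element sequences.
#' @param model A [promoter_model()].
#' @return A named logical vector, one entry per element.
#' @export
classify_functional <- function(sequences, model = promoter_model()) {
  seqs <- as.character(sequences)
  res <- vapply(seqs, function(s) nrow(scan_promoters(s, model)) > 0,
                logical(1))
  if (!is.null(names(sequences))) names(res) <- names(sequences)
  res
}

#' Read / write promoter models as YAML
#'
#' The model file carries `a_box`, `b_box` (consensus strings, or named
#' lists of per-base probability rows for PWMs), `spacer_range`,
#' `max_mismatches` and `min_score`. An editable default model is shipped in
#' `inst/extdata/type2_promoter.yaml`.
#'
#' @param path YAML file path.
#' @return A `promoter_model`.
#' @export
read_promoter_model <- function(path) {
  y <- yaml::read_yaml(path)
  as_box <- function(b) {
    if (is.list(b)) {
      m <- do.call(rbind, b[c("A", "C", "G", "T")])
      rownames(m) <- c("A", "C", "G", "T")
      m
    } else b
  }
  promoter_model(a_box = as_box(y$a_box), b_box = as_box(y$b_box),
                 spacer_range = unlist(y$spacer_range),
                 max_mismatches = y$max_mismatches %||% 2L,
                 min_score = y$min_score %||% "80%")
}

#' @rdname read_promoter_model
#' @param model A `promoter_model` to write.
#' @export
write_promoter_model <- function(model, path) {
  as_y <- function(b) {
    if (is.matrix(b)) lapply(as.data.frame(t(b)), identity) else b
  }
  yaml::write_yaml(list(a_box = as_y(model$a_box), b_box = as_y(model$b_box),
                        spacer_range = as.list(model$spacer_range),
                        max_mismatches = model$max_mismatches,
                        min_score = model$min_score), path)
  invisible(path)
}

#' Report promoter hits relative to parent genomic coordinates
#'
#' @param hits Hits from [scan_promoters()].
#' @param contig Parent contig name.
#' @param offset 0-based genomic start of the element on the parent contig.
#' @param path Optional BED output path covering each hit from A-box start
#'   to B-box end.
#' @return The hits with genomic coordinates added.
#' @export
hits_to_genomic <- function(hits, contig, offset, path = NULL) {
  if (nrow(hits) == 0) return(hits)
  lo <- pmin(hits$a_start, hits$b_start) + offset
  hi <- pmax(hits$a_end, hits$b_end) + offset
  hits$contig <- contig
  hits$genomic_start <- lo
  hits$genomic_end <- hi
  if (!is.null(path)) {
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(lo + 1L, hi),
                                 strand = hits$strand)
    names(gr) <- sprintf("type2_hit_%d", seq_len(nrow(hits)))
    rtracklayer::export(gr, path, format = "bed")
  }
  hits
}
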