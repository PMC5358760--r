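#' Generate a synthetic genome from a specification
#'
#' Builds random background sequence for each contig, inserts (overwrites)
#' independently mutated copies of each repeat family consensus at recorded
#' non-overlapping positions, resolves the Pol II pileup window of every
#' planted roadblock (the window abuts the Pol III unit boundary first
#' encountered by a polymerase travelling in the host gene's direction), and
#' assembles a ground-truth manifest mapping every planted feature to exact
#' coordinates. Repeat divergence is substitution-only, so exact-string tag
#' mapping remains well defined.
#'
#' @param spec A [genome_spec()] object.
#' @return A `synthetic_genome` list with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `contig_lengths`, `genes` (data.frame),
#'   `pol3_units`, `roadblocks` (with resolved `window_start`/`window_end`),
#'   `repeats` (one row per inserted copy) and `manifest`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    seqs <- lapply(spec$contigs, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE))

    genes_df <- .genes_as_df(spec$genes)
    rb <- .resolve_roadblocks(spec, genes_df)

    # regions repeat copies must avoid, so planted signal stays unconfounded
    avoid <- rbind(
      genes_df[, c("contig", "start", "end")],
      spec$pol3_units[, c("contig", "start", "end"), drop = FALSE],
      if (nrow(rb) > 0)
        data.frame(contig = rb$contig, start = rb$window_start,
                   end = rb$window_end)
    )

    repeats <- list()
    for (fam in spec$repeat_families) {
      cons <- toupper(fam$consensus)
      w <- nchar(cons)
      strands <- rep_len(fam$strands %||% "+", fam$copy_number)
      div <- fam$divergence %||% 0
      for (k in seq_len(fam$copy_number)) {
        pos <- .place_copy(spec$contigs, w, avoid)
        copy_seq <- .mutate_seq(cons, div)
        ins <- if (strands[k] == "-") revcomp(copy_seq) else copy_seq
        seqs[[pos$contig]][(pos$start + 1):(pos$start + w)] <-
          strsplit(ins, "")[[1]]
        rec <- data.frame(contig = pos$contig, start = pos$start,
                          end = pos$start + w, strand = strands[k],
                          family = fam$name %||% "repeat",
                          copy_id = sprintf("%s_copy%02d", fam$name %||% "repeat", k),
                          stringsAsFactors = FALSE)
        repeats[[length(repeats) + 1]] <- rec
        avoid <- rbind(avoid, rec[, c("contig", "start", "end")])
      }
    }
    repeats <- if (length(repeats) > 0) do.call(rbind, repeats) else
      new_intervals(family = character(), copy_id = character())

    dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
    names(dna) <- names(spec$contigs)

    manifest <- list(
      seed = spec$seed,
      contigs = as.list(spec$contigs),
      genes = genes_df,
      pol3_units = spec$pol3_units,
      roadblocks = rb,
      repeats = repeats
    )
    structure(list(sequences = dna, contig_lengths = spec$contigs,
                   genes = genes_df, pol3_units = spec$pol3_units,
                   roadblocks = rb, repeats = repeats,
                   manifest = manifest, spec = spec),
              class = "synthetic_genome")
  })
}

.genes_as_df <- function(genes) {
  if (length(genes) == 0)
    return(data.frame(id = character(), contig = character(), start = integer(),
                      end = integer(), strand = character(), tss = integer(),
                      tes = integer(), tss_peak_fold = numeric(),
                      body_level = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(genes, function(g)
    data.frame(id = g$id, contig = g$contig, start = g$start, end = g$end,
               strand = g$strand, tss = g$tss, tes = g$tes,
               tss_peak_fold = g$tss_peak_fold, body_level = g$body_level,
               stringsAsFactors = FALSE)))
}

# The pileup window is placed at the Pol III unit boundary facing the host
# gene's TSS: [start - width, start) for a '+' host, [end, end + width) for
# a '-' host.
.resolve_roadblocks <- function(spec, genes_df) {
  rb <- spec$roadblocks
  if (nrow(rb) == 0)
    return(data.frame(unit = integer(), contig = character(),
                      window_start = integer(), window_end = integer(),
                      fold = numeric(), width = integer(), nelf = logical(),
                      host_gene = character(), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(rb)), function(i) {
    u <- spec$pol3_units[rb$unit[i], ]
    host <- genes_df[genes_df$contig == u$contig &
                       genes_df$start <= u$start & genes_df$end >= u$end, ]
    if (nrow(host) == 0)
      stop("roadblock ", i, ": pol3 unit ", rb$unit[i],
           " is not contained in any gene")
    host <- host[1, ]
    w <- as.integer(rb$width[i])
    if (host$strand == "+") {
      ws <- u$start - w; we <- u$start
    } else {
      ws <- u$end; we <- u$end + w
    }
    data.frame(unit = rb$unit[i], contig = u$contig,
               window_start = as.integer(ws), window_end = as.integer(we),
               fold = rb$fold[i], width = w, nelf = rb$nelf[i],
               host_gene = host$id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.place_copy <- function(contigs, width, avoid, max_tries = 2000) {
  lens <- contigs - width
  lens[lens < 0] <- 0
  for (try in seq_len(max_tries)) {
    ctg <- sample(names(contigs), 1, prob = pmax(lens, 1e-9))
    if (contigs[[ctg]] < width) next
    s <- sample.int(contigs[[ctg]] - width + 1L, 1) - 1L
    sub <- avoid[avoid$contig == ctg, , drop = FALSE]
    if (nrow(sub) == 0 ||
        all(interval_overlap_bp(s, s + width, sub$start, sub$end) == 0))
      return(list(contig = ctg, start = s))
  }
  stop("could not place repeat copy of width ", width,
       " without overlapping planted features")
}

# Substitution-only mutation at per-base probability `div`; `spare` gives
# 1-based positions held invariant.
.mutate_seq <- function(s, div, spare = integer()) {
  if (div <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < div)
  hit <- setdiff(hit, spare)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a family of diverged element copies
#'
#' Generates `n` independently mutated (substitution-only) copies of a
#' consensus. When `plant_boxes` is supplied, an A box and a B box are first
#' written into the consensus separated by exactly `spacer` bp, and the box
#' positions are spared from mutation, so every copy retains an intact
#' internal type-2 promoter at the exact spacer length.
#'
#' @param consensus DNA string.
#' @param n Number of copies.
#' @param divergence Per-base substitution probability in \[0, 1\].
#' @param plant_boxes Optional list with `a_box`, `b_box` (DNA strings),
#'   `spacer` (bp between A-box end and B-box start) and optional `at`
#'   (0-based offset of the A box in the element, default 10).
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] of the copies.
#' @export
simulate_element_family <- function(consensus, n, divergence,
                                    plant_boxes = NULL, seed = 1L) {
  stopifnot(n >= 1, divergence >= 0, divergence <= 1)
  consensus <- toupper(consensus)
  spare <- integer()
  if (!is.null(plant_boxes)) {
    at <- plant_boxes$at %||% 10L
    a <- toupper(plant_boxes$a_box); b <- toupper(plant_boxes$b_box)
    sp <- plant_boxes$spacer
    b_at <- at + nchar(a) + sp
    if (b_at + nchar(b) > nchar(consensus))
      stop("planted boxes do not fit in the consensus")
    chars <- strsplit(consensus, "")[[1]]
    chars[(at + 1):(at + nchar(a))] <- strsplit(a, "")[[1]]
    chars[(b_at + 1):(b_at + nchar(b))] <- strsplit(b, "")[[1]]
    consensus <- paste(chars, collapse = "")
    spare <- c((at + 1):(at + nchar(a)), (b_at + 1):(b_at + nchar(b)))
  }
  with_seed(seed, {
    copies <- vapply(seq_len(n), function(i)
      .mutate_seq(consensus, divergence, spare = spare), character(1))
    out <- Biostrings::DNAStringSet(copies)
    names(out) <- sprintf("copy_%03d", seq_len(n))
    out
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome\n")
  cat(sprintf("  %d contig(s), %s bp\n", length(x$contig_lengths),
              format(sum(x$contig_lengths), big.mark = ",")))
  cat(sprintf("  genes: %d | Pol III units: %d | roadblocks: %d | repeat copies: %d\n",
              nrow(x$genes), nrow(x$pol3_units), nrow(x$roadblocks),
              nrow(x$repeats)))
  invisible(x)
}
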