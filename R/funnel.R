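#' Run the full nesting / roadblock funnel
#'
#' Chains the analysis stages: peak confirmation by recomputed weighted
#' occupancy, nested-unit discovery, cross-confirmation against a second
#' peak set, roadblock detection on the Pol II track, and NELF/DSIF
#' classification. Stage counts are reported after each step; the funnel is
#' monotone (each stage only removes or annotates events). When no Pol II
#' track is supplied the roadblock stages are skipped gracefully.
#'
#' @param pol3_peaks Pol III peak intervals (the candidate set).
#' @param genes Gene table.
#' @param ip,input IP and input `coverage_track`s for confirmation.
#' @param pol2 Optional Pol II `coverage_track`.
#' @param nelf,dsif Optional elongation-factor `coverage_track`s.
#' @param second_peakset Optional second peak set for cross-confirmation.
#' @param confirm_threshold Occupancy score threshold for confirmation.
#' @param pseudocount Pseudocount for occupancy scoring.
#' @param promoter_exclusion Bp excluded downstream of the TSS for nesting.
#' @param max_summit_distance Summit distance for cross-confirmation (bp).
#' @param window Roadblock window width (bp).
#' @param background_exclusion TSS exclusion for the Pol II background (bp).
#' @param q_threshold FDR threshold for significant roadblock calls.
#' @param nelf_threshold NELF window enrichment threshold.
#' @param gene_pol2_threshold Mean gene-body Pol II bin mass for a host gene
#'   to count as "Pol II occupied".
#' @return A `pol3_funnel` object: `counts` (named stage counts), `events`
#'   (per-event table) and `params`.
#' @export
run_funnel <- function(pol3_peaks, genes, ip, input, pol2 = NULL,
                       nelf = NULL, dsif = NULL, second_peakset = NULL,
                       confirm_threshold = 1, pseudocount = 1,
                       promoter_exclusion = 250L, max_summit_distance = 200L,
                       window = 200L, background_exclusion = 500L,
                       q_threshold = 0.05, nelf_threshold = 2,
                       gene_pol2_threshold = 1) {
  peaks <- as.data.frame(pol3_peaks, stringsAsFactors = FALSE)
  params <- list(confirm_threshold = confirm_threshold,
                 pseudocount = pseudocount,
                 promoter_exclusion = promoter_exclusion,
                 max_summit_distance = max_summit_distance,
                 window = window, background_exclusion = background_exclusion,
                 q_threshold = q_threshold, nelf_threshold = nelf_threshold,
                 gene_pol2_threshold = gene_pol2_threshold)

  counts <- c(peaks = nrow(peaks), confirmed = 0L, nested = 0L,
              cross_confirmed = NA_integer_, host_genes = 0L,
              pol2_occupied_genes = NA_integer_, roadblocks = NA_integer_,
              internal_tss = NA_integer_)
  if (nrow(peaks) == 0) {
    counts[] <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
    return(structure(list(counts = counts,
                          events = find_nested(peaks, genes),
                          params = params, skipped = character()),
                     class = "pol3_funnel"))
  }

  conf <- confirm_peaks(peaks, ip, input, threshold = confirm_threshold,
                        pseudocount = pseudocount)
  counts["confirmed"] <- conf$n_confirmed

  events <- find_nested(conf$confirmed, genes,
                        promoter_exclusion = promoter_exclusion)
  counts["nested"] <- nrow(events)
  counts["host_genes"] <- length(unique(events$gene_id))

  skipped <- character()
  if (!is.null(second_peakset)) {
    events <- cross_confirm(events, second_peakset,
                            max_summit_distance = max_summit_distance)
    events <- events[isTRUE(nrow(events) > 0) & events$cross_confirmed, ,
                     drop = FALSE]
    counts["cross_confirmed"] <- nrow(events)
    counts["host_genes"] <- length(unique(events$gene_id))
  } else {
    skipped <- c(skipped, "cross_confirm")
  }

  if (!is.null(pol2)) {
    gene_ids <- unique(events$gene_id)
    occ <- vapply(gene_ids, function(id) {
      g <- genes[genes$id == id, ][1, ]
      mean(.bin_values(pol2, g$contig, g$start, g$end)) >= gene_pol2_threshold
    }, logical(1))
    counts["pol2_occupied_genes"] <- sum(occ)

    events <- detect_roadblocks(pol2, events, genes, window = window,
                                background_exclusion = background_exclusion)
    events <- classify_accumulation(events, nelf = nelf, dsif = dsif,
                                    enrich_threshold = nelf_threshold)
    sig <- !is.na(events$q) & events$q < q_threshold
    counts["roadblocks"] <- sum(sig & events$classification != "putative_internal_TSS")
    counts["internal_tss"] <- sum(sig & events$classification == "putative_internal_TSS")
  } else {
    skipped <- c(skipped, "detect_roadblock", "classify_accumulation")
  }

  structure(list(counts = counts, events = events, params = params,
                 skipped = skipped),
            class = "pol3_funnel")
}

#' @export
print.pol3_funnel <- function(x, ...) {
  cat("Pol III nesting / roadblock funnel\n")
  lab <- c(peaks = "input peaks", confirmed = "confirmed by weighted occupancy",
           nested = "nested in Pol II genes", cross_confirmed = "cross-confirmed",
           host_genes = "host genes", pol2_occupied_genes = "Pol II-occupied hosts",
           roadblocks = "roadblock calls (q < threshold)",
           internal_tss = "putative internal TSS")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-34s %s\n", lab[[nm]],
                if (is.na(v)) "(skipped)" else format(v)))
  }
  if (length(x$skipped) > 0)
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pol3_funnel <- function(object, ...) {
  print(object)
  if (nrow(object$events) > 0) {
    cat("\nPer-event table:\n")
    cols <- intersect(c("peak_id", "gene_id", "orientation", "fold", "q",
                        "classification"), names(object$events))
    print(object$events[, cols], row.names = FALSE)
  }
  invisible(object)
}

#' Write funnel outputs
#'
#' Persists the per-event table as TSV, the stage counts and parameters as a
#' JSON report, and the roadblock windows as BED.
#'
#' @param funnel A `pol3_funnel`.
#' @param outdir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_funnel <- function(funnel, outdir) {
  stopifnot(inherits(funnel, "pol3_funnel"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(events = file.path(outdir, "events.tsv"),
             report = file.path(outdir, "funnel_report.json"),
             windows = file.path(outdir, "roadblock_windows.bed"))
  utils::write.table(funnel$events, paths[["events"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(counts = as.list(funnel$counts),
                            params = funnel$params,
                            skipped = funnel$skipped),
                       paths[["report"]], auto_unbox = TRUE, digits = NA)
  ev <- funnel$events
  if (!is.null(ev$window_start) && nrow(ev) > 0) {
    sig <- !is.na(ev$q) & ev$q < funnel$params$q_threshold
    wb <- ev[sig, , drop = FALSE]
    if (nrow(wb) > 0) {
      gr <- GenomicRanges::GRanges(wb$contig,
              IRanges::IRanges(wb$window_start + 1L, wb$window_end))
      names(gr) <- paste0(wb$peak_id, "_window")
      rtracklayer::export(gr, paths[["windows"]], format = "bed")
    }
  }
  invisible(paths)
}
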