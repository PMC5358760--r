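#' Find Pol III peaks nested inside Pol II transcription units
#'
#' A peak is called nested when it is fully contained within the host gene
#' span minus a promoter exclusion downstream of the TSS, so TSS-proximal
#' pausing signal is never mistaken for a nested Pol III unit. Orientation is
#' sense when peak and host strands agree, antisense otherwise.
#'
#' @param pol3_peaks Peak intervals (`contig`, `start`, `end`, `strand`,
#'   optional `id`).
#' @param genes Gene table as produced by [generate_genome()] (`id`,
#'   `contig`, `start`, `end`, `strand`, `tss`, `tes`).
#' @param promoter_exclusion Bp excluded downstream of the TSS (default 250).
#' @param fallback_strand Optional named character vector (peak id ->
#'   strand), e.g. from a promoter scan, consulted for peaks without strand.
#' @return A data.frame of nesting events: peak and host coordinates,
#'   `orientation`, `distance_to_host_tss`, `cross_confirmed` (`NA` until
#'   [cross_confirm()]).
#' @export
find_nested <- function(pol3_peaks, genes, promoter_exclusion = 250L,
                        fallback_strand = NULL) {
  peaks <- as.data.frame(pol3_peaks, stringsAsFactors = FALSE)
  empty <- data.frame(peak_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      peak_strand = character(), gene_id = character(),
                      gene_strand = character(), orientation = character(),
                      distance_to_host_tss = integer(),
                      cross_confirmed = logical(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(empty)
  if (is.null(peaks$id)) peaks$id <- sprintf("peak_%03d", seq_len(nrow(peaks)))
  if (is.null(peaks$strand)) peaks$strand <- NA_character_

  # interior span open to elongating Pol II, oriented by the host strand
  lo <- ifelse(genes$strand == "+", genes$tss + promoter_exclusion, genes$tes)
  hi <- ifelse(genes$strand == "+", genes$tes, genes$tss - promoter_exclusion)

  ev <- list()
  for (i in seq_len(nrow(peaks))) {
    host <- which(genes$contig == peaks$contig[i] &
                    peaks$start[i] >= lo & peaks$end[i] <= hi)
    for (h in host) {
      ps <- peaks$strand[i]
      if (is.na(ps) || !ps %in% c("+", "-")) {
        ps <- unname(fallback_strand[peaks$id[i]])
        if (is.null(ps) || is.na(ps))
          stop("peak ", peaks$id[i], " has no strand and no fallback strand; ",
               "cannot assign orientation")
      }
      mid <- (peaks$start[i] + peaks$end[i]) %/% 2
      ev[[length(ev) + 1]] <- data.frame(
        peak_id = peaks$id[i], contig = peaks$contig[i],
        start = peaks$start[i], end = peaks$end[i], peak_strand = ps,
        gene_id = genes$id[h], gene_strand = genes$strand[h],
        orientation = if (ps == genes$strand[h]) "sense" else "antisense",
        distance_to_host_tss = abs(mid - genes$tss[h]),
        cross_confirmed = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0) return(empty)
  do.call(rbind, ev)
}

#' Cross-confirm nesting events against a second peak set
#'
#' An event is confirmed when a summit in the second set lies within
#' `max_summit_distance` bp of the event peak's summit on the same contig.
#' Summits default to interval midpoints; a `summit` column (absolute
#' position) is used when present.
#'
#' @param events Events from [find_nested()].
#' @param second_peakset Peak intervals of the second dataset.
#' @param max_summit_distance Maximum summit-to-summit distance in bp.
#' @return The events with `cross_confirmed` filled in.
#' @export
cross_confirm <- function(events, second_peakset, max_summit_distance = 200L) {
  if (nrow(events) == 0) return(events)
  second <- as.data.frame(second_peakset, stringsAsFactors = FALSE)
  if (nrow(second) == 0) {
    events$cross_confirmed <- FALSE
    return(events)
  }
  s2 <- if (!is.null(second$summit)) second$summit
        else (second$start + second$end) %/% 2
  ev_summit <- (events$start + events$end) %/% 2
  events$cross_confirmed <- vapply(seq_len(nrow(events)), function(i) {
    any(second$contig == events$contig[i] &
          abs(s2 - ev_summit[i]) <= max_summit_distance)
  }, logical(1))
  events
}

#' Detect Pol II roadblock accumulations at nesting events
#'
#' For each event a window of `window` bp is placed abutting the Pol III
#' unit boundary that faces the host gene's TSS -- the side first reached by
#' a polymerase travelling in the host gene's direction. The background is
#' the median Pol II bin signal over the gene body, excluding the TSS
#' region (+/- `background_exclusion` bp) and the window itself. The fold is
#' the window mean over that background; the p-value is a Poisson upper-tail
#' test on the window tag mass with the background-scaled expectation, and
#' q-values are Benjamini-Hochberg adjusted across all events in the run.
#'
#' @param pol2 Pol II `coverage_track`.
#' @param events Events from [find_nested()].
#' @param genes Gene table (to orient windows and define gene bodies).
#' @param window Window width in bp.
#' @param background_exclusion Bp excluded around the TSS for the background.
#' @return The events with `window_start`, `window_end`, `fold`, `p`, `q`
#'   and `classification` columns (`"unclassified"` until
#'   [classify_accumulation()]; events with zero background are flagged in
#'   `flag`).
#' @export
detect_roadblocks <- function(pol2, events, genes, window = 200L,
                              background_exclusion = 500L) {
  if (nrow(events) == 0) {
    for (col in c("window_start", "window_end", "fold", "p", "q"))
      events[[col]] <- numeric(0)
    events$classification <- character(0)
    events$flag <- character(0)
    return(events)
  }
  stopifnot(inherits(pol2, "coverage_track"))
  res <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    g <- genes[genes$id == e$gene_id, ][1, ]
    if (g$strand == "+") {
      ws <- e$start - window; we <- e$start
    } else {
      ws <- e$end; we <- e$end + window
    }
    ws <- max(ws, 0L); we <- min(we, pol2$contig_lengths[[e$contig]])

    bs <- pol2$bin_size
    v <- pol2$bins[[e$contig]]
    b <- seq_along(v) - 1L
    mid <- b * bs + bs / 2
    in_body <- mid >= g$start & mid < g$end
    in_tss <- mid >= g$tss - background_exclusion &
      mid < g$tss + background_exclusion
    in_win <- mid >= ws & mid < we
    bg_bins <- v[in_body & !in_tss & !in_win]
    win_bins <- v[in_win]
    bg <- stats::median(bg_bins)
    if (!is.finite(bg) || bg <= 0) {
      return(data.frame(window_start = ws, window_end = we, fold = NA_real_,
                        p = NA_real_, flag = "zero_background",
                        stringsAsFactors = FALSE))
    }
    fold <- mean(win_bins) / bg
    # convert bin mass to approximate tag counts for the Poisson test
    to_tags <- bs / pol2$tag_length
    obs <- sum(win_bins) * to_tags
    lambda <- bg * length(win_bins) * to_tags
    p <- stats::ppois(ceiling(obs) - 1, lambda, lower.tail = FALSE)
    data.frame(window_start = ws, window_end = we, fold = fold, p = p,
               flag = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  events <- cbind(events, res)
  events$q <- stats::p.adjust(events$p, method = "BH")
  events$classification <- ifelse(events$flag == "zero_background",
                                  "unclassified", NA_character_)
  events
}

#' Classify intragenic Pol II accumulations by NELF/DSIF logic
#'
#' NELF marks promoter-proximal pausing only, so NELF enrichment at an
#' intragenic Pol II accumulation argues for an unannotated internal TSS
#' rather than a roadblock; DSIF travels with elongating Pol II and may be
#' present in either case. Events with window NELF enrichment at or above
#' the threshold are classified `putative_internal_TSS`; below it,
#' `roadblock`; without a NELF track, `unclassified`. Enrichment is the
#' observed window tag mass over the expectation under a uniform genome-wide
#' distribution of the track's tags.
#'
#' @param calls Events from [detect_roadblocks()].
#' @param nelf,dsif Optional `coverage_track`s.
#' @param enrich_threshold Minimal NELF window enrichment to call an
#'   internal TSS.
#' @return The calls with `nelf_enrichment`, `dsif_enrichment` and
#'   `classification` filled in.
#' @export
classify_accumulation <- function(calls, nelf = NULL, dsif = NULL,
                                  enrich_threshold = 2) {
  if (nrow(calls) == 0) {
    calls$nelf_enrichment <- numeric(0)
    calls$dsif_enrichment <- numeric(0)
    return(calls)
  }
  win_enrich <- function(track, contig, ws, we) {
    if (is.null(track)) return(NA_real_)
    obs <- locus_mass(track, contig, ws, we)
    expected <- track$total_weight * (we - ws) / sum(track$contig_lengths)
    obs / expected
  }
  calls$nelf_enrichment <- vapply(seq_len(nrow(calls)), function(i)
    win_enrich(nelf, calls$contig[i], calls$window_start[i],
               calls$window_end[i]), numeric(1))
  calls$dsif_enrichment <- vapply(seq_len(nrow(calls)), function(i)
    win_enrich(dsif, calls$contig[i], calls$window_start[i],
               calls$window_end[i]), numeric(1))
  keep_flag <- calls$flag == "zero_background"
  calls$classification <- ifelse(
    keep_flag | is.null(nelf) | is.na(calls$nelf_enrichment), "unclassified",
    ifelse(calls$nelf_enrichment >= enrich_threshold,
           "putative_internal_TSS", "roadblock"))
  calls
}
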