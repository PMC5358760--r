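#' Score loci as log2(IP/input)
#'
#' For each locus the IP and input masses are summed over the locus in tag
#' units, library-size normalized to tags per million, and combined into the
#' occupancy score \eqn{S = \log_2((ip + p) / (input + p))} with pseudocount
#' \eqn{p > 0}.
#'
#' @param ip,input `coverage_track`s on the same genome and bin size.
#' @param loci Intervals (`contig`, `start`, `end`, and optionally `strand`,
#'   `id`, `class`).
#' @param pseudocount Pseudocount `p` in normalized tags per locus.
#' @return A data.frame of locus scores: `id`, `class`, coordinates,
#'   `ip_mass`, `input_mass`, `S`, `percent` (`NA` until
#'   [normalize_percent()] is applied).
#' @export
score_loci <- function(ip, input, loci, pseudocount = 1) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"),
            pseudocount > 0)
  if (ip$bin_size != input$bin_size)
    stop("IP and input tracks have different bin sizes")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$id)) loci$id <- sprintf("locus_%03d", seq_len(nrow(loci)))
  if (is.null(loci$class)) loci$class <- "other"
  if (is.null(loci$strand)) loci$strand <- "*"

  ipm <- vapply(seq_len(nrow(loci)), function(i)
    locus_mass(ip, loci$contig[i], loci$start[i], loci$end[i]), numeric(1))
  inm <- vapply(seq_len(nrow(loci)), function(i)
    locus_mass(input, loci$contig[i], loci$start[i], loci$end[i]), numeric(1))
  ipm <- ipm * 1e6 / ip$total_weight
  inm <- inm * 1e6 / input$total_weight
  data.frame(id = loci$id, class = loci$class, contig = loci$contig,
             start = loci$start, end = loci$end, strand = loci$strand,
             ip_mass = ipm, input_mass = inm,
             S = log2((ipm + pseudocount) / (inm + pseudocount)),
             percent = NA_real_, stringsAsFactors = FALSE)
}

#' @rdname score_loci
#' @param locus A single interval (list or one-row data.frame).
#' @return For `score_locus()`, a one-row locus-score data.frame.
#' @export
score_locus <- function(ip, input, locus, pseudocount = 1) {
  score_loci(ip, input, as.data.frame(locus, stringsAsFactors = FALSE),
             pseudocount = pseudocount)
}

#' Normalize occupancy scores to percentages
#'
#' Scores are expressed as `100 * max(S, 0) / S_ref` relative to a reference
#' locus (or the maximum score), so the reference reads 100 and depleted loci
#' (negative S) are floored at 0.
#'
#' @param scores Locus scores from [score_loci()].
#' @param reference A locus `id`, or `"max"` for the highest-scoring locus.
#' @return The scores with the `percent` column filled in.
#' @export
normalize_percent <- function(scores, reference = "max") {
  s_ref <- if (identical(reference, "max")) {
    max(scores$S)
  } else {
    if (!reference %in% scores$id) stop("reference locus '", reference,
                                        "' not present")
    scores$S[scores$id == reference][1]
  }
  if (s_ref <= 0) stop("reference score must be positive for percentage normalization")
  scores$percent <- 100 * pmax(scores$S, 0) / s_ref
  scores
}

#' Mean occupancy score of a locus class
#'
#' Arithmetic mean of `S` over loci carrying the class label whose score
#' reaches the occupancy threshold (the "Pol III-occupied" set).
#'
#' @param scores Locus scores from [score_loci()].
#' @param class Class label (`"SINE"`, `"tRNA"`, `"MIR"`, ...).
#' @param threshold Minimal `S` to count as occupied (default 1, i.e.
#'   two-fold IP over input).
#' @return The mean score (NA if no locus qualifies).
#' @export
class_mean <- function(scores, class, threshold = 1) {
  sel <- scores$class == class & scores$S >= threshold
  if (!any(sel)) return(NA_real_)
  mean(scores$S[sel])
}

#' Confirm externally supplied peaks by recomputed weighted occupancy
#'
#' Rescores each peak from the (multi-mapping-aware) IP and input tracks and
#' keeps those whose score reaches the threshold. This is the step that
#' separates peaks supported by properly weighted repetitive signal from
#' artifacts of discarded or misassigned multi-mappers.
#'
#' @param peaks Peak intervals (`contig`, `start`, `end`, ...).
#' @param ip,input `coverage_track`s.
#' @param threshold Minimal occupancy score `S` to confirm.
#' @param pseudocount Pseudocount for scoring.
#' @return A `peak_confirmation` list: `peaks` (all, with `S` and
#'   `confirmed`), `confirmed` (the subset), `n_input`, `n_confirmed`.
#' @export
confirm_peaks <- function(peaks, ip, input, threshold = 1, pseudocount = 1) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) {
    return(structure(list(peaks = peaks, confirmed = peaks,
                          n_input = 0L, n_confirmed = 0L),
                     class = "peak_confirmation"))
  }
  sc <- score_loci(ip, input, peaks, pseudocount = pseudocount)
  peaks$S <- sc$S
  peaks$confirmed <- sc$S >= threshold
  structure(list(peaks = peaks,
                 confirmed = peaks[peaks$confirmed, , drop = FALSE],
                 n_input = nrow(peaks),
                 n_confirmed = sum(peaks$confirmed)),
            class = "peak_confirmation")
}

#' @export
print.peak_confirmation <- function(x, ...) {
  cat(sprintf("Peak confirmation: %d of %d peaks confirmed\n",
              x$n_confirmed, x$n_input))
  invisible(x)
}
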