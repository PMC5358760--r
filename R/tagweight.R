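#' Assign weights to multi-mapping tags
#'
#' A sequenced tag that was observed \eqn{c} times and matches \eqn{m}
#' genomic locations contributes total weight \eqn{c}, split over its
#' matches. Two schemes are provided:
#' \describe{
#'   \item{uniform}{every match receives \eqn{c/m} — the minimal scheme
#'     consistent with weighting by times-sequenced and number of genomic
#'     matches.}
#'   \item{em}{weights start at \eqn{c/m} and are iteratively redistributed
#'     proportionally to the local coverage anchored by uniquely mapping
#'     tags (\eqn{m = 1}) in a window around each match, until the largest
#'     per-location change drops below `tol` or `max_iter` is reached. A
#'     repeat copy flanked by more unique signal therefore attracts more of
#'     the ambiguous weight.}
#' }
#' Per-tag weights always sum to \eqn{c} exactly, so total assigned weight
#' equals total sequencing depth under both schemes.
#'
#' @param tags A `tag_set`.
#' @param scheme `"uniform"` or `"em"`.
#' @param window Half-width in bp of the local-coverage window around each
#'   match (EM scheme).
#' @param tol Convergence tolerance on the maximum per-location weight
#'   change (EM scheme).
#' @param max_iter Maximum EM iterations.
#' @return A data.frame of weighted placements: `contig`, `start`, `end`,
#'   `strand`, `tag_id`, `weight`.
#' @export
assign_weights <- function(tags, scheme = c("uniform", "em"),
                           window = 500L, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(tags, "tag_set"))
  scheme <- match.arg(scheme)
  tg <- tags$tags
  mm <- tags$matches
  if (nrow(tg) == 0) stop("empty tag list")
  ti <- match(mm$tag_id, tg$tag_id)
  if (anyNA(ti)) stop("matches refer to unknown tag ids")
  if (!all(tg$tag_id %in% mm$tag_id))
    stop("tag with empty match list: ",
         tg$tag_id[which(!tg$tag_id %in% mm$tag_id)[1]])

  w <- tg$c[ti] / tg$m[ti]
  if (scheme == "em") {
    multi <- tg$m[ti] > 1
    if (!any(multi)) {
      # nothing to redistribute
    } else if (!any(tg$m == 1)) {
      warning("EM requested but no uniquely mapping tags; falling back to uniform c/m")
    } else {
      w <- .em_weights(tg, mm, ti, w, window, tol, max_iter)
    }
  }
  out <- mm
  out$weight <- w
  out
}

.em_weights <- function(tg, mm, ti, w, window, tol, max_iter) {
  mid <- (mm$start + mm$end) / 2
  is_uni <- tg$m[ti] == 1
  multi_rows <- which(!is_uni)

  ctg_f <- factor(mm$contig)
  # per-contig sorted unique-tag midpoints with cumulative weights (fixed)
  uni_by_ctg <- lapply(levels(ctg_f), function(ctg) {
    r <- which(is_uni & mm$contig == ctg)
    o <- order(mid[r])
    list(mid = mid[r][o], cw = cumsum(w[r][o]))
  })
  names(uni_by_ctg) <- levels(ctg_f)

  wsum <- function(sorted_mid, cum_w, lo, hi) {
    if (length(sorted_mid) == 0) return(numeric(length(lo)))
    i_hi <- findInterval(hi, sorted_mid)
    i_lo <- findInterval(lo, sorted_mid, left.open = TRUE)
    hi_s <- ifelse(i_hi > 0, cum_w[pmax(i_hi, 1)], 0) * (i_hi > 0)
    lo_s <- ifelse(i_lo > 0, cum_w[pmax(i_lo, 1)], 0) * (i_lo > 0)
    hi_s - lo_s
  }

  # neighbour rows of the same tag within the window (incl. the row itself),
  # so a tag's own mass never attracts itself
  same_tag_nb <- vector("list", length(multi_rows))
  names(same_tag_nb) <- as.character(multi_rows)
  by_tag <- split(multi_rows, mm$tag_id[multi_rows])
  for (rows in by_tag) {
    for (j in seq_along(rows)) {
      r <- rows[j]
      nb <- rows[mm$contig[rows] == mm$contig[r] &
                   abs(mid[rows] - mid[r]) <= window]
      same_tag_nb[[as.character(r)]] <- nb
    }
  }

  multi_ctg <- mm$contig[multi_rows]
  lo <- mid[multi_rows] - window
  hi <- mid[multi_rows] + window

  for (iter in seq_len(max_iter)) {
    # per-contig sorted multi midpoints with current cumulative weights
    multi_by_ctg <- lapply(levels(ctg_f), function(ctg) {
      r <- multi_rows[multi_ctg == ctg]
      o <- order(mid[r])
      list(mid = mid[r][o], cw = cumsum(w[r][o]))
    })
    names(multi_by_ctg) <- levels(ctg_f)

    local <- numeric(length(multi_rows))
    for (ctg in levels(ctg_f)) {
      sel <- which(multi_ctg == ctg)
      if (length(sel) == 0) next
      u <- uni_by_ctg[[ctg]]
      m2 <- multi_by_ctg[[ctg]]
      local[sel] <- wsum(u$mid, u$cw, lo[sel], hi[sel]) +
        wsum(m2$mid, m2$cw, lo[sel], hi[sel])
    }
    # remove each tag's own contribution to its windows
    own <- vapply(seq_along(multi_rows), function(j) {
      sum(w[same_tag_nb[[as.character(multi_rows[j])]]])
    }, numeric(1))
    local <- pmax(local - own, 0)

    new_w <- w
    for (rows in by_tag) {
      li <- local[match(rows, multi_rows)]
      tot <- sum(li)
      cc <- tg$c[ti[rows[1]]]
      new_w[rows] <- if (tot > 0) cc * li / tot else cc / length(rows)
    }
    delta <- max(abs(new_w - w))
    w <- new_w
    if (delta < tol) break
  }
  w
}

#' Bin weighted placements into a coverage track
#'
#' Each placement adds its weight to every bin it overlaps, prorated by the
#' overlapped fraction: a bin receives `weight * overlap_bp / bin_size`, so
#' the summed track mass equals total weight times placement length over bin
#' size. Coverage is strand-collapsed.
#'
#' @param placements Weighted placements from [assign_weights()].
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param bin_size Bin width in bp.
#' @return A `coverage_track`: per-contig bin vectors plus `bin_size`,
#'   `tag_length` and `total_weight` (the conserved sum of multiplicities).
#' @export
build_coverage <- function(placements, contig_lengths, bin_size = 10L) {
  stopifnot(nrow(placements) > 0, !is.null(names(contig_lengths)))
  bin_size <- as.integer(bin_size)
  widths <- unique(placements$end - placements$start)
  tag_length <- as.integer(stats::median(placements$end - placements$start))

  bins <- lapply(contig_lengths, function(L)
    numeric(ceiling(L / bin_size)))

  fb <- placements$start %/% bin_size
  lb <- (placements$end - 1L) %/% bin_size
  span <- max(lb - fb)
  pieces <- vector("list", span + 1)
  for (k in 0:span) {
    sel <- which(fb + k <= lb)
    if (length(sel) == 0) next
    b <- fb[sel] + k
    ov <- pmin(placements$end[sel], (b + 1) * bin_size) -
      pmax(placements$start[sel], b * bin_size)
    pieces[[k + 1]] <- data.frame(contig = placements$contig[sel], bin = b,
                                  val = placements$weight[sel] * ov / bin_size,
                                  stringsAsFactors = FALSE)
  }
  acc <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  for (ctg in unique(acc$contig)) {
    sub <- acc[acc$contig == ctg, ]
    s <- rowsum(sub$val, sub$bin)
    idx <- as.integer(rownames(s)) + 1L
    keep <- idx <= length(bins[[ctg]])
    bins[[ctg]][idx[keep]] <- bins[[ctg]][idx[keep]] + s[keep]
  }
  structure(list(bins = bins, bin_size = bin_size, tag_length = tag_length,
                 total_weight = sum(placements$weight),
                 contig_lengths = contig_lengths),
            class = "coverage_track")
}

# Mass of a locus in tag units: prorated bin sum times bin_size/tag_length.
locus_mass <- function(track, contig, start, end) {
  if (!contig %in% names(track$bins))
    stop("locus contig '", contig, "' not covered by the track")
  L <- track$contig_lengths[[contig]]
  if (start < 0 || end > L) stop("locus [", start, ",", end,
                                 ") outside contig bounds (", L, " bp)")
  bs <- track$bin_size
  v <- track$bins[[contig]]
  fb <- start %/% bs
  lb <- (end - 1L) %/% bs
  b <- fb:lb
  ov <- pmin(end, (b + 1) * bs) - pmax(start, b * bs)
  sum(v[b + 1] * ov / bs) * bs / track$tag_length
}

# Values of bins whose midpoint falls inside [start, end).
.bin_values <- function(track, contig, start, end) {
  bs <- track$bin_size
  v <- track$bins[[contig]]
  b <- seq_along(v) - 1L
  mid <- b * bs + bs / 2
  v[mid >= start & mid < end]
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track: %d contig(s), bin %d bp, tag length %d bp\n",
              length(x$bins), x$bin_size, x$tag_length))
  cat(sprintf("  total weight %.1f (mass %.1f bin units)\n",
              x$total_weight, sum(vapply(x$bins, sum, numeric(1)))))
  invisible(x)
}
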