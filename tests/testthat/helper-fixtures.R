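# Shared fixtures and independent oracles. Everything here is built in code;
# oracles deliberately avoid the code paths they check.

# hand-built tag set (bypasses the simulator)
make_tag_set <- function(c_vals, match_list, tag_length = 36L,
                         contig_lengths = c(c1 = 100000L)) {
  stopifnot(length(c_vals) == length(match_list))
  matches <- do.call(rbind, lapply(seq_along(match_list), function(i) {
    m <- match_list[[i]]
    data.frame(tag_id = i, contig = m$contig %||% "c1", start = m$start,
               end = m$start + tag_length,
               strand = m$strand %||% rep("+", length(m$start)),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    tags = data.frame(tag_id = seq_along(c_vals), seq = NA_character_,
                      c = as.integer(c_vals),
                      m = lengths(lapply(match_list, `[[`, "start")),
                      stringsAsFactors = FALSE),
    matches = matches, sources = NULL, tag_length = as.integer(tag_length),
    track_kind = "test", depth = sum(c_vals),
    contig_lengths = contig_lengths), class = "tag_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coverage track built directly from bin values (bypasses build_coverage)
make_track <- function(bins, bin_size = 10L, tag_length = 36L,
                       total_weight = NULL) {
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 tag_length = as.integer(tag_length),
                 total_weight = total_weight %||%
                   sum(vapply(bins, sum, numeric(1))) * bin_size / tag_length,
                 contig_lengths = vapply(bins, function(v)
                   length(v) * as.integer(bin_size), integer(1))),
            class = "coverage_track")
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# element with exact A/B boxes planted at a given spacer
box_element <- function(spacer, len = 200L, at = 50L, seed = 42,
                        a_box = "TGGCTTAGTACG", b_box = "GTTCGAATC") {
  s <- strsplit(rand_dna(len, seed), "")[[1]]
  s[(at + 1):(at + nchar(a_box))] <- strsplit(a_box, "")[[1]]
  b_at <- at + nchar(a_box) + spacer
  stopifnot(b_at + nchar(b_box) <= len)
  s[(b_at + 1):(b_at + nchar(b_box))] <- strsplit(b_box, "")[[1]]
  paste(s, collapse = "")
}

# --- independent brute-force promoter-scan oracle -------------------------
# naive double loop with its own IUPAC table and its own reverse complement
.oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                      Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                      K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

.oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

.oracle_box_starts <- function(chars, box, max_mm) {
  w <- nchar(box)
  bx <- strsplit(box, "")[[1]]
  starts <- integer(0)
  if (length(chars) < w) return(starts)
  for (s in 0:(length(chars) - w)) {
    mm <- 0L
    for (j in seq_len(w)) {
      ch <- chars[s + j]
      if (ch == "N" || !(ch %in% .oracle_iupac[[bx[j]]])) mm <- mm + 1L
    }
    if (mm <= max_mm) starts <- c(starts, s)
  }
  starts
}

oracle_scan <- function(sequence, model) {
  L <- nchar(sequence)
  wa <- nchar(model$a_box); wb <- nchar(model$b_box)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else .oracle_revcomp(sequence)
    chars <- strsplit(s, "")[[1]]
    a <- .oracle_box_starts(chars, model$a_box, model$max_mismatches)
    b <- .oracle_box_starts(chars, model$b_box, model$max_mismatches)
    for (ai in a) for (bi in b) {
      sp <- bi - (ai + wa)
      if (sp < max(model$spacer_range[1], 0L) || sp > model$spacer_range[2])
        next
      if (strand == "+") {
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand, a_start = ai, a_end = ai + wa,
          b_start = bi, b_end = bi + wb, spacer = sp)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand, a_start = L - (ai + wa), a_end = L - ai,
          b_start = L - (bi + wb), b_end = L - bi, spacer = sp)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(strand = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), spacer = integer()))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$a_start, out$b_start), , drop = FALSE]
}

# --- least-squares topology oracle for 5 taxa -----------------------------
# edges on the tip-to-tip path, via BFS over the unrooted edge list
.tree_path_edges <- function(tree, from, to) {
  edges <- tree$edge
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  prev <- rep(NA_integer_, nodes); prev_edge <- rep(NA_integer_, nodes)
  queue <- from; seen <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (k in seq_len(NROW(adj[[v]]))) {
      u <- adj[[v]][k, 1]
      if (!(u %in% seen)) {
        seen <- c(seen, u); prev[u] <- v; prev_edge[u] <- adj[[v]][k, 2]
        queue <- c(queue, u)
      }
    }
  }
  path <- integer(0); v <- to
  while (v != from) { path <- c(path, prev_edge[v]); v <- prev[v] }
  path
}

# least-squares branch lengths + RSS of a topology against a distance matrix
ls_fit_topology <- function(tree, dm) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  d <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k, .tree_path_edges(tree, i, j)] <- 1
    d[k] <- dm[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(A, d)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# best topology among all unrooted 5-taxon trees by least squares
ls_best_topology <- function(dm) {
  taxa <- rownames(dm)
  all_tr <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  rss <- vapply(all_tr, function(tr) ls_fit_topology(tr, dm)$rss, numeric(1))
  all_tr[[which.min(rss)]]
}

# random unrooted binary tree with positive branch lengths -> additive matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 10)
  list(tree = tr, dm = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}
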