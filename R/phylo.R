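#' Read a multiple alignment
#'
#' @param path Aligned FASTA or Clustal file.
#' @param format `"fasta"`, `"clustal"`, or `"auto"` (sniffed from the first
#'   line).
#' @return A named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- Biostrings::readDNAMultipleAlignment(path, format = format)
  out <- as.character(Biostrings::DNAStringSet(aln))
  validate_alignment(out)
}

validate_alignment <- function(aln) {
  if (length(aln) < 2) stop("an alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must have equal length")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("aligned sequences must carry unique names")
  toupper(aln)
}

#' Percent-identity distances from a multiple alignment
#'
#' Pairwise identity is `100 * matches / compared columns`; the distance is
#' `100 - identity`, so distances live on the 0-100 percent scale. Under
#' `pairwise_deletion` only columns where both sequences have a residue are
#' compared; under `count_as_mismatch` columns where exactly one sequence is
#' gapped count as mismatches (columns gapped in both are never compared).
#'
#' @param aln Named character vector of aligned sequences (see
#'   [read_alignment()]).
#' @param gap_rule `"pairwise_deletion"` or `"count_as_mismatch"`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
percent_identity_distance <- function(aln,
                                      gap_rule = c("pairwise_deletion",
                                                   "count_as_mismatch")) {
  gap_rule <- match.arg(gap_rule)
  aln <- validate_alignment(aln)
  n <- length(aln)
  chars <- do.call(rbind, strsplit(aln, ""))
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gi <- chars[i, ] == "-"; gj <- chars[j, ] == "-"
      if (gap_rule == "pairwise_deletion") {
        comp <- !gi & !gj
        match <- comp & chars[i, ] == chars[j, ]
      } else {
        comp <- !(gi & gj)
        match <- comp & !gi & !gj & chars[i, ] == chars[j, ]
      }
      if (sum(comp) == 0)
        stop("no comparable columns between '", names(aln)[i], "' and '",
             names(aln)[j], "'")
      id <- 100 * sum(match) / sum(comp)
      d[i, j] <- d[j, i] <- 100 - id
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimizing
#' \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)} is joined,
#' with branch lengths from the usual split formula
#' \eqn{l_i = d(i,j)/2 + (R_i - R_j) / (2(n-2))}. Ties on Q are broken by
#' the lexicographically lowest taxon-index pair, so the output is fully
#' deterministic. Negative branch lengths are clamped to zero; the original
#' values are recorded in the `clamped` attribute of the result. The tree is
#' unrooted (the final join leaves a trifurcation).
#'
#' @param dm Symmetric non-negative distance matrix with dimnames
#'   (>= 3 taxa), e.g. from [percent_identity_distance()].
#' @return An [ape::read.tree()]-style `phylo` object; branch lengths are in
#'   the units of `dm` (percent, for percent-identity input).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")

  taxa <- rownames(dm)
  # each active node is represented by a Newick subtree string
  labels <- vapply(taxa, .quote_newick, character(1))
  clamped <- list()

  clamp <- function(len, what) {
    if (len < 0) {
      clamped[[length(clamped) + 1]] <<- data.frame(node = what,
                                                    original = len)
      0
    } else len
  }

  while (nrow(dm) > 3) {
    n <- nrow(dm)
    R <- rowSums(dm)
    # strict '<' scan in row-major upper-triangle order implements the
    # lowest-index tie break
    best <- c(1L, 2L); best_q <- Inf
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * dm[i, j] - R[i] - R[j]
        if (q < best_q - 1e-12) {
          best_q <- q; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- dm[i, j] - li
    li <- clamp(li, labels[i]); lj <- clamp(lj, labels[j])

    new_d <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    new_lab <- sprintf("(%s:%.17g,%s:%.17g)", labels[i], li, labels[j], lj)

    keep <- setdiff(seq_len(n), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    labels <- c(labels[keep], new_lab)
    rownames(dm) <- colnames(dm) <- labels
  }

  # resolve the final three nodes around a central trifurcation
  l1 <- clamp((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2, labels[1])
  l2 <- clamp((dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2, labels[2])
  l3 <- clamp((dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2, labels[3])
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 labels[1], l1, labels[2], l2, labels[3], l3)
  tree <- ape::read.tree(text = nwk)
  if (length(clamped) > 0)
    attr(tree, "clamped") <- do.call(rbind, clamped)
  tree
}

.quote_newick <- function(x) {
  if (grepl("[ (),:;'\\[\\]]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Write / read Newick trees and distance matrices
#'
#' Thin wrappers with the package's conventions: Newick through ape (the
#' write-read-write cycle is idempotent) and distances as TSV with taxa as
#' the first column.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname write_newick
#' @param dm Distance matrix.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(taxon = rownames(dm), as.data.frame(dm, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
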