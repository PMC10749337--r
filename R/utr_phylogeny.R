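#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) with simple
#' match/mismatch scoring and a linear gap penalty. UTR haplotypes are
#' near-identical, so pairwise global alignments (rather than a progressive
#' MSA) feed the distance matrix.
#'
#' @param seq_a,seq_b nucleotide strings (non-empty).
#' @param match,mismatch,gap alignment scores (gap is the per-base penalty,
#'   negative).
#' @return list with gapped strings `a` and `b` and the alignment `score`.
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("align_pair requires non-empty sequences")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(normalize_dna(seq_a)),
    Biostrings::DNAString(normalize_dna(seq_b)),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(gap))
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Uncorrected p-distance of an aligned pair
#'
#' Mismatches divided by compared columns; columns containing a gap are
#' excluded from the denominator ("without distance corrections").
#'
#' @param alignment a list with gapped strings `a` and `b` (from
#'   [align_pair()]).
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1]]
  b <- strsplit(alignment$b, "")[[1]]
  if (length(a) != length(b)) abort("aligned strings differ in length")
  cmp <- a != "-" & b != "-"
  if (!any(cmp)) abort("no comparable columns (all-gap overlap)")
  sum(a[cmp] != b[cmp]) / sum(cmp)
}

#' Pairwise p-distance matrix for a set of sequences
#'
#' @param seqs named character vector of sequences.
#' @param ... scoring parameters passed to [align_pair()].
#' @return symmetric matrix with zero diagonal, labelled by `names(seqs)`.
#' @export
distance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) abort("sequences must be named")
  dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(dm)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- p_distance(align_pair(seqs[[i]], seqs[[j]], ...))
      dm[i, j] <- d
      dm[j, i] <- d
    }
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj()`), which recovers the
#' generating topology and branch lengths exactly on additive matrices.
#' Negative estimated branch lengths are clamped to zero (with a message
#' reporting how many).
#'
#' @param dm symmetric numeric matrix (or `dist`) with at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    abort("distance matrix must be square")
  }
  if (nrow(dm) < 3) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) abort("distance matrix is not symmetric")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("clamped %d negative branch length(s) to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Does a tree contain a given bipartition?
#'
#' Checks whether some internal edge of the (unrooted) tree separates
#' `group` from the remaining tips.
#'
#' @param tree a `phylo`.
#' @param group character vector of tip labels.
#' @return logical.
#' @export
has_split <- function(tree, group) {
  tips <- tree$tip.label
  g <- sort(intersect(group, tips))
  if (length(g) == 0 || length(g) == length(tips)) return(TRUE)
  n_tip <- length(tips)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tips[node])
    unlist(lapply(kids[[as.character(node)]], below), use.names = FALSE)
  }
  for (node in unique(tree$edge[, 2])) {
    if (node <= n_tip) next
    side <- sort(below(node))
    if (identical(side, g) ||
        identical(side, sort(setdiff(tips, g)))) {
      return(TRUE)
    }
  }
  # edges at the root of the stored (arbitrary) rooting
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  for (node in kids[[as.character(root)]]) {
    side <- sort(below(node))
    if (identical(side, g) || identical(side, sort(setdiff(tips, g)))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Build the UTR-type tree
#'
#' Aligns the supplied per-type sequences pairwise, computes uncorrected
#' p-distances and returns the neighbor-joining tree. The sequences should
#' be the full per-type transcript (coding) sequences: UTR-type haplotypes
#' share most of their UTR SNPs within lineages, and the lineage signal
#' lives in the coding region (see the methods vignette).
#'
#' @param seqs named character vector: UTR-type name -> sequence.
#' @param ... scoring parameters for [align_pair()].
#' @return list with `tree` (a `phylo`) and `distances` (the matrix).
#' @export
utr_tree <- function(seqs, ...) {
  dm <- distance_matrix(seqs, ...)
  list(tree = neighbor_joining(dm), distances = dm)
}
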