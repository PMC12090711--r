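# Sequence distances and embeddings. Each OG is summarised by the
# symmetric matrix of pairwise amino-acid p-distances (pairwise gap
# deletion); row i of that matrix is the embedding of strain i used for all
# centroid arithmetic downstream, and classical MDS provides the
# low-dimensional view used to validate candidate genes.

#' Amino-acid p-distance between two aligned sequences
#'
#' Fraction of differing residues among compared columns; a column is
#' compared only when neither sequence has a gap (\code{'-'}) there
#' (pairwise deletion). If no columns can be compared the distance is 1,
#' with a warning.
#'
#' @param a,b aligned sequences of equal length (character scalars).
#' @return distance in \[0, 1\].
#' @examples
#' pDistance("AAAA", "AATA")  # 0.25
#' pDistance("A-CG", "AACG")  # 0 (3 compared columns, all equal)
#' @export
pDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stopf("unequal sequence lengths (%d vs %d): align the sequences first (see alignPair)",
          nchar(a), nchar(b))
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  cmp <- A != "-" & B != "-"
  if (!any(cmp)) {
    warnf("no comparable (gap-free) columns; p-distance set to 1")
    return(1)
  }
  mean(A[cmp] != B[cmp])
}

# internal: all pairwise p-distances of N equal-length sequences, given as
# an N x L character matrix. Match counts come from one tcrossprod per
# residue over non-gap indicator matrices, so the cost is ~21 BLAS calls.
.pDistMatrix <- function(S) {
  n <- nrow(S)
  nongap <- S != "-"
  compared <- tcrossprod(nongap * 1)
  matches <- matrix(0, n, n)
  for (r in setdiff(unique(as.vector(S)), "-")) {
    I <- (S == r & nongap) * 1
    matches <- matches + tcrossprod(I)
  }
  d <- matrix(0, n, n)
  pos <- compared > 0
  d[pos] <- (compared[pos] - matches[pos]) / compared[pos]
  if (any(!pos)) {
    warnf("sequence pair(s) with no comparable columns; p-distance set to 1")
    d[!pos] <- 1
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(S), rownames(S))
  d
}

#' Pairwise p-distance matrix for an OG family
#'
#' Computes all pairwise p-distances among an OG's members. Aligned
#' families (equal-length members) are compared column-wise with pairwise
#' gap deletion; unaligned families are pairwise-aligned on the fly with
#' [alignPair()]. Strains are ordered lexicographically, so the result is
#' invariant to member input order.
#'
#' @param fam an [OgFamily-class] with at least two members, or a named
#'   character vector of sequences.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal and
#'   strain dimnames.
#' @examples
#' buildDistanceMatrix(OgFamily("og", c(s1 = "AAAA", s2 = "AAAT")))
#' @export
buildDistanceMatrix <- function(fam) {
  seqs <- if (is(fam, "OgFamily")) {
    setNames(as.character(members(fam)), names(members(fam)))
  } else fam
  if (length(seqs) < 2L) stopf("need >= 2 members to build a distance matrix")
  seqs <- seqs[order(names(seqs))]
  aligned <- length(unique(nchar(seqs))) == 1L
  n <- length(seqs)
  if (aligned) {
    S <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
    rownames(S) <- names(seqs)
    return(.pDistMatrix(S))
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- alignPair(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- pDistance(al$a, al$b)
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, eigendecomposes, and returns
#' coordinates on the top \code{dims} axes; negative eigenvalues are
#' truncated to zero. Each axis is deterministically oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param d symmetric distance matrix (zero diagonal).
#' @param dims number of dimensions, \code{dims < nrow(d)}.
#' @return numeric matrix (N x dims) with the rownames of \code{d}.
#' @examples
#' x <- c(0, 3, 5)
#' d <- as.matrix(dist(x))
#' classicalMds(d, 1)
#' @export
classicalMds <- function(d, dims) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (dims >= n) stopf("dims must be < number of points (%d)", n)
  if (dims < 1L) stopf("dims must be >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d * d) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(dims)], 0)
  X <- e$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(lam), nrow = dims)
  for (j in seq_len(dims)) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(d)
  colnames(X) <- paste0("dim", seq_len(dims))
  X
}
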