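# Pairwise global alignment (Needleman-Wunsch, linear gap penalty) used as
# a fallback when an OG's member sequences are not pre-aligned. Scoring:
# match +1, mismatch -1, gap -2. The traceback is deterministic: on score
# ties prefer the diagonal move, then up (gap in b), then left (gap in a).

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap penalty of -2, with a deterministic traceback (ties resolved
#' diagonal, then up, then left). Intended for aligning the two members of
#' an unaligned OG pair before computing a p-distance; supply a proper MSA
#' (e.g. from mafft) for large families.
#'
#' @param a,b non-empty sequences (character scalars).
#' @return list with elements \code{a}, \code{b} (gapped aligned strings of
#'   equal length) and \code{score} (the optimal alignment score).
#' @examples
#' alignPair("ACGT", "AGT")
#' @export
alignPair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stopf("alignPair needs non-empty sequences")
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  gap <- -2
  M <- matrix(0, n + 1L, m + 1L)
  M[1L, ] <- gap * (0:m)
  M[, 1L] <- gap * (0:n)
  # row-wise update; the within-row 'left' chain with a linear gap is a
  # running maximum of candidate + 2*k, so each row is vectorised
  for (i in seq_len(n)) {
    s <- ifelse(B == A[i], 1, -1)
    cand <- pmax(M[i, 1:m] + s, M[i, 2:(m + 1L)] + gap)
    cand <- c(M[i + 1L, 1L], cand)             # k = 0 term seeds the chain
    M[i + 1L, ] <- cummax(cand + gap * -(0:m)) + gap * (0:m)
  }
  # traceback with the stated preference order
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        M[i + 1L, j + 1L] == M[i, j] + (if (A[i] == B[j]) 1 else -1)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && M[i + 1L, j + 1L] == M[i, j + 1L] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = M[n + 1L, m + 1L])
}
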