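# Shared fixtures and independent oracles. Oracles deliberately use naive
# formulations (explicit loops, exhaustive enumeration) so they share no
# code path with the implementation they check.

# the worked 4-strain OG used throughout: two divergent allele pairs
workedFamily <- function() {
  OgFamily("worked", c(s1 = "AAAA", s2 = "AAAT", s3 = "GGGG", s4 = "GGGT"))
}

makeGroups <- function(active, silent, species = "sp", cytokine = "IL10",
                       med = 1) {
  new("PhenotypeGroups", species = species, cytokine = cytokine,
      median = med, active = active, silent = silent, degenerate = FALSE)
}

workedGroups <- function() makeGroups(c("s1", "s2"), c("s3", "s4"))

# textbook Calinski-Harabasz by explicit loops over points and clusters
bruteCH <- function(X, labels) {
  ks <- unique(labels)
  grand <- colMeans(X)
  b <- 0; w <- 0
  for (k in ks) {
    rows <- X[labels == k, , drop = FALSE]
    cen <- colMeans(rows)
    b <- b + nrow(rows) * sum((cen - grand)^2)
    for (i in seq_len(nrow(rows))) w <- w + sum((rows[i, ] - cen)^2)
  }
  if (b == 0) return(0)
  if (w == 0) return(Inf)
  (b / (length(ks) - 1)) / (w / (nrow(X) - length(ks)))
}

# exhaustive global-alignment score by recursion (small sequences only)
bruteAlignScore <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) + (if (A[i] == B[j]) 1 else -1))
    if (i > 0) best <- max(best, rec(i - 1, j) - 2)
    if (j > 0) best <- max(best, rec(i, j - 1) - 2)
    best
  }
  rec(length(A), length(B))
}

# exact two-sided rank-sum p by enumerating all group assignments
enumRankSumP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2      # Mann-Whitney U of x
  assign <- combn(n + m, n)
  u <- apply(assign, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  lo <- mean(u <= wObs); hi <- mean(u >= wObs)
  min(1, 2 * min(lo, hi))
}

# random embedding with a random bipartition (for SS-decomposition checks)
randomEmbedding <- function(n = 8, d = 5) {
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("t%02d", seq_len(n)), NULL))
  nA <- sample(1:(n - 1), 1)
  list(X = X, active = rownames(X)[seq_len(nA)],
       silent = rownames(X)[(nA + 1):n])
}

# random distance matrix from random short sequences (valid p-distances)
randomSeqDistance <- function(n = 6, L = 20) {
  aa <- c("A", "C", "D", "E", "G")
  seqs <- setNames(vapply(seq_len(n), function(i)
    paste(sample(aa, L, TRUE), collapse = ""), character(1)),
    sprintf("t%02d", seq_len(n)))
  buildDistanceMatrix(seqs)
}
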