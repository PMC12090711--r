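# The PG (potential-gene) index. Each OG's strains are embedded as the rows
# of the OG's overall p-distance matrix, so active, silent and overall
# centroids live in the same N-dimensional space and the variance
# decomposition BGSS + WGSS = total SS holds exactly. The CH index between
# the two phenotype groups is then scaled by a sequence-distribution factor
# that down-weights OGs whose members are largely identical.

#' Centroid of a strain group in an embedding
#'
#' @param emb numeric matrix with strain rownames (typically the rows of an
#'   OG's overall distance matrix).
#' @param strains non-empty subset of the rownames.
#' @return numeric vector, the arithmetic mean of the member rows.
#' @export
groupCentroid <- function(emb, strains) {
  if (!length(strains)) stopf("empty strain set has no centroid")
  missing <- setdiff(strains, rownames(emb))
  if (length(missing))
    stopf("strain(s) not in embedding: %s", paste(missing, collapse = ", "))
  colMeans(emb[strains, , drop = FALSE])
}

# internal: resolve active/silent arguments against an embedding
.resolveGroups <- function(emb, active, silent) {
  if (is(active, "PhenotypeGroups")) {
    silent <- intersect(silentStrains(active), rownames(emb))
    active <- intersect(activeStrains(active), rownames(emb))
  } else if (is.null(silent)) {
    silent <- setdiff(rownames(emb), active)
  }
  if (!length(active) || !length(silent))
    stopf("both groups must be non-empty within the OG (filter OGs first)")
  list(active = active, silent = silent)
}

#' Between-group sum of squares
#'
#' \eqn{BGSS = \sum_i n_i \|C_i - C\|^2} over the active and silent groups,
#' where \eqn{C_i} is the group centroid and \eqn{C} the overall centroid
#' of all embedded strains.
#'
#' @param emb numeric matrix with strain rownames; its rows are exactly the
#'   OG's member strains.
#' @param active either a character vector of active strain ids or a
#'   [PhenotypeGroups-class] (intersected with the embedding's strains).
#' @param silent character vector of silent strain ids; defaults to the
#'   complement of \code{active} within the embedding.
#' @return non-negative scalar.
#' @examples
#' emb <- rbind(a1 = c(0, 0), a2 = c(0, 2), b1 = c(4, 0), b2 = c(4, 2))
#' bgss(emb, c("a1", "a2"))  # 16
#' @export
bgss <- function(emb, active, silent = NULL) {
  g <- .resolveGroups(emb, active, silent)
  C <- colMeans(emb)
  ca <- groupCentroid(emb, g$active)
  cs <- groupCentroid(emb, g$silent)
  length(g$active) * sum((ca - C)^2) + length(g$silent) * sum((cs - C)^2)
}

#' Within-group sum of squares
#'
#' \eqn{WGSS = \sum_i \sum_{X \in C_i} \|X - C_i\|^2}: squared distances of
#' each strain to its own group centroid, summed over both groups.
#'
#' @inheritParams bgss
#' @return non-negative scalar.
#' @export
wgss <- function(emb, active, silent = NULL) {
  g <- .resolveGroups(emb, active, silent)
  tot <- 0
  for (grp in g) {
    rows <- emb[grp, , drop = FALSE]
    tot <- tot + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  tot
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-group sum of squares, each normalised by its
#' degrees of freedom: \eqn{(BGSS/(K-1)) / (WGSS/(n-K))}. With all points
#' coincident across groups (\code{bgss == 0}) the index is 0; with perfect
#' within-group homogeneity but separated groups (\code{wgss == 0},
#' \code{bgss > 0}) it is \code{Inf}, which ranks above every finite score.
#'
#' @param bgss,wgss sums of squares.
#' @param n number of strains; must exceed \code{K}.
#' @param K number of clusters (2: active and silent).
#' @return non-negative scalar, possibly \code{Inf}.
#' @examples
#' chIndex(16, 4, 4)  # 8
#' @export
chIndex <- function(bgss, wgss, n, K = 2) {
  if (n <= K) stopf("CH index needs n > K (n = %d, K = %d)", n, K)
  if (bgss == 0) return(0)
  if (wgss == 0) return(Inf)
  (bgss / (K - 1)) / (wgss / (n - K))
}

#' Sequence-distribution factor
#'
#' \eqn{N_{overall} / \mathrm{zero\_value\_count}_{overall}}, where zeros
#' are counted over the full N x N overall distance matrix including the
#' diagonal. The factor is exactly 1 when all off-diagonal distances are
#' positive and shrinks towards \eqn{1/N} as member sequences collapse to
#' identical copies, down-weighting low-diversity OGs.
#'
#' @param d the OG's overall distance matrix (N >= 2).
#' @return scalar in \eqn{(0, 1]}.
#' @examples
#' d <- matrix(c(0, .5, .5, 0), 2, 2)
#' seqDistFactor(d)  # 1
#' @export
seqDistFactor <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stopf("seqDistFactor needs N >= 2")
  n / sum(d == 0)
}

#' PG index from a distance matrix
#'
#' Core computation shared by [pgScore()]: embeds the strains as the rows
#' of the overall distance matrix, computes BGSS/WGSS/CH between the two
#' phenotype groups (K = 2), the sequence-distribution factor, and their
#' product, the PG index. An infinite CH propagates to an infinite PG.
#'
#' @param d symmetric distance matrix with strain dimnames.
#' @inheritParams bgss
#' @return list with \code{n_overall, n_active, n_silent, zero_count,
#'   bgss, wgss, ch_index, seq_dist_factor, pg_index}.
#' @export
pgIndexFromDistance <- function(d, active, silent = NULL) {
  d <- as.matrix(d)
  g <- .resolveGroups(d, active, silent)
  emb <- d                      # row-embedding: row i represents strain i
  b <- bgss(emb, g$active, g$silent)
  w <- wgss(emb, g$active, g$silent)
  n <- nrow(d)
  ch <- chIndex(b, w, n, 2)
  sdf <- seqDistFactor(d)
  list(n_overall = n, n_active = length(g$active),
       n_silent = length(g$silent), zero_count = sum(d == 0),
       bgss = b, wgss = w, ch_index = ch, seq_dist_factor = sdf,
       pg_index = ch * sdf)
}

#' Score one OG against a phenotype split
#'
#' Assembles the full per-OG scoring pipeline: overall p-distance matrix
#' ([buildDistanceMatrix()]), row-embedding, BGSS, WGSS, CH index with the
#' K = 2 phenotype labels, sequence-distribution factor and PG index.
#'
#' @param fam an [OgFamily-class].
#' @param groups a [PhenotypeGroups-class]; only strains present in the OG
#'   contribute, and both groups must retain at least one member.
#' @return one-row data.frame with columns \code{og_id, n_overall,
#'   n_active, n_silent, zero_count, bgss, wgss, ch_index,
#'   seq_dist_factor, pg_index}.
#' @examples
#' fam <- OgFamily("toy", c(s1 = "AAAA", s2 = "AAAT",
#'                          s3 = "GGGG", s4 = "GGGT"))
#' g <- new("PhenotypeGroups", species = "sp", cytokine = "IL10",
#'          median = 1, active = c("s1", "s2"), silent = c("s3", "s4"),
#'          degenerate = FALSE)
#' pgScore(fam, g)
#' @export
pgScore <- function(fam, groups) {
  d <- buildDistanceMatrix(fam)
  res <- pgIndexFromDistance(d, groups)
  data.frame(og_id = ogId(fam), n_overall = res$n_overall,
             n_active = res$n_active, n_silent = res$n_silent,
             zero_count = res$zero_count, bgss = res$bgss, wgss = res$wgss,
             ch_index = res$ch_index, seq_dist_factor = res$seq_dist_factor,
             pg_index = res$pg_index, stringsAsFactors = FALSE)
}
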