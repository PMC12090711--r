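# K = 2 k-means on the row-embedding, used to re-cluster top candidates by
# sequence similarity alone and recalculate the CH index with the data-driven
# labels. Seeding is k-means++-style from a seeded RNG; Lloyd iterations run
# to exact assignment convergence; an emptied cluster is repaired by moving
# in the point farthest from its current centroid.

# internal: one seeded k-means(K=2) run on numeric matrix X
.kmeansTwoOnce <- function(X, maxIter = 300L) {
  n <- nrow(X)
  c1 <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, c1)^2)
  if (all(d2 == 0)) {                       # all points coincide
    return(list(labels = rep(1L, n), wss = 0, degenerate = TRUE))
  }
  c2 <- X[sample.int(n, 1L, prob = d2), ]
  centers <- rbind(c1, c2)
  labels <- integer(n)
  for (it in seq_len(maxIter)) {
    da <- rowSums(sweep(X, 2, centers[1L, ])^2)
    db <- rowSums(sweep(X, 2, centers[2L, ])^2)
    new_labels <- ifelse(da <= db, 1L, 2L)   # tie -> cluster 1
    for (k in 1:2) {
      if (!any(new_labels == k)) {           # empty-cluster repair
        within <- ifelse(new_labels == 1L, da, db)
        far <- which.max(within)
        new_labels[far] <- k
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in 1:2)
      centers[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  wss <- 0
  for (k in 1:2) {
    rows <- X[labels == k, , drop = FALSE]
    wss <- wss + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  list(labels = labels, wss = wss, degenerate = FALSE)
}

#' K = 2 k-means with CH recalculation for one OG
#'
#' Re-clusters an OG's strains by sequence similarity alone: k-means
#' (K = 2, k-means++-style seeding, Lloyd iterations, several restarts
#' keeping the lowest within-cluster sum of squares) on the rows of the
#' OG's overall p-distance matrix, followed by recalculation of the CH
#' index with the k-means labels. No sequence-distribution factor is
#' applied to the recalculated CH. Families whose members are all identical
#' are degenerate and get a recalculated CH of 0 (flagged unplottable);
#' families with fewer than 3 members have no defined CH and are flagged.
#'
#' @param fam an [OgFamily-class], or a precomputed distance matrix.
#' @param restarts number of seeded restarts (default 10).
#' @param seed integer RNG seed making the run reproducible.
#' @return list with \code{labels} (integer 1/2 named by strain, or NULL
#'   when flagged), \code{ch} (recalculated CH; 0 for degenerate families,
#'   \code{NA} when undefined), and \code{flagged} (TRUE when the OG cannot
#'   be ranked or plotted).
#' @examples
#' fam <- OgFamily("toy", c(s1 = "AAAA", s2 = "AAAT",
#'                          s3 = "GGGG", s4 = "GGGT"))
#' kmeans2RecalcCh(fam, seed = 1)
#' @export
kmeans2RecalcCh <- function(fam, restarts = 10L, seed = 1L) {
  d <- if (is(fam, "OgFamily")) buildDistanceMatrix(fam) else as.matrix(fam)
  n <- nrow(d)
  if (n < 3L)
    return(list(labels = NULL, ch = NA_real_, flagged = TRUE))
  X <- d                        # row-embedding, as for the PG index
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- .kmeansTwoOnce(X)
    if (run$degenerate) { best <- run; break }
    if (is.null(best) || run$wss < best$wss) best <- run
  }
  if (best$degenerate || length(unique(best$labels)) < 2L)
    return(list(labels = setNames(rep(1L, n), rownames(d)), ch = 0,
                flagged = TRUE))
  labels <- setNames(best$labels, rownames(d))
  grp1 <- names(labels)[labels == 1L]
  grp2 <- names(labels)[labels == 2L]
  b <- bgss(X, grp1, grp2)
  w <- wgss(X, grp1, grp2)
  ch <- chIndex(b, w, n, 2)
  list(labels = labels, ch = ch, flagged = ch == 0)
}
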