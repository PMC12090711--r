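# The full screen: OG filtering, scoring, top-2% selection, k-means
# re-clustering with recalculated-CH ranking, cross-cytokine overlap, rank
# tests, and the presence/absence marker screen.

#' Screen configuration
#'
#' Bundles the tunable screen parameters with their standard values: the
#' top PG-index fraction (2\%), K = 2 clusters, top-3 overlap across
#' cytokine comparisons, k-means restarts, a minimum of 2 strains per
#' phenotype group for an OG to be scorable, and the marker-screen
#' thresholds (present in >= 80\% of active and <= 50\% of silent strains).
#'
#' @param topFraction fraction of scored OGs selected by PG index.
#' @param K number of clusters (fixed to 2: active and silent).
#' @param topKOverlap list depth for the cross-cytokine overlap.
#' @param kmeansRestarts restarts for [kmeans2RecalcCh()].
#' @param seed RNG seed for the k-means re-clustering.
#' @param minPerGroup minimum member strains per phenotype group.
#' @param markerActiveThreshold,markerSilentThreshold marker-screen bounds.
#' @param filterMode \code{"both"} (default: an OG needs
#'   \code{minPerGroup} strains in each group) or \code{"any"} (either
#'   group suffices; the literal reading of "active or silent").
#' @return named list of class \code{ScreenConfig}.
#' @export
screenConfig <- function(topFraction = 0.02, K = 2L, topKOverlap = 3L,
                         kmeansRestarts = 10L, seed = 1L, minPerGroup = 2L,
                         markerActiveThreshold = 0.80,
                         markerSilentThreshold = 0.50,
                         filterMode = c("both", "any")) {
  stopifnot(topFraction > 0, topFraction <= 1, K == 2L,
            markerActiveThreshold >= 0, markerActiveThreshold <= 1,
            markerSilentThreshold >= 0, markerSilentThreshold <= 1)
  structure(list(topFraction = topFraction, K = 2L,
                 topKOverlap = as.integer(topKOverlap),
                 kmeansRestarts = as.integer(kmeansRestarts),
                 seed = as.integer(seed), minPerGroup = as.integer(minPerGroup),
                 markerActiveThreshold = markerActiveThreshold,
                 markerSilentThreshold = markerSilentThreshold,
                 filterMode = match.arg(filterMode)),
            class = "ScreenConfig")
}

#' Filter OGs eligible for scoring
#'
#' Excludes OGs represented in a single strain or absent, retaining OGs
#' conserved across multiple strains of the phenotype groups: by default an
#' OG must be present in at least \code{minPerGroup} strains of the active
#' group \emph{and} of the silent group (both finite centroids must exist);
#' \code{filterMode = "any"} requires only one of the two.
#'
#' @param presence a [PresenceMatrix-class].
#' @param groups a non-degenerate [PhenotypeGroups-class].
#' @param config a [screenConfig()].
#' @return character vector of retained OG identifiers (possibly empty,
#'   with a warning).
#' @export
filterOgs <- function(presence, groups, config = screenConfig()) {
  if (isDegenerate(groups))
    stopf("refusing degenerate phenotype groups (one side empty)")
  m <- isPresent(presence)
  act <- intersect(activeStrains(groups), colnames(m))
  sil <- intersect(silentStrains(groups), colnames(m))
  nA <- rowSums(m[, act, drop = FALSE])
  nS <- rowSums(m[, sil, drop = FALSE])
  keep <- if (config$filterMode == "both")
    nA >= config$minPerGroup & nS >= config$minPerGroup
  else
    nA >= config$minPerGroup | nS >= config$minPerGroup
  ids <- rownames(m)[keep]
  if (!length(ids)) warnf("no OGs pass the filter")
  ids
}

#' Score all filtered OGs
#'
#' Runs [pgScore()] on every requested OG family; output rows are ordered
#' by OG identifier, so the result is deterministic given the inputs.
#'
#' @param families named list of [OgFamily-class] objects.
#' @param groups a [PhenotypeGroups-class].
#' @param ids OG identifiers to score (default: all families). Families
#'   missing from \code{families} are skipped with a warning.
#' @return data.frame, one row per scored OG.
#' @export
scoreAll <- function(families, groups, ids = names(families)) {
  ids <- sort(ids)
  missing <- setdiff(ids, names(families))
  if (length(missing))
    warnf("%d OG(s) without sequences skipped", length(missing))
  ids <- intersect(ids, names(families))
  if (!length(ids)) stopf("no OGs to score")
  do.call(rbind, lapply(ids, function(og) pgScore(families[[og]], groups)))
}

#' Select the top PG-index fraction
#'
#' Keeps the best \code{max(1, ceiling(topFraction * M))} OGs by PG index
#' descending; ties are broken by CH index descending, then \code{n_overall}
#' descending, then OG identifier ascending.
#'
#' @param scores data.frame from [scoreAll()].
#' @param topFraction fraction in (0, 1].
#' @return character vector of selected OG identifiers, in rank order.
#' @export
selectTopFraction <- function(scores, topFraction = 0.02) {
  if (!nrow(scores)) stopf("no scores to select from")
  k <- max(1L, ceiling(topFraction * nrow(scores)))
  ord <- order(-scores$pg_index, -scores$ch_index, -scores$n_overall,
               scores$og_id)
  scores$og_id[ord][seq_len(min(k, nrow(scores)))]
}

#' Overlap of the top-k recalculated-CH candidates of two comparisons
#'
#' Intersection of the two comparisons' top-\code{k} OG lists ranked by
#' recalculated CH index (e.g. the IL-10 and IL-12 screens of one species).
#'
#' @param resultA,resultB [ScreenResult-class] objects, or character
#'   vectors already ranked by recalculated CH.
#' @param topK list depth (default 3).
#' @return character vector of shared OG identifiers (order follows
#'   \code{resultA}).
#' @export
overlapTopK <- function(resultA, resultB, topK = 3L) {
  rankedIds <- function(r) {
    if (is(r, "ScreenResult")) {
      s <- scoreTable(r)
      s <- s[!is.na(s$kmeans_rank), , drop = FALSE]
      s$og_id[order(s$kmeans_rank)]
    } else as.character(r)
  }
  a <- head(rankedIds(resultA), topK)
  b <- head(rankedIds(resultB), topK)
  a[a %in% b]
}

#' Kruskal-Wallis rank test over labelled score groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value
#' (df = groups - 1), as used to compare PG-index distributions. With all
#' values identical the statistic is 0 and p is 1.
#'
#' @param scoreGroups named list of numeric vectors (e.g. the PG indices of
#'   several comparisons).
#' @return list with \code{statistic} (H), \code{p.value} and \code{df}.
#' @examples
#' kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic  # 3.857
#' @export
kruskalWallis <- function(scoreGroups) {
  if (length(scoreGroups) < 2L) stopf("need >= 2 groups")
  if (any(!lengths(scoreGroups))) stopf("all groups must be non-empty")
  vals <- unlist(scoreGroups, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    return(list(statistic = 0, p.value = 1, df = length(scoreGroups) - 1L))
  kt <- kruskal.test(scoreGroups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for every pair of groups (exact when sample
#' sizes are small and ties are absent, otherwise the normal approximation
#' with tie and continuity corrections); each p-value is multiplied by the
#' number of pairs and capped at 1.
#'
#' @inheritParams kruskalWallis
#' @return symmetric matrix of Bonferroni-adjusted p-values (NA diagonal).
#' @export
pairwiseWilcoxonBonferroni <- function(scoreGroups) {
  if (length(scoreGroups) < 2L) stopf("need >= 2 groups")
  if (any(!lengths(scoreGroups))) stopf("all groups must be non-empty")
  g <- length(scoreGroups)
  npairs <- g * (g - 1L) / 2L
  p <- matrix(NA_real_, g, g,
              dimnames = list(names(scoreGroups), names(scoreGroups)))
  for (idx in seq_len(npairs)) {
    ij <- combn(g, 2)[, idx]
    x <- scoreGroups[[ij[1]]]; y <- scoreGroups[[ij[2]]]
    raw <- if (length(unique(c(x, y))) == 1L) 1
    else suppressWarnings(wilcox.test(x, y)$p.value)
    p[ij[1], ij[2]] <- p[ij[2], ij[1]] <- min(1, raw * npairs)
  }
  p
}

#' Presence/absence marker screen
#'
#' Flags an OG as a candidate probiotic marker when it is present in at
#' least 80\% of the active strains and at most 50\% of the silent strains
#' (both bounds inclusive; thresholds configurable).
#'
#' @inheritParams filterOgs
#' @return data.frame with columns \code{og_id, active_fraction,
#'   silent_fraction, marker}.
#' @export
markerScreen <- function(presence, groups, config = screenConfig()) {
  if (isDegenerate(groups))
    stopf("refusing degenerate phenotype groups (one side empty)")
  m <- isPresent(presence)
  act <- intersect(activeStrains(groups), colnames(m))
  sil <- intersect(silentStrains(groups), colnames(m))
  fa <- rowSums(m[, act, drop = FALSE]) / length(act)
  fs <- rowSums(m[, sil, drop = FALSE]) / length(sil)
  data.frame(og_id = rownames(m), active_fraction = fa, silent_fraction = fs,
             marker = fa >= config$markerActiveThreshold &
                      fs <= config$markerSilentThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full screen for one comparison
#'
#' Orchestrates one (species, cytokine) comparison end to end: OG
#' filtering, PG-index scoring, top-fraction selection, K = 2 k-means
#' re-clustering of every selected candidate with CH recalculation, and
#' recalculated-CH ranking (candidates with a recalculated CH of 0 are
#' flagged unplottable; they keep a rank but sort last).
#'
#' @param presence a [PresenceMatrix-class].
#' @param families named list of [OgFamily-class] objects.
#' @param groups a non-degenerate [PhenotypeGroups-class].
#' @param config a [screenConfig()]; its \code{seed} drives the k-means
#'   restarts, so the screen is fully deterministic given the inputs.
#' @return A [ScreenResult-class].
#' @export
runScreen <- function(presence, families, groups, config = screenConfig()) {
  ids <- filterOgs(presence, groups, config)
  scores <- scoreAll(families, groups, ids)
  scores$pg_rank <- rank_by_pg(scores)
  top <- selectTopFraction(scores, config$topFraction)
  scores$in_top_fraction <- scores$og_id %in% top
  scores$kmeans_ch <- NA_real_
  labels <- list()
  for (og in top) {
    km <- kmeans2RecalcCh(families[[og]], restarts = config$kmeansRestarts,
                          seed = deriveSeed(config$seed, match(og, sort(top))))
    scores$kmeans_ch[scores$og_id == og] <- km$ch
    if (!is.null(km$labels)) labels[[og]] <- km$labels
  }
  scores$kmeans_rank <- NA_integer_
  ranked <- which(scores$in_top_fraction & !is.na(scores$kmeans_ch))
  if (length(ranked)) {
    ord <- ranked[order(-scores$kmeans_ch[ranked], scores$og_id[ranked])]
    scores$kmeans_rank[ord] <- seq_along(ord)
  }
  new("ScreenResult", species = groups@species, cytokine = groups@cytokine,
      scores = scores, top = top, kmeansLabels = labels,
      config = unclass(config))
}

# internal: dense rank by PG index descending, ties by og_id ascending
rank_by_pg <- function(scores) {
  ord <- order(-scores$pg_index, scores$og_id)
  r <- integer(nrow(scores))
  r[ord] <- seq_len(nrow(scores))
  r
}
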