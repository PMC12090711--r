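# OG filtering, top-fraction selection, k-means re-clustering, overlap,
# rank tests and the marker screen.

test_that("OG filter requires multi-strain conservation in both groups", {
  m <- rbind(single  = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
             onesided = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
             balanced = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  colnames(m) <- sprintf("s%d", 1:6)
  pm <- PresenceMatrix(m)
  g <- makeGroups(c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_identical(filterOgs(pm, g), "balanced")
  expect_setequal(filterOgs(pm, g, screenConfig(filterMode = "any")),
                  c("onesided", "balanced"))
  gd <- new("PhenotypeGroups", species = "sp", cytokine = "IL10", median = 1,
            active = sprintf("s%d", 1:6), silent = character(0),
            degenerate = TRUE)
  expect_error(filterOgs(pm, gd), "degenerate")
})

test_that("scoreAll is deterministic and one row per OG", {
  fams <- list(
    og_b = OgFamily("og_b", c(s1 = "AAAA", s2 = "AATT", s3 = "GGGG", s4 = "GGTT")),
    og_a = OgFamily("og_a", c(s1 = "AAAA", s2 = "AAAT", s3 = "GGGG", s4 = "GGGT")))
  g <- workedGroups()
  s1 <- scoreAll(fams, g)
  s2 <- scoreAll(rev(fams), g)
  expect_identical(s1, s2)                 # canonical og_id order
  expect_identical(s1$og_id, c("og_a", "og_b"))
  expect_warning(scoreAll(fams, g, ids = c("og_a", "missing")), "skipped")
})

test_that("top-fraction selection uses ceiling with a floor of one", {
  mk <- function(M) data.frame(og_id = sprintf("og%03d", seq_len(M)),
                               pg_index = seq_len(M), ch_index = seq_len(M),
                               n_overall = 10L)
  expect_length(selectTopFraction(mk(100), 0.02), 2)
  expect_length(selectTopFraction(mk(151), 0.02), 4)   # ceiling(3.02)
  expect_length(selectTopFraction(mk(10), 0.02), 1)    # floor guard
  expect_identical(selectTopFraction(mk(100), 0.02), c("og100", "og099"))
})

test_that("top-fraction ties break by CH, then size, then og_id", {
  sc <- data.frame(og_id = c("b", "a", "c", "d"),
                   pg_index = c(5, 5, 5, 1),
                   ch_index = c(9, 9, 10, 1),
                   n_overall = c(4L, 4L, 4L, 4L))
  expect_identical(selectTopFraction(sc, 0.75), c("c", "a", "b"))
  sc$ch_index <- c(9, 9, 9, 1); sc$n_overall <- c(4L, 5L, 4L, 4L)
  expect_identical(selectTopFraction(sc, 0.75), c("a", "b", "c"))
})

test_that("k-means re-clustering recovers planted allele bipartitions", {
  fam <- OgFamily("og", c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAC",
                          a3 = "AAAAAAAACA", b1 = "GGGGGGGGGG",
                          b2 = "GGGGGGGGCG", b3 = "GGGGGGGGGC"))
  for (seed in 1:5) {
    km <- kmeans2RecalcCh(fam, restarts = 1, seed = seed)
    expect_false(km$flagged)
    expect_identical(km$labels[c("a1", "a2", "a3")],
                     setNames(rep(km$labels[["a1"]], 3), c("a1", "a2", "a3")))
    expect_identical(km$labels[c("b1", "b2", "b3")],
                     setNames(rep(km$labels[["b1"]], 3), c("b1", "b2", "b3")))
    expect_false(km$labels[["a1"]] == km$labels[["b1"]])
  }
  # independent cross-check: stats::kmeans on the same embedding
  d <- buildDistanceMatrix(fam)
  ref <- stats::kmeans(d, centers = d[c("a1", "b1"), ], algorithm = "Lloyd")
  km <- kmeans2RecalcCh(fam, seed = 1)
  expect_identical(unname(km$labels == km$labels[["a1"]]),
                   unname(ref$cluster == ref$cluster[["a1"]]))
})

test_that("degenerate and tiny families are flagged in re-clustering", {
  same <- OgFamily("og", c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA"))
  km <- kmeans2RecalcCh(same, seed = 1)
  expect_identical(km$ch, 0)
  expect_true(km$flagged)
  two <- OgFamily("og", c(s1 = "AAAA", s2 = "GGGG"))
  km2 <- kmeans2RecalcCh(two, seed = 1)
  expect_true(km2$flagged)
  expect_true(is.na(km2$ch))
})

test_that("recalculated CH equals the phenotype-label CH when partitions coincide", {
  km <- kmeans2RecalcCh(workedFamily(), seed = 1)
  expect_setequal(names(km$labels)[km$labels == km$labels[["s1"]]],
                  c("s1", "s2"))
  expect_equal(km$ch, 28.33333333, tolerance = 1e-8)
})

test_that("recalculated CH increases with planted separation", {
  set.seed(19)
  base <- paste(rep("A", 50), collapse = "")
  chs <- vapply(c(0.1, 0.2, 0.4, 0.8), function(delta) {
    nmut <- round(50 * delta)
    other <- paste(c(rep("G", nmut), rep("A", 50 - nmut)), collapse = "")
    fam <- OgFamily("og", c(
      a1 = base, a2 = sub("A$", "C", base), a3 = sub("^A", "C", base),
      b1 = other, b2 = sub("A$", "C", other), b3 = sub("G$", "C", other)))
    kmeans2RecalcCh(fam, seed = 3)$ch
  }, numeric(1))
  expect_true(all(diff(chs) > 0))
})

test_that("top-k overlap is a symmetric intersection", {
  expect_identical(overlapTopK(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_identical(overlapTopK(c("a", "b"), c("c", "d")), character(0))
  expect_identical(overlapTopK(c("a", "b", "c"), c("c", "b", "a")),
                   c("a", "b", "c"))
  expect_setequal(overlapTopK(c("a", "b", "c"), c("b", "c", "d")),
                  overlapTopK(c("b", "c", "d"), c("a", "b", "c")))
})

test_that("Kruskal-Wallis H matches the hand-derived value and conventions", {
  kw <- kruskalWallis(list(lo = c(1, 2, 3), hi = c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_identical(kw$df, 1L)
  expect_identical(kruskalWallis(list(a = c(2, 2), b = c(2, 2)))$statistic, 0)
  expect_identical(kruskalWallis(list(a = c(2, 2), b = c(2, 2)))$p.value, 1)
  # invariant under strictly monotone transforms
  g <- list(a = c(1, 3, 7), b = c(2, 9, 11), c = c(4, 5, 6))
  expect_equal(kruskalWallis(g)$statistic,
               kruskalWallis(lapply(g, function(v) exp(v) + 1))$statistic)
})

test_that("pairwise Wilcoxon applies the Bonferroni factor and exact 3v3 p", {
  p2 <- pairwiseWilcoxonBonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(p2["a", "b"], 0.1)              # single pair, factor 1
  expect_equal(p2["a", "b"], enumRankSumP(c(1, 2, 3), c(4, 5, 6)))

  g4 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9),
             d = c(10, 11, 12))
  p4 <- pairwiseWilcoxonBonferroni(g4)
  expect_equal(p4["a", "b"], min(1, 0.1 * 6))  # 6 comparisons
  expect_true(all(p4[upper.tri(p4)] <= 1))
  expect_identical(p4, t(p4))
})

test_that("exact rank-sum p agrees with enumeration over all 3v3 partitions", {
  vals <- 1:6
  for (ix in asplit(combn(6, 3), 2)) {
    x <- vals[ix]; y <- vals[-ix]
    got <- suppressWarnings(wilcox.test(x, y)$p.value)
    expect_equal(got, enumRankSumP(x, y), info = paste(x, collapse = ","))
  }
})

test_that("marker screen applies inclusive 80/50 thresholds", {
  m <- rbind(boundary = c(rep(TRUE, 4), FALSE, TRUE, TRUE, FALSE, FALSE),
             weak     = c(rep(TRUE, 4), FALSE, TRUE, TRUE, TRUE, FALSE),
             everywhere = rep(TRUE, 9))
  colnames(m) <- sprintf("s%d", 1:9)
  pm <- PresenceMatrix(m)
  g <- makeGroups(sprintf("s%d", 1:5), sprintf("s%d", 6:9))
  res <- markerScreen(pm, g)
  expect_identical(res$marker[res$og_id == "boundary"], TRUE)   # 0.8 / 0.5
  expect_identical(res$marker[res$og_id == "weak"], FALSE)      # 0.75 silent? no: 3/4
  expect_identical(res$marker[res$og_id == "everywhere"], FALSE)
  expect_equal(res$active_fraction[res$og_id == "boundary"], 0.8)
  expect_equal(res$silent_fraction[res$og_id == "boundary"], 0.5)
})

test_that("runScreen produces a coherent, deterministic ScreenResult", {
  cfg <- simConfig(nStrains = 12, nCoreOgs = 20, nAccessoryOgs = 5,
                   nMarkerOgs = 2, seqLength = 60, seed = 23)
  st <- simulateStudy(cfg)
  r1 <- runScreen(st$presence, st$families, st$groups, screenConfig(seed = 5))
  r2 <- runScreen(st$presence, st$families, st$groups, screenConfig(seed = 5))
  expect_identical(scoreTable(r1), scoreTable(r2))
  s <- scoreTable(r1)
  expect_true(all(topCandidates(r1) %in% s$og_id))
  expect_identical(sum(s$in_top_fraction), length(topCandidates(r1)))
  # pg_rank is a permutation and the top list is a prefix of the pg order
  expect_setequal(s$pg_rank, seq_len(nrow(s)))
  first <- s$og_id[order(-s$pg_index, s$og_id)][seq_along(topCandidates(r1))]
  expect_setequal(topCandidates(r1), first)
  # k-means labels exist for ranked candidates
  expect_true(all(names(kmeansLabels(r1)) %in% topCandidates(r1)))
})
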