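# BGSS, WGSS, CH index, sequence-distribution factor and PG index.

toyEmbedding <- function() {
  rbind(a1 = c(0, 0), a2 = c(0, 2), b1 = c(4, 0), b2 = c(4, 2))
}

test_that("group centroids are member-row means", {
  emb <- rbind(x = c(0, 2), y = c(2, 0), z = c(3, 4))
  expect_identical(groupCentroid(emb, c("x", "y")), c(1, 1))
  expect_identical(groupCentroid(emb, "z"), c(3, 4))
  expect_error(groupCentroid(emb, character(0)), "empty")
  # overall centroid = size-weighted mean of group centroids
  ca <- groupCentroid(emb, c("x", "y")); cz <- groupCentroid(emb, "z")
  expect_equal((2 * ca + 1 * cz) / 3, colMeans(emb))
})

test_that("BGSS and WGSS reproduce the 2-D toy and degenerate cases", {
  emb <- toyEmbedding()
  expect_identical(bgss(emb, c("a1", "a2")), 16)
  expect_identical(wgss(emb, c("a1", "a2")), 4)
  same <- matrix(1, 4, 2, dimnames = list(rownames(emb), NULL))
  expect_identical(bgss(same, c("a1", "a2")), 0)
  expect_identical(wgss(same, c("a1", "a2")), 0)
  expect_error(bgss(emb, rownames(emb)), "non-empty")
})

test_that("the worked 4-strain OG yields the frozen oracle values", {
  d <- buildDistanceMatrix(workedFamily())
  expect_equal(bgss(d, c("s1", "s2")), 2.65625)
  expect_equal(wgss(d, c("s1", "s2")), 0.1875)
  expect_equal(bgss(d, c("s1", "s2")) + wgss(d, c("s1", "s2")),
               2.84375)  # = total SS about the grand centroid
  expect_equal(chIndex(2.65625, 0.1875, 4), 28.33333333, tolerance = 1e-8)
  # and the brute-force CH on the same embedded points agrees
  labels <- c(1, 1, 2, 2)
  expect_equal(bruteCH(d, labels), 28.33333333, tolerance = 1e-8)
})

test_that("CH index handles its boundary conventions", {
  expect_identical(chIndex(16, 4, 4), 8)
  expect_identical(chIndex(0, 4, 4), 0)
  expect_identical(chIndex(0, 0, 4), 0)
  expect_identical(chIndex(3, 0, 4), Inf)
  expect_error(chIndex(1, 1, 2), "n > K")
})

test_that("sequence-distribution factor counts zeros over the full matrix", {
  d4 <- buildDistanceMatrix(workedFamily())
  expect_identical(seqDistFactor(d4), 1)        # only diagonal zeros: 4/4
  dup <- buildDistanceMatrix(OgFamily("og",
    c(s1 = "AAAA", s2 = "AAAA", s3 = "GGGG", s4 = "GGGT")))
  expect_equal(seqDistFactor(dup), 4 / 6)       # one identical pair
  allsame <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_identical(seqDistFactor(allsame), 0.25)  # 4/16
})

test_that("pgScore assembles the worked example end to end", {
  s <- pgScore(workedFamily(), workedGroups())
  expect_identical(s$og_id, "worked")
  expect_identical(s$n_overall, 4L)
  expect_identical(s$n_active, 2L)
  expect_identical(s$n_silent, 2L)
  expect_equal(s$bgss, 2.65625)
  expect_equal(s$wgss, 0.1875)
  expect_equal(s$ch_index, 28.33333333, tolerance = 1e-8)
  expect_identical(s$seq_dist_factor, 1)
  expect_equal(s$pg_index, 28.33333333, tolerance = 1e-8)
})

test_that("identical sequences across groups give PG = 0", {
  fam <- OgFamily("og", c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA", s4 = "AAAA"))
  s <- pgScore(fam, workedGroups())
  expect_identical(s$bgss, 0)
  expect_identical(s$pg_index, 0)
})

test_that("perfectly separated identical-within-group alleles give PG = Inf", {
  fam <- OgFamily("og", c(s1 = "AAAA", s2 = "AAAA", s3 = "GGGG", s4 = "GGGG"))
  s <- pgScore(fam, workedGroups())
  expect_identical(s$ch_index, Inf)
  expect_identical(s$pg_index, Inf)
})

test_that("variance decomposition holds on random embeddings", {
  set.seed(101)
  for (i in 1:200) {
    r <- randomEmbedding(sample(4:12, 1), sample(2:8, 1))
    b <- bgss(r$X, r$active, r$silent)
    w <- wgss(r$X, r$active, r$silent)
    tss <- sum(sweep(r$X, 2, colMeans(r$X))^2)
    expect_equal(b + w, tss, tolerance = 1e-9)
  }
})

test_that("CH equals the textbook brute force on random labelled points", {
  set.seed(103)
  for (i in 1:50) {
    r <- randomEmbedding(sample(4:10, 1), 3)
    labels <- as.integer(rownames(r$X) %in% r$active) + 1L
    b <- bgss(r$X, r$active, r$silent)
    w <- wgss(r$X, r$active, r$silent)
    expect_equal(chIndex(b, w, nrow(r$X), 2), bruteCH(r$X, labels),
                 tolerance = 1e-9)
  }
})

test_that("PG index is invariant to permutation, label swap and scaling", {
  set.seed(107)
  for (i in 1:100) {
    d <- randomSeqDistance(sample(4:8, 1), 15)
    ids <- rownames(d)
    nA <- sample(1:(length(ids) - 1), 1)
    act <- sample(ids, nA); sil <- setdiff(ids, act)
    ref <- pgIndexFromDistance(d, act, sil)
    # permutation of the strain order
    p <- sample(length(ids))
    expect_equal(pgIndexFromDistance(d[p, p], act, sil)$pg_index,
                 ref$pg_index, tolerance = 1e-9)
    # swapping the active/silent labels as sets
    expect_equal(pgIndexFromDistance(d, sil, act)$pg_index,
                 ref$pg_index, tolerance = 1e-9)
    # uniform scaling of all distances
    s <- runif(1, 0.1, 3)
    sc <- pgIndexFromDistance(d * s, act, sil)
    expect_equal(sc$ch_index, ref$ch_index, tolerance = 1e-9)
    expect_equal(sc$pg_index, ref$pg_index, tolerance = 1e-9)
  }
})

test_that("rigidly separating the groups never decreases CH", {
  set.seed(109)
  emb0 <- rbind(a1 = c(0, 0), a2 = c(0.3, 0.1), a3 = c(0.1, 0.4),
                b1 = c(1, 1), b2 = c(1.2, 0.9), b3 = c(0.8, 1.1))
  act <- c("a1", "a2", "a3"); sil <- c("b1", "b2", "b3")
  prev <- -Inf
  for (shift in seq(0, 5, by = 0.5)) {
    emb <- emb0
    emb[sil, ] <- emb[sil, ] + shift
    ch <- chIndex(bgss(emb, act, sil), wgss(emb, act, sil), nrow(emb), 2)
    expect_gte(ch, prev)
    prev <- ch
  }
})
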