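# bands as columns: build an incidence matrix from a list of band species sets
bands_from_sets <- function(sets, n_species) {
  m <- matrix(0L, n_species, length(sets))
  for (j in seq_along(sets)) m[sets[[j]], j] <- 1L
  as_incidence(m)
}

test_that("Jaccard similarity does set arithmetic and drops empty bands", {
  m <- bands_from_sets(list(c(1, 2, 3), c(2, 3, 4), c(1, 2, 3), 5), 5)
  j <- jaccard_similarity(m)
  expect_equal(unname(j[1, 2]), 0.5)     # {a,b,c} vs {b,c,d} -> 2/4
  expect_equal(unname(j[1, 3]), 1)       # identical bands
  expect_equal(unname(j[1, 4]), 0)       # disjoint bands
  expect_equal(j, t(j))
  expect_equal(unname(diag(j)), rep(1, 4))
  with_empty <- bands_from_sets(list(c(1, 2), integer(0), c(2, 3)), 3)
  expect_message(j2 <- jaccard_similarity(with_empty), "empty")
  expect_equal(dim(j2), c(2L, 2L))
})

test_that("the internal fast profile agrees with vegan's Jaccard", {
  m <- unclass(gen_cooccurrence(15, 8, "random", fill = 0.4, seed = 3))
  prof <- macronull:::similarity_profile(m)
  veg <- sort(1 - as.vector(vegan::vegdist(t(m), "jaccard", binary = TRUE)))
  expect_equal(prof, veg, tolerance = 1e-12)
})

test_that("UPGMA merges by average linkage with ultrametric heights", {
  s2 <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- upgma(s2)
  expect_equal(hc2$height, 0.3)
  # d(AB)=0.1, d(AC)=d(BC)=0.4: AB first at 0.1, then C joins at 0.4
  s3 <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.6, 0.6, 0.6, 1), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- upgma(s3)
  expect_equal(hc3$height, c(0.1, 0.4))
  cop <- stats::cophenetic(hc3)
  # ultrametricity: the two largest of any triple are equal
  d <- as.matrix(cop)
  trip <- sort(c(d["A", "B"], d["A", "C"], d["B", "C"]), decreasing = TRUE)
  expect_equal(trip[1], trip[2])
})

test_that("SIMPROF statistic is non-negative and degenerates to p = 1", {
  ident <- as_incidence(matrix(c(1, 1, 0, 0), 4, 3)) # identical bands
  sp <- simprof(ident, n_perm_mean = 50, n_perm_test = 49, seed = 1)
  expect_equal(sp$pi, 0)
  expect_equal(sp$p_value, 1)
  m <- gen_cooccurrence(15, 6, "random", fill = 0.4, seed = 2)
  sp2 <- simprof(m, n_perm_mean = 50, n_perm_test = 49, seed = 3)
  expect_gte(sp2$pi, 0)
  expect_error(simprof(as_incidence(matrix(1, 3, 2))), "3 bands")
})

test_that("two sharply distinct band groups are detected", {
  m <- local({
    x <- matrix(0L, 30, 10)
    set.seed(5)
    for (i in 1:15) x[i, sample(1:5, 3)] <- 1L
    for (i in 16:30) x[i, 5 + sample(1:5, 3)] <- 1L
    as_incidence(x)
  })
  sp <- simprof(m, n_perm_mean = 300, n_perm_test = 299, seed = 6)
  expect_lte(sp$p_value, 0.01)
})

test_that("SIMPROF p-values are uniform for exchangeable bands", {
  set.seed(7)
  pvals <- replicate(200, {
    x <- matrix(0L, 20, 8)
    for (i in 1:20) x[i, sample.int(8, 3)] <- 1L
    simprof(as_incidence(x), n_perm_mean = 100, n_perm_test = 99,
            seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted blocks are recovered as significant groups", {
  m <- local({
    x <- matrix(0L, 45, 12)
    set.seed(8)
    for (i in 1:15) x[i, sample(1:4, 3)] <- 1L
    for (i in 16:30) x[i, 4 + sample(1:4, 3)] <- 1L
    for (i in 31:45) x[i, 8 + sample(1:4, 3)] <- 1L
    as_incidence(x)
  })
  cl <- cluster_bands(m, n_perm = 300, seed = 9)
  g <- significant_groups(cl)
  expect_equal(length(unique(g$group)), 3)
  # bands within a planted block share a group
  expect_equal(length(unique(g$group[g$band %in% 0:3])), 1)
  expect_equal(length(unique(g$group[g$band %in% 4:7])), 1)
  expect_equal(length(unique(g$group[g$band %in% 8:11])), 1)
})

test_that("without significant structure all bands form one group", {
  m <- gen_cooccurrence(20, 8, "random", fill = 0.4, seed = 10)
  cl <- cluster_bands(m, n_perm = 150, alpha = 1e-6, seed = 11)
  expect_equal(length(unique(significant_groups(cl)$group)), 1)
})

test_that("clustering is invariant to band order up to tie-breaking", {
  m <- gen_cooccurrence(25, 10, "random", fill = 0.35, seed = 12)
  j1 <- jaccard_similarity(m)
  perm <- c(3, 1, 2, 7, 10, 5, 4, 9, 6, 8)
  m2 <- as_incidence(unclass(m)[, perm])
  colnames(m2) <- colnames(m)[perm]
  j2 <- jaccard_similarity(m2)
  expect_equal(j2[rownames(j1), colnames(j1)], j1)
  h1 <- upgma(j1); h2 <- upgma(j2)
  expect_equal(sort(h1$height), sort(h2$height))
})

test_that("Newick export writes one tree with all band labels", {
  skip_if_not_installed("ape")
  m <- gen_cooccurrence(15, 6, "random", fill = 0.4, seed = 13)
  cl <- cluster_bands(m, n_perm = 60, seed = 14)
  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cl, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, as.character(cl$groups$band))
})
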