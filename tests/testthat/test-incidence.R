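test_that("ranges fill every intersecting band, with south-limit clamp", {
  dom <- band_domain(18, 56)
  rng <- tibble::tibble(
    species = c("mid", "edge", "point"),
    lat_min = c(38, 55, 40.3),
    lat_max = c(41, 56, 40.3)
  )
  m <- ranges_to_incidence(rng, dom)
  expect_equal(dim(m), c(3L, 38L))
  expect_equal(colnames(m)[unclass(m)["mid", ] == 1],
               as.character(38:41))
  # a range touching 56 degrees S stays in band 55, no phantom band
  expect_equal(colnames(m)[unclass(m)["edge", ] == 1], "55")
  # point ranges occupy exactly one band
  expect_equal(sum(unclass(m)["point", ]), 1L)
  expect_false(any(rowSums(unclass(m)) == 0))
  expect_error(
    ranges_to_incidence(tibble::tibble(species = "out", lat_min = 10,
                                       lat_max = 20), dom),
    "out"
  )
})

test_that("the bundled 84-species range table yields an 84 x 38 matrix", {
  path <- system.file("extdata", "demo_ranges_synthetic.csv",
                      package = "macronull")
  m <- ranges_to_incidence(read_ranges(path), band_domain(18, 56))
  expect_equal(dim(m), c(84L, 38L))
  expect_true(all(unclass(m) %in% 0:1))
})

test_that("record binning marks only occupied bands unless fill is requested", {
  dom <- band_domain(18, 56)
  rec <- tibble::tibble(species = "a", latitude = c(39.2, 41.7))
  sparse <- records_to_incidence(rec, dom, fill = FALSE)
  expect_equal(colnames(sparse)[unclass(sparse)[1, ] == 1], c("39", "41"))
  filled <- records_to_incidence(rec, dom, fill = TRUE)
  expect_equal(colnames(filled)[unclass(filled)[1, ] == 1],
               as.character(39:41))
  single <- records_to_incidence(
    tibble::tibble(species = "b", latitude = 33.5), dom, fill = TRUE)
  expect_equal(sum(unclass(single)), 1L)
})

test_that("record fill mode equals range construction on derived ranges", {
  dom <- band_domain(18, 56)
  set.seed(42)
  for (i in 1:5) {
    rec <- tibble::tibble(
      species = sample(letters[1:6], 40, replace = TRUE),
      latitude = runif(40, 18, 56)
    )
    a <- records_to_incidence(rec, dom, fill = TRUE)
    b <- ranges_to_incidence(derive_ranges(rec), dom)
    expect_equal(unclass(a)[rownames(b), ], strip_incidence(b))
  }
})

test_that("every range-built row is a contiguous run of presences", {
  m <- ranges_to_incidence(gen_ranges(n_species = 50, seed = 7))
  expect_true(all(apply(unclass(m), 1, is_contiguous_row)))
})

test_that("packing sorts marginals decreasingly, stably and idempotently", {
  m <- as_incidence(rbind(c(1, 0), c(1, 1)))
  pm <- pack_matrix(m)
  expect_equal(unname(strip_incidence(pm)), rbind(c(1L, 1L), c(1L, 0L)))
  expect_equal(strip_incidence(pack_matrix(pm)), strip_incidence(pm))
  r6 <- as_incidence(random_binary_matrix(6, 6, seed = 3))
  p6 <- unclass(pack_matrix(r6))
  expect_true(all(diff(rowSums(p6)) <= 0))
  expect_true(all(diff(colSums(p6)) <= 0))
  # packing permutes rows/columns, never alters them: restoring the
  # original column order recovers the original rows as a multiset
  restored <- p6[, colnames(r6), drop = FALSE]
  expect_equal(sort(apply(restored, 1, paste, collapse = "")),
               sort(apply(unclass(r6), 1, paste, collapse = "")))
  expect_equal(sort(rowSums(p6)), sort(rowSums(unclass(r6))))
  expect_equal(sort(colSums(p6)), sort(colSums(unclass(r6))))
})

test_that("per-band richness is the column-sum profile", {
  expect_equal(richness_per_band(as_incidence(diag(3)))$richness, rep(1L, 3))
  expect_equal(richness_per_band(as_incidence(matrix(1, 5, 4)))$richness,
               rep(5L, 4))
  rng <- gen_ranges(n_species = 30, seed = 11)
  m <- ranges_to_incidence(rng)
  # enumeration oracle: count ranges whose band interval covers each band
  lo <- floor(rng$lat_min); hi <- pmin(floor(rng$lat_max), 55)
  by_hand <- vapply(18:55, function(k) sum(lo <= k & hi >= k), integer(1))
  expect_equal(richness_per_band(m)$richness, by_hand)
})

test_that("CSV round-trips preserve ranges, matrices and covariates", {
  tmp <- withr::local_tempdir()
  rng <- gen_ranges(n_species = 10, seed = 5)[, c("species", "lat_min",
                                                  "lat_max")]
  f <- file.path(tmp, "r.csv")
  write_ranges(rng, f)
  expect_equal(as.data.frame(read_ranges(f)), as.data.frame(rng))

  m <- ranges_to_incidence(gen_ranges(n_species = 12, seed = 6))
  f2 <- file.path(tmp, "m.csv")
  write_incidence(m, f2)
  m2 <- read_incidence(f2)
  expect_equal(unclass(m2), unclass(m))

  cov <- gen_covariates(seed = 2)
  f3 <- file.path(tmp, "c.csv")
  write_covariates(cov, f3)
  expect_equal(as.data.frame(read_covariates(f3)), as.data.frame(cov),
               tolerance = 1e-12)
  # a missing band is reported by name
  write_covariates(cov[-3, ], f3)
  expect_error(read_covariates(f3, band_domain(18, 56)), "20")
})

test_that("signed-latitude input is normalised to degrees South", {
  rngs <- tibble::tibble(species = "a", lat_min = -41, lat_max = -38)
  m <- ranges_to_incidence(rngs, band_domain(18, 56), signed = TRUE)
  expect_equal(colnames(m)[unclass(m)[1, ] == 1], as.character(38:41))
})
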