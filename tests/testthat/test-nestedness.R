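triangle <- function(n) {
  as_incidence(outer(seq(n, 1), seq_len(n),
                     function(r, j) as.integer(j <= r)))
}

test_that("NODF hits its definitional limits", {
  expect_equal(nodf(triangle(4))$nodf_total, 100)
  expect_equal(nodf(triangle(6))$nodf_rows, 100)
  # identical rows: no decreasing row fill, so the row component is 0
  same <- as_incidence(matrix(rep(c(1, 1, 0, 0), 3), 3, 4, byrow = TRUE))
  expect_equal(nodf(same)$nodf_rows, 0)
})

test_that("NODF equals the brute-force pair loop and vegan on random matrices", {
  for (seed in 1:6) {
    m <- random_binary_matrix(5, 5, seed = seed)
    ours <- nodf(as_incidence(m))
    oracle <- oracle_nodf(m)
    expect_equal(ours$nodf_total, oracle$total, tolerance = 1e-12)
    expect_equal(ours$nodf_rows, oracle$rows, tolerance = 1e-12)
    expect_equal(ours$nodf_cols, oracle$cols, tolerance = 1e-12)
    veg <- vegan::nestednodf(m, order = TRUE)$statistic
    expect_equal(ours$nodf_total, unname(veg["NODF"]), tolerance = 1e-9)
  }
})

test_that("NODF is invariant to row and column permutations", {
  m <- random_binary_matrix(7, 6, seed = 9)
  shuffled <- m[sample(7), sample(6)]
  expect_equal(nodf(as_incidence(m)), nodf(as_incidence(shuffled)))
})

test_that("temperature is 0 for perfect nestedness and high for checkerboards", {
  expect_equal(nestedness_temperature(triangle(4)), 0)
  expect_equal(nestedness_temperature(triangle(8)), 0)
  cb <- as_incidence(outer(1:6, 1:6, function(i, j) as.integer((i + j) %% 2 == 0)))
  expect_gt(nestedness_temperature(cb), 50)
  expect_gt(nestedness_temperature(cb),
            nestedness_temperature(gen_nested(6, 6, 1, 0.55, seed = 1)))
  expect_error(nestedness_temperature(as_incidence(matrix(1, 3, 3))),
               "undefined")
})

test_that("temperature equals an independent cell-loop recomputation", {
  for (seed in c(2, 5, 8)) {
    m <- random_binary_matrix(5, 5, seed = seed)
    expect_equal(nestedness_temperature(as_incidence(m)),
                 oracle_temperature(m), tolerance = 1e-6)
  }
  m2 <- random_binary_matrix(8, 10, fill = 0.3, seed = 3)
  expect_equal(nestedness_temperature(as_incidence(m2)),
               oracle_temperature(m2), tolerance = 1e-6)
})

test_that("temperature tracks vegan's calculator directionally", {
  t_nested <- nestedness_temperature(gen_nested(12, 10, 0.9, 0.3, seed = 1))
  t_random <- nestedness_temperature(gen_nested(12, 10, 0.1, 0.3, seed = 1))
  v_nested <- vegan::nestedtemp(unclass(gen_nested(12, 10, 0.9, 0.3, seed = 1)))$statistic
  v_random <- vegan::nestedtemp(unclass(gen_nested(12, 10, 0.1, 0.3, seed = 1)))$statistic
  expect_lt(t_nested, t_random)
  expect_lt(v_nested, v_random)
})

test_that("BR discrepancy counts misplaced presences", {
  expect_equal(br_discrepancy(triangle(5)), 0)
  # equal column totals keep the stable order, so the (0,1) row with
  # r = 1 contributes one misplaced presence
  tied <- as_incidence(rbind(c(1, 0), c(0, 1)))
  expect_equal(br_discrepancy(tied), 1)
  for (seed in 1:5) {
    m <- random_binary_matrix(6, 6, seed = seed + 20)
    expect_equal(br_discrepancy(as_incidence(m)), oracle_br(m))
  }
})

test_that("fixed-equiprobable null preserves row sums and detects nesting", {
  m <- gen_nested(10, 10, rho = 1, fill = 0.55, seed = 2)
  draws <- macronull:::with_seed(3, replicate(
    20, macronull:::null_draw(unclass(m), "fixed-equiprobable"),
    simplify = FALSE))
  for (d in draws) expect_equal(rowSums(d), unname(rowSums(unclass(m))))
  nt <- nestedness_null_test(m, "NODF_total", n_iter = 1000, seed = 4)
  expect_lte(nt$p_value, 0.01)
  expect_gt(nt$observed, nt$null_mean)
  expect_true(nt$null_ci95[1] <= nt$null_mean &&
                nt$null_mean <= nt$null_ci95[2])
})

test_that("equiprobable-equiprobable null preserves total fill", {
  m <- gen_nested(8, 8, rho = 0.5, fill = 0.4, seed = 5)
  d <- macronull:::with_seed(6,
    macronull:::null_draw(unclass(m), "equiprobable-equiprobable"))
  expect_equal(sum(d), sum(unclass(m)))
})

test_that("stronger planted nestedness raises NODF and lowers temperature", {
  stats_at <- function(rho) {
    vals <- vapply(1:15, function(i) {
      m <- gen_nested(20, 12, rho = rho, fill = 0.3, seed = i)
      c(nodf(m)$nodf_total, nestedness_temperature(m))
    }, numeric(2))
    rowMeans(vals)
  }
  weak <- stats_at(0.2); strong <- stats_at(0.9)
  expect_gt(strong[1], weak[1]) # NODF rises
  expect_lt(strong[2], weak[2]) # T falls
})
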