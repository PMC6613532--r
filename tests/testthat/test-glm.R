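indep_covariates <- function(seed, n_pred = 5) {
  set.seed(seed)
  out <- tibble::tibble(band = 18:55)
  for (i in seq_len(n_pred)) out[[paste0("x", i)]] <- rnorm(38)
  out
}

test_that("the intercept-only Poisson fit is the sample mean", {
  cov <- indep_covariates(1)
  y <- gen_glm_bands(cov, beta = numeric(0), intercept = log(8), seed = 2)
  f <- fit_poisson(y, character())
  expect_equal(unname(exp(stats::coef(f$glm)[1])), mean(y$richness),
               tolerance = 1e-8)
  expect_equal(f$pseudo_r2_mcfadden, 0)
  expect_equal(f$pseudo_r2_nagelkerke, 0)
})

test_that("AICc applies the small-sample correction and vanishes at large n", {
  expect_equal(aicc(-134.69, 2, 39), 2 * 134.69 + 4 + 12 / 36)
  expect_lt(abs(aicc(-100, 3, 1e6) - (-2 * -100 + 6)), 1e-4)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("pseudo-R2 formulas match hand arithmetic and are monotone", {
  ll0 <- -140; n <- 38
  r2 <- pseudo_r2(-120, ll0, n)
  expect_equal(r2$mcfadden, 1 - (-120) / (-140))
  expect_equal(r2$nagelkerke,
               (1 - exp(2 / 38 * (-140 - -120))) / (1 - exp(2 / 38 * -140)))
  lls <- c(-135, -125, -110)
  mf <- vapply(lls, function(l) pseudo_r2(l, ll0, n)$mcfadden, numeric(1))
  ng <- vapply(lls, function(l) pseudo_r2(l, ll0, n)$nagelkerke, numeric(1))
  expect_true(all(diff(mf) > 0))
  expect_true(all(diff(ng) > 0))
})

test_that("fits agree with stats::glm and nesting never lowers loglik", {
  cov <- indep_covariates(3)
  y <- gen_glm_bands(cov, beta = c(x1 = 0.4, x2 = -0.2), seed = 4)
  dat <- dplyr::inner_join(y, cov, by = "band")
  f1 <- fit_poisson(dat, "x1")
  f12 <- fit_poisson(dat, c("x1", "x2"))
  f123 <- fit_poisson(dat, c("x1", "x2", "x3"))
  expect_gte(f12$loglik, f1$loglik)
  expect_gte(f123$loglik, f12$loglik)
  # deviance identity on the fitted glm
  expect_equal(f12$glm$deviance,
               2 * (sum(stats::dpois(dat$richness, dat$richness, log = TRUE)) -
                      f12$loglik),
               tolerance = 1e-6)
})

test_that("single-predictor ranking is deterministic and finds the signal", {
  cov <- indep_covariates(5)
  set.seed(6)
  firsts <- replicate(50, {
    y <- gen_glm_bands(cov, beta = c(x2 = 0.6), seed = sample.int(1e6, 1))
    dat <- dplyr::inner_join(y, cov, by = "band")
    rank_single_predictors(dat, paste0("x", 1:5))$predictor[1]
  })
  expect_gte(mean(firsts == "x2"), 0.95)
  y <- gen_glm_bands(cov, beta = c(x2 = 0.6), seed = 7)
  dat <- dplyr::inner_join(y, cov, by = "band")
  r1 <- rank_single_predictors(dat, paste0("x", 1:5))
  r2 <- rank_single_predictors(dat, paste0("x", 1:5))
  expect_identical(dplyr::select(r1, -"fit"), dplyr::select(r2, -"fit"))
  expect_true(all(diff(r1$aicc) >= 0))
  expect_equal(r1$delta_aicc[1], 0)
})

test_that("stepwise AICc always keeps the planted predictor, mostly alone", {
  # AICc selection is not consistent: a spurious extra predictor clears
  # the 2k penalty in a sizeable minority of replicates, so the honest
  # expectations are certain inclusion and a typically minimal model
  set.seed(9)
  stats <- vapply(1:50, function(i) {
    cov <- indep_covariates(1000 + i)
    y <- gen_glm_bands(cov, beta = c(x3 = 0.7), seed = sample.int(1e6, 1))
    dat <- dplyr::inner_join(y, cov, by = "band")
    sel <- stepwise_aicc(dat, scope = paste0("x", 1:5))$predictors
    c("x3" %in% sel, identical(sel, "x3"), length(sel))
  }, numeric(3))
  expect_gte(mean(stats[1, ]), 0.95) # planted predictor retained
  expect_gte(mean(stats[2, ]), 0.50) # exact singleton in most seeds
  expect_lt(mean(stats[3, ]), 2)     # little spurious inflation
})

test_that("stepwise handles empty scope and ignores column order", {
  cov <- indep_covariates(10)
  y <- gen_glm_bands(cov, beta = c(x1 = 0.5), seed = 11)
  dat <- dplyr::inner_join(y, cov, by = "band")
  expect_equal(stepwise_aicc(dat, scope = character())$predictors, character())
  a <- stepwise_aicc(dat, scope = c("x1", "x2", "x3"))
  b <- stepwise_aicc(dat, scope = c("x3", "x1", "x2"))
  expect_equal(a$predictors, b$predictors)
  expect_equal(a$aicc, b$aicc)
})

test_that("near-collinear predictors trigger a warning", {
  cov <- indep_covariates(12)
  cov$x2 <- cov$x1 + rnorm(38, sd = 1e-8)
  y <- gen_glm_bands(cov, beta = c(x1 = 0.3), seed = 13)
  dat <- dplyr::inner_join(y, cov, by = "band")
  expect_warning(fit_poisson(dat, c("x1", "x2")), "collinear")
})
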