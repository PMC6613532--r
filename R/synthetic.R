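#' Synthetic data with known, controllable structure
#'
#' Generators for latitudinal ranges, structured incidence matrices and
#' Poisson richness counts. Every generator is a pure function of its
#' arguments and `seed`, so downstream statistics can be verified by
#' parameter recovery. The defaults emulate the study conditions of the
#' Chilean freshwater mollusk gradient: 84 species on 18-56 degrees S with
#' a strongly right-skewed range-size distribution (more than half of the
#' ranges narrower than 2 degrees).
#'
#' @name synthetic
NULL

# Split one master seed into independent substream seeds (all < 2^31).
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Evaluate `expr` under `seed`, then restore the caller's RNG state.
# `seed` is forced first so that arguments like `seed = sample.int(...)`
# advance the caller's stream instead of being rolled back.
with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Inverse-CDF draws from a lognormal truncated to [lo, hi].
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), meanlog, sdlog)
}

# CDF of the same truncated lognormal (used by tests as the closed form).
plnorm_trunc <- function(q, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  pmin(1, pmax(0, (stats::plnorm(q, meanlog, sdlog) - p_lo) / (p_hi - p_lo)))
}

#' Generate species latitudinal ranges
#'
#' Range sizes are drawn from the chosen model and each range's midpoint is
#' then placed uniformly on its feasible interval
#' `[north + r/2, south - r/2]` -- the same placement rule as the
#' mid-domain null, reused as a generator. The default size model is a
#' lognormal truncated to `[1, domain width]` degrees with `meanlog = 0`,
#' `sdlog = 1`, which keeps over half of the ranges under 2 degrees,
#' matching the right-skewed empirical distribution.
#'
#' @param n_species Number of species (default 84).
#' @param domain A [band_domain()] (default 18-56 degrees S).
#' @param size_model One of `"lognormal"` (truncated), `"empirical"`
#'   (resample `sizes` with replacement) or `"fixed"` (all equal).
#' @param meanlog,sdlog Lognormal parameters (size model `"lognormal"`).
#' @param sizes Numeric vector of sizes to resample (size model `"empirical"`).
#' @param fixed_size Common size in degrees (size model `"fixed"`).
#' @param seed Integer seed; same seed, same output.
#' @return A tibble with `species`, `lat_min`, `lat_max`, `midpoint`, `extent`.
#' @examples
#' rng <- gen_ranges(n_species = 10, seed = 1)
#' mean(rng$extent < 2)
#' @export
gen_ranges <- function(n_species = 84, domain = band_domain(),
                       size_model = c("lognormal", "empirical", "fixed"),
                       meanlog = 0, sdlog = 1, sizes = NULL, fixed_size = NULL,
                       seed = 1L) {
  size_model <- match.arg(size_model)
  width <- domain$south_limit - domain$north_limit
  with_seed(seed, {
    r <- switch(size_model,
      lognormal = rlnorm_trunc(n_species, meanlog, sdlog, 1, width),
      empirical = {
        if (is.null(sizes)) stop("`sizes` required for empirical resampling.",
                                 call. = FALSE)
        if (any(sizes > width)) stop("Empirical sizes exceed the domain width.",
                                     call. = FALSE)
        sample(sizes, n_species, replace = TRUE)
      },
      fixed = {
        if (is.null(fixed_size)) stop("`fixed_size` required.", call. = FALSE)
        if (fixed_size > width) stop("`fixed_size` exceeds the domain width.",
                                     call. = FALSE)
        rep(fixed_size, n_species)
      }
    )
    mid <- stats::runif(n_species, domain$north_limit + r / 2,
                        domain$south_limit - r / 2)
    tibble::tibble(
      species = sprintf("sp%03d", seq_len(n_species)),
      lat_min = mid - r / 2,
      lat_max = mid + r / 2,
      midpoint = mid,
      extent = r
    )
  })
}

#' Generate an incidence matrix with tunable nestedness
#'
#' At `rho = 1` the output is a perfectly nested packed matrix (a staircase
#' of decreasing row fills at the requested density). Each presence is then
#' independently relocated to a uniformly chosen empty cell with
#' probability `1 - rho`, so `rho = 0` is a uniformly random matrix with
#' the same number of presences (matched density).
#'
#' @param n_species,n_sites Matrix dimensions.
#' @param rho Nestedness strength in `[0, 1]`.
#' @param fill Target proportion of presences (default 0.25).
#' @param seed Integer seed.
#' @return An `incidence` matrix (generic site domain).
#' @export
gen_nested <- function(n_species = 84, n_sites = 38, rho = 1, fill = 0.25,
                       seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, fill > 0, fill < 1)
  n_pres <- min(n_species * n_sites,
                max(n_species, round(fill * n_species * n_sites)))
  rf <- staircase_fills(n_species, n_sites, n_pres)
  m <- matrix(0L, n_species, n_sites)
  for (i in seq_len(n_species)) m[i, seq_len(rf[i])] <- 1L
  with_seed(seed, {
    if (rho < 1) {
      pres <- which(m == 1L)
      move <- pres[stats::runif(length(pres)) > rho]
      for (cell in move) {
        empty <- which(m == 0L)
        if (!length(empty)) break
        m[cell] <- 0L
        m[if (length(empty) == 1L) empty else sample(empty, 1L)] <- 1L
      }
    }
    as_incidence(m)
  })
}

#' Generate an incidence matrix with tunable co-occurrence structure
#'
#' Starts from a random matrix (each species' presences placed uniformly)
#' and plants structure with margin-preserving directional checkerboard
#' swaps: random 2x2 checkerboard submatrices are swapped only when the
#' move lowers (`"aggregated"`) or raises (`"segregated"`) the C-score.
#' Both row and column sums stay exactly those of the random start, so the
#' planted matrix sits in the corresponding tail of its own fixed-fixed
#' (SIM9) ensemble: aggregation lowers the observed C-score below the null
#' mean, segregation raises it above. `effect` scales the number of
#' attempted directional moves (0 = none).
#'
#' @param n_species,n_sites Matrix dimensions.
#' @param structure `"random"`, `"segregated"` or `"aggregated"`.
#' @param effect Structure strength in `[0, 1]`.
#' @param fill Expected per-cell occupancy used to draw row totals.
#' @param moves_per_species Directional swap attempts per species at
#'   `effect = 1` (default 30).
#' @param seed Integer seed.
#' @return An `incidence` matrix.
#' @export
gen_cooccurrence <- function(n_species = 84, n_sites = 38,
                             structure = c("random", "segregated", "aggregated"),
                             effect = 1, fill = 0.25, moves_per_species = 30,
                             seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(effect >= 0, effect <= 1)
  with_seed(seed, {
    m <- matrix(0L, n_species, n_sites)
    for (i in seq_len(n_species)) {
      m[i, sample.int(n_sites, max(1L, stats::rbinom(1L, n_sites, fill)))] <- 1L
    }
    if (structure != "random" && effect > 0) {
      sgn <- if (structure == "segregated") 1 else -1
      n_attempts <- round(effect * moves_per_species * n_species)
      for (a in seq_len(n_attempts)) {
        i <- sample.int(n_species, 2L)
        j <- sample.int(n_sites, 2L)
        s <- m[i, j]
        is_cb <- (s[1L] + s[4L] == 2L && s[2L] + s[3L] == 0L) ||
          (s[1L] + s[4L] == 0L && s[2L] + s[3L] == 2L)
        if (is_cb && sgn * cu_swap_delta(m, i, j) > 0) {
          m[i, j] <- s[c(3L, 4L, 1L, 2L)]
        }
      }
    }
    as_incidence(m)
  })
}

# Decreasing row fills summing exactly to n_pres, strictly decreasing
# wherever the integer/density constraints allow (a square matrix at
# triangular density yields the exact R..1 staircase, the one
# configuration whose packed matrix scores NODF = 100).
staircase_fills <- function(R, C, n_pres) {
  stopifnot(n_pres >= R, n_pres <= R * C)
  w <- seq(R, 1)
  f <- sort(pmax(1L, pmin(C, as.integer(round(n_pres * w / sum(w))))),
            decreasing = TRUE)
  # strictness pass (may undershoot the total)
  for (i in seq_len(R)[-1]) f[i] <- max(1L, min(f[i], f[i - 1L] - 1L))
  repeat {
    delta <- n_pres - sum(f)
    if (delta == 0L) break
    if (delta > 0L) {
      cap <- c(C, pmax(f[-R] - 1L, 1L)) # strict headroom per row
      i <- which(f < cap)[1L]
      if (is.na(i)) i <- which(f < C)[1L] # ties unavoidable: relax
      f[i] <- f[i] + 1L
    } else {
      flo <- c(pmin(f[-1L] + 1L, C), 1L) # strict floor per row
      i <- rev(which(f > flo))[1L]
      if (is.na(i)) i <- rev(which(f > 1L))[1L]
      f[i] <- f[i] - 1L
    }
  }
  f
}

# Change in the total checkerboard-unit sum if the 2x2 checkerboard at
# rows i = (i1, i2), cols j = (j1, j2) were diagonally swapped. Only pairs
# involving rows i1 or i2 are affected; row sums are unchanged.
cu_swap_delta <- function(m, i, j) {
  r <- rowSums(m)
  new1 <- m[i[1L], ]; new1[j] <- m[i[2L], j]
  new2 <- m[i[2L], ]; new2[j] <- m[i[1L], j]
  others <- setdiff(seq_len(nrow(m)), i)
  s_old <- m[others, , drop = FALSE] %*% cbind(m[i[1L], ], m[i[2L], ])
  s_new <- m[others, , drop = FALSE] %*% cbind(new1, new2)
  cu <- function(s, a) (r[a] - s) * (r[others] - s)
  delta <- sum(cu(s_new[, 1L], i[1L])) + sum(cu(s_new[, 2L], i[2L])) -
    sum(cu(s_old[, 1L], i[1L])) - sum(cu(s_old[, 2L], i[2L]))
  s12_old <- sum(m[i[1L], ] * m[i[2L], ])
  s12_new <- sum(new1 * new2)
  delta + (r[i[1L]] - s12_new) * (r[i[2L]] - s12_new) -
    (r[i[1L]] - s12_old) * (r[i[2L]] - s12_old)
}

#' Generate per-band Poisson richness counts from covariates
#'
#' Counts are drawn `Poisson(exp(eta))` with
#' `eta = intercept + X beta` where `X` holds the named predictor columns,
#' z-score standardized by default (the scale on which the models are
#' fitted).
#'
#' @param covariates A data frame with a `band` column and predictor columns.
#' @param beta Named numeric vector of coefficients on the (standardized)
#'   predictor scale; names must be covariate columns.
#' @param intercept Intercept on the log scale (default `log(10)`, i.e. a
#'   mean richness of 10 species per band when all predictors are at their
#'   mean).
#' @param standardize Standardize predictors before applying `beta`?
#' @param seed Integer seed.
#' @return A tibble with `band` and `richness`.
#' @export
gen_glm_bands <- function(covariates, beta, intercept = log(10),
                          standardize = TRUE, seed = 1L) {
  miss <- setdiff(names(beta), names(covariates))
  if (length(miss)) {
    stop("`beta` names absent from covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(covariates[names(beta)])
  if (length(beta) && standardize) X <- scale(X)
  eta <- as.numeric(intercept + if (length(beta)) X %*% beta else 0)
  with_seed(seed, tibble::tibble(
    band = as.integer(covariates$band),
    richness = stats::rpois(nrow(covariates), exp(eta))
  ))
}

#' Generate a synthetic per-band environmental covariate table
#'
#' Produces the eleven predictor columns used throughout the package
#' (climatic, topographic and hydrographic descriptors of each 1-degree
#' band) with latitude-linked trends plus noise, scaled to plausible
#' magnitudes. Purely synthetic: a stand-in for a tabulated GIS extraction.
#'
#' @param domain A [band_domain()].
#' @param seed Integer seed.
#' @return A tibble with `band` plus 11 numeric predictor columns.
#' @export
gen_covariates <- function(domain = band_domain(), seed = 1L) {
  with_seed(seed, {
    b <- domain$bands
    n <- length(b)
    z <- (b - mean(b)) / stats::sd(b) # standardized latitude
    noise <- function(s) stats::rnorm(n, 0, s)
    tibble::tibble(
      band = b,
      annual_temperature = 8.6 - 2.5 * z + noise(0.8),
      seasonality_temperature = 300 - 45 * z + noise(20),
      annual_precipitation = pmax(10, 950 + 800 * z + noise(250)),
      seasonality_precipitation = pmax(5, 66 + 35 * z + noise(12)),
      annual_uv_radiation = pmax(500, 3900 - 1800 * z + noise(400)),
      range_heterogeneity = pmax(100, 3200 - 1500 * z^2 + noise(600)),
      shannon_heterogeneity = pmax(5000, 26000 - 4000 * z^2 + noise(3000)),
      altitude_mean = pmax(100, 1370 - 900 * z + noise(300)),
      altitude_range = pmax(300, 3200 - 1000 * z^2 + noise(500)),
      band_area = pmax(1e6, 1.9e7 - 4e6 * z + noise(4e6)),
      kernel_density_river = pmin(0.6, pmax(0.005, 0.31 + 0.15 * z + noise(0.07)))
    )
  })
}
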