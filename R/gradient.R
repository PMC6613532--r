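#' Chao2 incidence-based richness estimate
#'
#' Inventory-completeness estimate with latitudinal bands as incidence
#' samples. With `q1` uniques (species in exactly one band) and `q2`
#' duplicates (exactly two bands), the classic estimator
#' `S_est = S_obs + q1^2 / (2 q2)` is used when `q2 > 0`, and the
#' bias-corrected form
#' `S_est = S_obs + ((m - 1) / m) * q1 (q1 - 1) / (2 (q2 + 1))`
#' when `q2 = 0` (`m` = number of bands).
#'
#' @param m An `incidence` matrix (bands as samples).
#' @return A one-row tibble: `s_obs`, `q1`, `q2`, `m`, `s_est`.
#' @examples
#' mat <- as_incidence(rbind(diag(3), 1))
#' chao2(mat)
#' @export
chao2 <- function(m) {
  vals <- unclass(m)
  if (!length(vals) || sum(vals) == 0L) {
    stop("Cannot estimate richness from an empty incidence matrix.",
         call. = FALSE)
  }
  occ <- rowSums(vals)
  s_obs <- sum(occ > 0)
  q1 <- sum(occ == 1)
  q2 <- sum(occ == 2)
  n_bands <- ncol(vals)
  s_est <- if (q2 > 0) {
    s_obs + q1^2 / (2 * q2)
  } else {
    s_obs + (n_bands - 1) / n_bands * q1 * (q1 - 1) / (2 * (q2 + 1))
  }
  tibble::tibble(s_obs = s_obs, q1 = q1, q2 = q2, m = n_bands, s_est = s_est)
}

#' Rapoport's rule randomized regression
#'
#' Regresses each species' latitudinal extent (response) on its range
#' midpoint (predictor) and evaluates the slope against a permutation null
#' in which extents are shuffled across midpoints. The permutation p-value
#' includes the observed arrangement (`+1` correction), so it is never 0.
#' A positive, significant slope -- ranges widening poleward -- supports
#' Rapoport's rule.
#'
#' @param ranges A data frame with `species`, `lat_min`, `lat_max`
#'   (midpoint/extent derived), or already carrying `midpoint`/`extent`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param tails `"two"` (default; tests slope != 0) or `"one"`
#'   (tests slope > 0, the rule's direction).
#' @return An object of class `rapoport_test` with elements `slope`,
#'   `intercept`, `r` (Pearson correlation), `p_perm`, `n_perm`, `tails`,
#'   `data` (midpoint/extent tibble) and `null_slopes`.
#' @export
rapoport_test <- function(ranges, n_perm = 999, seed = 1L,
                          tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!all(c("midpoint", "extent") %in% names(ranges))) {
    ranges <- range_summary(ranges)
  }
  if (nrow(ranges) < 3) stop("Need at least 3 species.", call. = FALSE)
  mid <- ranges$midpoint
  ext <- ranges$extent
  if (stats::var(mid) == 0) {
    stop("Midpoints have zero variance; the slope is undefined.", call. = FALSE)
  }
  slope_of <- function(y) stats::cov(mid, y) / stats::var(mid)
  slope <- slope_of(ext)
  intercept <- mean(ext) - slope * mean(mid)
  r <- if (stats::var(ext) == 0) 0 else stats::cor(mid, ext)
  null_slopes <- with_seed(seed, vapply(
    seq_len(n_perm), function(i) slope_of(sample(ext)), numeric(1)
  ))
  exceed <- if (tails == "two") {
    sum(abs(null_slopes) >= abs(slope))
  } else {
    sum(null_slopes >= slope)
  }
  structure(
    list(slope = slope, intercept = intercept, r = r,
         p_perm = (1 + exceed) / (1 + n_perm), n_perm = n_perm, tails = tails,
         data = tibble::tibble(species = ranges$species, midpoint = mid,
                               extent = ext),
         null_slopes = null_slopes),
    class = "rapoport_test"
  )
}

#' @export
print.rapoport_test <- function(x, ...) {
  cat("Rapoport randomized regression (extent ~ midpoint)\n")
  cat(sprintf("  slope = %.4f, r = %.3f, p = %.4g (%s-tailed, %d permutations)\n",
              x$slope, x$r, x$p_perm, x$tails, x$n_perm))
  invisible(x)
}

#' @method tidy rapoport_test
#' @export
tidy.rapoport_test <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "midpoint"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance rapoport_test
#' @export
glance.rapoport_test <- function(x, ...) {
  tibble::tibble(slope = x$slope, r = round(x$r, 3), p_perm = x$p_perm,
                 n_perm = x$n_perm, tails = x$tails)
}

#' @method autoplot rapoport_test
#' @export
autoplot.rapoport_test <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$midpoint, .data$extent)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Range midpoint (degrees S)", y = "Range extent (degrees)",
      title = "Rapoport's rule: extent vs midpoint",
      subtitle = sprintf("slope = %.3f, r = %.3f, permutation p = %.3f",
                         object$slope, object$r, object$p_perm)
    )
}
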