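#' Nestedness metrics and null-model tests
#'
#' Three classic measures of nestedness of a packed presence-absence
#' matrix: NODF (overlap and decreasing fill, 0-100, higher = more
#' nested), matrix temperature T (0-100, lower = more nested) and the BR
#' discrepancy (count of misplaced presences, lower = more nested), each
#' testable against Monte Carlo null matrices. Packing is applied
#' internally, so all metrics are invariant to the input row/column order.
#'
#' @name nestedness
NULL

#' NODF nestedness metric
#'
#' For every ordered pair of rows (and of columns) of the packed matrix
#' with strictly decreasing marginal fill, the paired nestedness is
#' `100 * shared presences / fill of the poorer line`; pairs with equal
#' fill contribute 0. The row and column components are means over their
#' pairs and the total is the mean over all pairs combined.
#'
#' @param m An `incidence` matrix (packing is applied internally).
#' @return A one-row tibble with `nodf_total`, `nodf_rows`, `nodf_cols`.
#' @examples
#' tri <- as_incidence(outer(4:1, 1:4, function(r, j) as.integer(j <= r)))
#' nodf(tri) # perfectly nested: 100 everywhere
#' @export
nodf <- function(m) {
  p <- unclass(pack_matrix(m))
  if (nrow(p) < 2 && ncol(p) < 2) {
    stop("NODF needs at least 2 rows or 2 columns.", call. = FALSE)
  }
  comp <- function(x) { # x: lines in packed (decreasing-fill) order
    f <- rowSums(x)
    n <- nrow(x)
    if (n < 2) return(c(sum = 0, pairs = 0, mean = NA_real_))
    shared <- tcrossprod(x)
    tot <- 0
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      dec <- f[i] > f[j] & f[j] > 0
      tot <- tot + sum(100 * shared[i, j][dec] / f[j][dec])
    }
    c(sum = tot, pairs = n * (n - 1) / 2, mean = tot / (n * (n - 1) / 2))
  }
  rows <- comp(p)
  cols <- comp(t(p))
  tibble::tibble(
    nodf_total = unname((rows["sum"] + cols["sum"]) /
                          (rows["pairs"] + cols["pairs"])),
    nodf_rows = unname(rows["mean"]),
    nodf_cols = unname(cols["mean"])
  )
}

#' Matrix temperature
#'
#' Departure from perfect nestedness of the packed matrix, on a 0-100
#' scale (0 = perfectly nested). Cells are mapped to the unit square
#' (presence-rich corner at the origin) and compared with the isocline
#' `x^p + y^p = 1`, where `p` is solved so that the area inside the
#' isocline equals the matrix fill. Unexpected presences (outside the
#' isocline) and absences (inside) contribute the squared relative
#' distance from the isocline measured along the main-diagonal line
#' through the cell; the summed surprise `U` is normalized by the
#' conventional constant 0.04145 per cell.
#'
#' This is a fully specified re-formalization of the classic temperature
#' calculator; exact numeric parity with legacy software is not claimed.
#'
#' @param m An `incidence` matrix.
#' @return Temperature in `[0, 100]` (values slightly above 100 are
#'   clamped).
#' @export
nestedness_temperature <- function(m) {
  p <- unclass(pack_matrix(m))
  fill <- mean(p)
  if (fill == 0 || fill == 1) {
    stop("Temperature is undefined for all-zero or all-one matrices.",
         call. = FALSE)
  }
  R <- nrow(p); C <- ncol(p)
  pw <- isocline_power(fill)
  x <- (rep(seq_len(C), each = R) - 0.5) / C
  y <- (rep(seq_len(R), times = C) - 0.5) / R
  v <- as.integer(p) # column-major matches the y/x construction above
  side <- x^pw + y^pw # <= 1: inside isocline (expected presence region)
  unexpected <- (v == 1L & side > 1) | (v == 0L & side < 1)
  u <- numeric(sum(unexpected))
  xs <- x[unexpected]; ys <- y[unexpected]
  for (i in seq_along(xs)) {
    u[i] <- diag_surprise(xs[i], ys[i], pw)
  }
  min(100, 100 * sum(u) / (0.04145 * R * C))
}

# Solve x^p + y^p = 1 isocline power so the enclosed area equals `fill`.
# Area inside the curve in the unit square is Gamma(1+1/p)^2 / Gamma(1+2/p).
isocline_power <- function(fill) {
  area <- function(lp) {
    p <- exp(lp)
    exp(2 * lgamma(1 + 1 / p) - lgamma(1 + 2 / p))
  }
  stats::uniroot(function(lp) area(lp) - fill, lower = log(0.02),
                 upper = log(80), tol = 1e-10)$root |> exp()
}

# Squared relative distance from the isocline along the diagonal line
# y = x + c through the cell (x0, y0).
diag_surprise <- function(x0, y0, pw) {
  c0 <- y0 - x0
  t_lo <- max(0, -c0)
  t_hi <- min(1, 1 - c0)
  g <- function(t) t^pw + (t + c0)^pw - 1
  t_iso <- stats::uniroot(g, lower = t_lo, upper = t_hi, tol = 1e-10)$root
  ((x0 - t_iso) / (t_hi - t_lo))^2
}

#' BR discrepancy
#'
#' After ordering columns by decreasing totals (stable ties), the
#' discrepancy is the number of absences among the leftmost `r_i` cells of
#' each row `i` with row sum `r_i` -- equivalently, the number of
#' presences that must be shifted left to achieve maximal packing given
#' the row sums. 0 for a perfectly packed nested matrix.
#'
#' @param m An `incidence` matrix.
#' @return A non-negative integer.
#' @export
br_discrepancy <- function(m) {
  p <- unclass(m)
  p <- p[, order(colSums(p), decreasing = TRUE), drop = FALSE]
  total <- 0L
  for (i in seq_len(nrow(p))) {
    r <- sum(p[i, ])
    if (r > 0) total <- total + r - sum(p[i, seq_len(r)])
  }
  total
}

# One draw from each null model. fixed-equiprobable redraws each species'
# presences into a uniform random subset of bands of the same row total.
null_draw <- function(p, null_model) {
  R <- nrow(p); C <- ncol(p)
  switch(null_model,
    "fixed-equiprobable" = {
      out <- matrix(0L, R, C)
      rs <- rowSums(p)
      for (i in seq_len(R)) if (rs[i] > 0) out[i, sample.int(C, rs[i])] <- 1L
      out
    },
    "equiprobable-equiprobable" = {
      out <- matrix(0L, R, C)
      out[sample.int(R * C, sum(p))] <- 1L
      out
    },
    stop("Unknown null model: ", null_model, call. = FALSE)
  )
}

#' Monte Carlo null-model test of a nestedness metric
#'
#' Compares the observed metric with its distribution over randomized
#' matrices. The default null model keeps row totals fixed (each species'
#' occurrence frequency) while columns are equiprobable, i.e. any band may
#' receive any species. `"fixed-fixed"` uses the SIM9 sequential-swap
#' chain instead. The p-value is one-tailed in the nested direction of the
#' metric (high NODF, low T, low BR), with the `+1` correction.
#'
#' @param m An `incidence` matrix.
#' @param metric One of `"NODF_total"`, `"NODF_rows"`, `"NODF_cols"`,
#'   `"T"`, `"BR"`.
#' @param null_model `"fixed-equiprobable"` (default), `"fixed-fixed"` or
#'   `"equiprobable-equiprobable"`.
#' @param n_iter Null matrices to draw (the study used 50,000).
#' @param seed Integer seed.
#' @return An object of class `nestedness_test`: `metric`, `observed`,
#'   `null_mean`, `null_ci95`, `p_value`, `n_iter`, `null_model`, `seed`,
#'   `null_values`.
#' @export
nestedness_null_test <- function(m, metric = c("NODF_total", "NODF_rows",
                                               "NODF_cols", "T", "BR"),
                                 null_model = c("fixed-equiprobable",
                                                "fixed-fixed",
                                                "equiprobable-equiprobable"),
                                 n_iter = 1000, seed = 1L) {
  metric <- match.arg(metric)
  null_model <- match.arg(null_model)
  if (n_iter < 100) warning("n_iter < 100 gives unstable p-values.",
                            call. = FALSE)
  p <- unclass(m)
  score <- switch(metric,
    NODF_total = function(x) nodf(as_incidence(x))$nodf_total,
    NODF_rows = function(x) nodf(as_incidence(x))$nodf_rows,
    NODF_cols = function(x) nodf(as_incidence(x))$nodf_cols,
    T = function(x) nestedness_temperature(as_incidence(x)),
    BR = function(x) br_discrepancy(as_incidence(x))
  )
  observed <- score(p)
  null_values <- if (null_model == "fixed-fixed") {
    sim9_chain(m, n_iter = n_iter, seed = seed, fun = function(x) score(x))
  } else {
    with_seed(seed, vapply(seq_len(n_iter),
                           function(i) score(null_draw(p, null_model)),
                           numeric(1)))
  }
  nested_low <- metric %in% c("T", "BR") # nested direction of the tail
  exceed <- if (nested_low) sum(null_values <= observed)
            else sum(null_values >= observed)
  structure(
    list(metric = metric, observed = observed,
         null_mean = mean(null_values),
         null_ci95 = stats::quantile(null_values, c(0.025, 0.975),
                                     names = FALSE),
         p_value = (1 + exceed) / (1 + length(null_values)),
         n_iter = length(null_values), null_model = null_model, seed = seed,
         null_values = null_values),
    class = "nestedness_test"
  )
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat(sprintf("Nestedness test: %s = %.4g (null %s, %d iterations)\n",
              x$metric, x$observed, x$null_model, x$n_iter))
  cat(sprintf("  null mean %.4g, 95%% CI (%.4g-%.4g), one-tailed p = %.4g\n",
              x$null_mean, x$null_ci95[1], x$null_ci95[2], x$p_value))
  invisible(x)
}

#' @method tidy nestedness_test
#' @export
tidy.nestedness_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, observed = x$observed, null_mean = x$null_mean,
    ci_lower = x$null_ci95[1], ci_upper = x$null_ci95[2],
    p_value = x$p_value, null_model = x$null_model, n_iter = x$n_iter
  )
}

#' @method glance nestedness_test
#' @export
glance.nestedness_test <- tidy.nestedness_test

#' @method autoplot nestedness_test
#' @export
autoplot.nestedness_test <- function(object, ...) {
  df <- tibble::tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$metric, y = "Null frequency",
                  title = sprintf("%s against the %s null", object$metric,
                                  object$null_model),
                  subtitle = sprintf("observed %.3f, p = %.4g",
                                     object$observed, object$p_value))
}
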