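#' C-score checkerboard index
#'
#' Mean over all unordered species pairs of the checkerboard units
#' `CU_ij = (r_i - S_ij)(r_j - S_ij)`, where `r` are row totals and
#' `S_ij` the number of shared sites. High values indicate segregation
#' (species co-occurring less than their totals allow), low values
#' aggregation.
#'
#' @param m An `incidence` matrix with at least 2 species.
#' @return The mean checkerboard unit (non-negative).
#' @examples
#' c_score(as_incidence(rbind(c(1, 0), c(0, 1)))) # perfect checkerboard: 1
#' @export
c_score <- function(m) {
  p <- unclass(m)
  if (nrow(p) < 2) stop("C-score needs at least 2 species.", call. = FALSE)
  r <- rowSums(p)
  shared <- tcrossprod(p)
  cu <- (r - shared) * t(r - t(shared)) # (r_i - S_ij)(r_j - S_ij)
  mean(cu[upper.tri(cu)])
}

#' SIM9 sequential-swap null chain
#'
#' Samples from the fixed-fixed ensemble (all binary matrices with the
#' observed row and column sums) by repeatedly drawing a random row pair
#' and column pair and, when the 2x2 submatrix is a checkerboard, swapping
#' its diagonal. Attempted swaps (including rejections) count toward
#' burn-in and thinning, giving a deterministic chain length. After
#' `burn_in` attempts, every `thin`-th state is recorded.
#'
#' @param m An `incidence` matrix.
#' @param n_iter Number of recorded null states.
#' @param burn_in Attempted swaps discarded before recording.
#' @param thin Attempted swaps between recorded states.
#' @param seed Integer seed.
#' @param fun Optional statistic computed on each recorded state; when
#'   supplied, a numeric vector of its values is returned instead of the
#'   (memory-hungry) list of matrices.
#' @return A list of binary matrices, or a numeric vector if `fun` is given.
#' @export
sim9_chain <- function(m, n_iter = 1000, burn_in = 30000, thin = 10,
                       seed = 1L, fun = NULL) {
  p <- unclass(m)
  R <- nrow(p); C <- ncol(p)
  if (R < 2 || C < 2) stop("SIM9 needs at least a 2x2 matrix.", call. = FALSE)
  if (!has_checkerboard(p)) {
    warning("Matrix has no swappable 2x2 checkerboard; the fixed-fixed ",
            "ensemble collapses to the observed matrix.", call. = FALSE)
  }
  keep_mat <- is.null(fun)
  out <- if (keep_mat) vector("list", n_iter) else numeric(n_iter)
  with_seed(seed, {
    total <- burn_in + n_iter * thin
    kept <- 0L
    for (a in seq_len(total)) {
      i <- sample.int(R, 2L)
      j <- sample.int(C, 2L)
      s <- p[i, j]
      if ((s[1L] + s[4L] == 2L && s[2L] + s[3L] == 0L) ||
          (s[1L] + s[4L] == 0L && s[2L] + s[3L] == 2L)) {
        p[i, j] <- s[c(3L, 4L, 1L, 2L)] # swap the diagonal
      }
      if (a > burn_in && (a - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        if (keep_mat) out[[kept]] <- p else out[kept] <- fun(p)
      }
    }
  })
  out
}

has_checkerboard <- function(p) {
  shared <- tcrossprod(p)
  r <- rowSums(p)
  # a pair with r_i > S and r_j > S has sites exclusive to each: checkerboard
  any((r - shared) * t(r - t(shared)) > 0 & upper.tri(shared))
}

#' C-score co-occurrence test against the SIM9 null
#'
#' Computes the C-score on each state of the SIM9 fixed-fixed chain and
#' summarises the ensemble as a standardized effect size
#' `SES = (observed - null mean) / null sd` with both tail probabilities
#' (`+1` correction). A significantly high C-score indicates segregation,
#' a significantly low one aggregation.
#'
#' @inheritParams sim9_chain
#' @return An object of class `cooccurrence_test`: `observed`, `null_mean`,
#'   `null_variance`, `ses`, `p_lower` (aggregation tail), `p_upper`
#'   (segregation tail), chain settings and `null_values`.
#' @export
cooccurrence_test <- function(m, n_iter = 1000, burn_in = 30000, thin = 10,
                              seed = 1L) {
  observed <- c_score(m)
  null_values <- sim9_chain(m, n_iter = n_iter, burn_in = burn_in,
                            thin = thin, seed = seed,
                            fun = function(x) {
                              r <- rowSums(x)
                              s <- tcrossprod(x)
                              cu <- (r - s) * t(r - t(s))
                              mean(cu[upper.tri(cu)])
                            })
  nv <- stats::var(null_values)
  structure(
    list(observed = observed, null_mean = mean(null_values),
         null_variance = nv,
         ses = if (nv > 0) (observed - mean(null_values)) / sqrt(nv)
               else NA_real_,
         p_lower = (1 + sum(null_values <= observed)) / (1 + length(null_values)),
         p_upper = (1 + sum(null_values >= observed)) / (1 + length(null_values)),
         n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
         null_values = null_values),
    class = "cooccurrence_test"
  )
}

#' @export
print.cooccurrence_test <- function(x, ...) {
  cat("C-score vs SIM9 fixed-fixed null\n")
  cat(sprintf("  observed %.4f, null mean %.4f (var %.3g), SES %.2f\n",
              x$observed, x$null_mean, x$null_variance, x$ses))
  cat(sprintf("  p(null >= obs) = %.4g [segregation], p(null <= obs) = %.4g [aggregation]\n",
              x$p_upper, x$p_lower))
  invisible(x)
}

#' @method tidy cooccurrence_test
#' @export
tidy.cooccurrence_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, null_mean = x$null_mean,
    null_variance = x$null_variance, ses = x$ses,
    p_upper = x$p_upper, p_lower = x$p_lower,
    n_iter = x$n_iter, burn_in = x$burn_in, thin = x$thin
  )
}

#' @method glance cooccurrence_test
#' @export
glance.cooccurrence_test <- tidy.cooccurrence_test

#' @method autoplot cooccurrence_test
#' @export
autoplot.cooccurrence_test <- function(object, ...) {
  df <- tibble::tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "C-score", y = "Null frequency",
                  title = "C-score against the SIM9 fixed-fixed null",
                  subtitle = sprintf("observed %.3f, SES %.2f",
                                     object$observed, object$ses))
}
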