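# Independent brute-force oracles used to verify the package's metrics.
# These deliberately use naive loops and first-principles definitions,
# not the package's vectorized code paths.

random_binary_matrix <- function(nr, nc, fill = 0.45, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# NODF by explicit pair loops on an already packed matrix.
oracle_nodf <- function(m) {
  p <- unclass(pack_matrix(as_incidence(m)))
  pair_sum <- function(x) {
    n <- nrow(x)
    f <- rowSums(x)
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (f[i] > f[j] && f[j] > 0) {
          tot <- tot + 100 * sum(x[i, ] == 1 & x[j, ] == 1) / f[j]
        }
      }
    }
    tot
  }
  sr <- unname(pair_sum(p)); sc <- unname(pair_sum(t(p)))
  nr <- choose(nrow(p), 2); nc <- choose(ncol(p), 2)
  list(total = (sr + sc) / (nr + nc), rows = sr / nr, cols = sc / nc)
}

# C-score by explicit double loop over species pairs.
oracle_cscore <- function(m) {
  n <- nrow(m)
  r <- rowSums(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sum(m[i, ] == 1 & m[j, ] == 1)
      tot <- tot + (r[i] - s) * (r[j] - s)
    }
  }
  tot / choose(n, 2)
}

# BR discrepancy by direct count of absences in each row's packed prefix.
oracle_br <- function(m) {
  p <- m[, order(colSums(m), decreasing = TRUE), drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(p))) {
    r <- sum(p[i, ])
    if (r > 0) tot <- tot + sum(p[i, seq_len(r)] == 0)
  }
  tot
}

# Matrix temperature U re-derived cell by cell with scalar arithmetic.
oracle_temperature <- function(m) {
  p <- unclass(pack_matrix(as_incidence(m)))
  R <- nrow(p); C <- ncol(p)
  fill <- mean(p)
  area <- function(pw) exp(2 * lgamma(1 + 1 / pw) - lgamma(1 + 2 / pw))
  pw <- exp(uniroot(function(lp) area(exp(lp)) - fill, c(log(0.02), log(80)),
                    tol = 1e-12)$root)
  u_tot <- 0
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      x0 <- (j - 0.5) / C
      y0 <- (i - 0.5) / R
      side <- x0^pw + y0^pw
      bad <- (p[i, j] == 1 && side > 1) || (p[i, j] == 0 && side < 1)
      if (bad) {
        c0 <- y0 - x0
        t_lo <- max(0, -c0); t_hi <- min(1, 1 - c0)
        t_iso <- uniroot(function(t) t^pw + (t + c0)^pw - 1, c(t_lo, t_hi),
                         tol = 1e-12)$root
        u_tot <- u_tot + ((x0 - t_iso) / (t_hi - t_lo))^2
      }
    }
  }
  min(100, 100 * u_tot / (0.04145 * R * C))
}

# All binary matrices with the given row and column sums (tiny cases only).
enumerate_fixed_fixed <- function(rs, cs) {
  R <- length(rs); C <- length(cs)
  grid <- expand.grid(rep(list(0:1), R * C))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    m <- matrix(as.integer(grid[i, ]), R, C)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      out[[length(out) + 1]] <- m
    }
  }
  out
}

# Expected per-band richness by exhaustive enumeration of all discrete
# placements (uniform product over species).
oracle_mde_expectation <- function(sizes, D) {
  expect <- numeric(D)
  for (b in sizes) {
    pos <- 0:(D - b)
    for (s in pos) {
      covered <- (s + 1):(s + b)
      expect[covered] <- expect[covered] + 1 / length(pos)
    }
  }
  expect
}

# Per-species contiguity of 1s in an incidence row.
is_contiguous_row <- function(v) {
  w <- which(v == 1)
  length(w) > 0 && all(diff(w) == 1)
}

# incidence matrix stripped to a bare unnamed-attribute integer matrix
strip_incidence <- function(m) {
  m <- unclass(m)
  attr(m, "domain") <- NULL
  m
}
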