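#' Jaccard similarity between latitudinal bands
#'
#' `J(a, b) = |A intersect B| / |A union B|` over the species sets of two
#' bands. Empty bands have no defined similarity with anything and are
#' dropped with a message.
#'
#' @param m An `incidence` matrix.
#' @return A symmetric band-by-band similarity matrix with unit diagonal,
#'   labelled by band, restricted to non-empty bands.
#' @export
jaccard_similarity <- function(m) {
  p <- unclass(m)
  empty <- colSums(p) == 0
  if (any(empty)) {
    message("Dropping ", sum(empty), " empty band(s): ",
            paste(colnames(p)[empty], collapse = ", "))
    p <- p[, !empty, drop = FALSE]
  }
  if (ncol(p) < 2) stop("Need at least 2 non-empty bands.", call. = FALSE)
  d <- vegan::vegdist(t(p), method = "jaccard", binary = TRUE)
  j <- 1 - as.matrix(d)
  diag(j) <- 1
  j
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Average-linkage agglomeration on the dissimilarity `1 - J`, giving an
#' ultrametric tree whose cophenetic heights are non-decreasing from
#' leaves to root.
#'
#' @param similarity A symmetric similarity matrix (e.g.
#'   [jaccard_similarity()]).
#' @return An [stats::hclust] object.
#' @export
upgma <- function(similarity) {
  if (nrow(similarity) < 2) stop("Need at least 2 items.", call. = FALSE)
  stats::hclust(stats::as.dist(1 - similarity), method = "average")
}

# Sorted pairwise Jaccard similarities of the bands of `p`, by direct set
# arithmetic (fast path for the permutation loop; agrees with vegdist).
# Two simultaneously empty bands are treated as identical (J = 1).
similarity_profile <- function(p) {
  inter <- crossprod(p)
  sz <- colSums(p)
  un <- outer(sz, sz, `+`) - inter
  j <- ifelse(un > 0, inter / un, 1)
  sort(j[upper.tri(j)])
}

#' SIMPROF test of internal structure for one group of bands
#'
#' Tests whether a set of bands shows more multivariate structure than
#' expected if each species' presences were arranged at random across the
#' bands. The observed profile is the sorted vector of pairwise Jaccard
#' similarities; the expected profile is its rank-wise mean over
#' `n_perm_mean` permutations in which every species' row is independently
#' shuffled across the bands; the statistic is
#' `pi = sum_k |s_obs(k) - s_null(k)|`, compared against `pi` values of
#' `n_perm_test` further permuted profiles (`+1` correction).
#'
#' @param m An `incidence` matrix restricted to the bands under test
#'   (at least 3 columns).
#' @param n_perm_mean Permutations used for the mean profile.
#' @param n_perm_test Permutations used for the null `pi` distribution.
#' @param seed Integer seed.
#' @return A list with `pi`, `p_value`, `n_perm_mean`, `n_perm_test`.
#' @export
simprof <- function(m, n_perm_mean = 200, n_perm_test = 199, seed = 1L) {
  p <- unclass(m)
  p <- p[rowSums(p) > 0, , drop = FALSE]
  if (ncol(p) < 3) stop("SIMPROF needs at least 3 bands.", call. = FALSE)
  obs <- similarity_profile(p)
  shuffle <- function(x) {
    t(apply(x, 1, sample))
  }
  with_seed(seed, {
    null_profiles <- vapply(seq_len(n_perm_mean),
                            function(i) similarity_profile(shuffle(p)),
                            numeric(length(obs)))
    mean_profile <- rowMeans(null_profiles)
    pi_obs <- sum(abs(obs - mean_profile))
    pi_null <- vapply(seq_len(n_perm_test), function(i) {
      sum(abs(similarity_profile(shuffle(p)) - mean_profile))
    }, numeric(1))
    list(pi = pi_obs,
         p_value = (1 + sum(pi_null >= pi_obs)) / (1 + n_perm_test),
         n_perm_mean = n_perm_mean, n_perm_test = n_perm_test)
  })
}

#' Jaccard-UPGMA clustering of bands with SIMPROF significance
#'
#' Clusters the (non-empty) latitudinal bands by Jaccard similarity with
#' UPGMA linkage, then walks the dendrogram from the root applying the
#' SIMPROF test at each internal node. Descent stops at nodes without
#' significant internal structure (homogeneous groups); the retained
#' partition is the set of maximal homogeneous subtrees.
#'
#' @param m An `incidence` matrix.
#' @param n_perm Total permutation budget per node, split 2:1 between the
#'   mean profile and the test distribution (the study used 50,000).
#' @param alpha Significance level for structure (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `band_clustering`: `hclust` (the tree),
#'   `nodes` (tibble of tested nodes: `node`, `n_bands`, `pi`, `p_value`,
#'   `significant`), `groups` (tibble `band` -> `group`), `alpha`, `seed`.
#' @export
cluster_bands <- function(m, n_perm = 999, alpha = 0.05, seed = 1L) {
  j <- jaccard_similarity(m)
  hc <- upgma(j)
  p <- unclass(m)[, colnames(j), drop = FALSE]
  n_mean <- ceiling(2 * n_perm / 3)
  n_test <- n_perm - n_mean
  seeds <- substream_seeds(seed, nrow(hc$merge))

  # leaves under each internal node of the hclust merge tree
  leaves_of <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves_of[[k]] <- unlist(lapply(kids, function(x) {
      if (x < 0) -x else leaves_of[[x]]
    }))
  }

  nodes <- list()
  groups <- rep(NA_integer_, ncol(p))
  next_group <- 0L
  assign_group <- function(leaf_idx) {
    next_group <<- next_group + 1L
    groups[leaf_idx] <<- next_group
  }
  visit <- function(k) { # k: internal node index; descend while significant
    if (k < 0) { # a leaf reached through significant splits: singleton
      assign_group(-k)
      return(invisible())
    }
    leaf_idx <- leaves_of[[k]]
    if (length(leaf_idx) < 3) { # too small to test: homogeneous
      assign_group(leaf_idx)
      return(invisible())
    }
    sp <- simprof(as_incidence(p[, leaf_idx, drop = FALSE]),
                  n_perm_mean = n_mean, n_perm_test = n_test,
                  seed = seeds[k])
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(
      node = k, n_bands = length(leaf_idx), pi = sp$pi, p_value = sp$p_value,
      significant = sp$p_value <= alpha
    )
    if (sp$p_value <= alpha) {
      visit(hc$merge[k, 1]); visit(hc$merge[k, 2])
    } else {
      assign_group(leaf_idx)
    }
  }
  visit(nrow(hc$merge))

  band_order <- as.integer(hc$labels)
  group_tbl <- tibble::tibble(band = band_order, group = groups) |>
    dplyr::arrange(.data$band)
  # renumber groups in band order for readability
  group_tbl$group <- match(group_tbl$group, unique(group_tbl$group))
  structure(
    list(hclust = hc, similarity = j,
         nodes = dplyr::bind_rows(nodes),
         groups = group_tbl, alpha = alpha, n_perm = n_perm, seed = seed),
    class = "band_clustering"
  )
}

#' Significant band groups from a SIMPROF-pruned dendrogram
#'
#' @param x A [cluster_bands()] result.
#' @return A tibble `band` -> `group` (groups numbered south-to-north by
#'   first band).
#' @export
significant_groups <- function(x) {
  stopifnot(inherits(x, "band_clustering"))
  x$groups
}

#' @export
print.band_clustering <- function(x, ...) {
  ng <- length(unique(x$groups$group))
  cat(sprintf("Jaccard-UPGMA clustering with SIMPROF (alpha = %g)\n", x$alpha))
  cat(sprintf("  %d bands, %d tested nodes, %d significant, %d groups\n",
              nrow(x$groups), nrow(x$nodes), sum(x$nodes$significant), ng))
  invisible(x)
}

#' @method tidy band_clustering
#' @export
tidy.band_clustering <- function(x, ...) x$groups

#' @method glance band_clustering
#' @export
glance.band_clustering <- function(x, ...) {
  tibble::tibble(n_bands = nrow(x$groups),
                 n_groups = length(unique(x$groups$group)),
                 n_nodes_tested = nrow(x$nodes),
                 n_significant = sum(x$nodes$significant),
                 alpha = x$alpha, n_perm = x$n_perm)
}

#' @method autoplot band_clustering
#' @export
autoplot.band_clustering <- function(object, ...) {
  hc <- object$hclust
  ord <- hc$order
  df <- tibble::tibble(
    x = seq_along(ord),
    band = hc$labels[ord],
    group = factor(object$groups$group[match(hc$labels[ord],
                                             object$groups$band)])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, 0, colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$band), vjust = -1.2,
                       size = 3, colour = "black") +
    ggplot2::labs(x = "Dendrogram order", y = NULL, colour = "Group",
                  title = "SIMPROF-significant band groups") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Export a band dendrogram as Newick
#'
#' Branch lengths are cophenetic heights. Requires the ape package.
#'
#' @param x A [cluster_bands()] result or an `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(x, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export needs the ape package.", call. = FALSE)
  }
  hc <- if (inherits(x, "band_clustering")) x$hclust else x
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
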