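# Ancestry coordinates: IBS distance, classical MDS, sub-populations --------

#' Pairwise identity-by-state genetic distance
#'
#' Distance between two samples is one minus the mean shared-allele
#' proportion over SNPs non-missing in both: sharing is 1 for identical
#' genotypes, 1/2 for genotypes one allele apart, 0 for opposite
#' homozygotes.
#'
#' @param geno A [geno_matrix()] (diploid).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
ibs_distance <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$values
  n <- nrow(x)
  if (n < 2) stop_dyad("need at least 2 samples", "dim")
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0L
  x0 <- matrix(as.numeric(x0), n)
  obs_n <- matrix(as.numeric(obs), n)
  # sum over shared SNPs of |xi - xj| via crossprods:
  # |d| = d^2 - 2*[one sample 0, other 2]
  cross <- tcrossprod(x0)
  s2 <- x0^2
  # per-pair sums restricted to jointly observed SNPs
  sum_sq_i <- tcrossprod(s2, obs_n)      # sum_i x_i^2 over SNPs obs in j
  sum_sq_j <- t(sum_sq_i)
  d2 <- sum_sq_i + sum_sq_j - 2 * cross
  i0 <- matrix(as.numeric(obs & x == 0L), n)
  i2 <- matrix(as.numeric(obs & x == 2L), n)
  opp <- tcrossprod(i0, i2)
  abs_d <- d2 - 2 * (opp + t(opp))
  m_pair <- tcrossprod(obs_n)
  if (any(m_pair[upper.tri(m_pair)] == 0)) {
    stop_dyad("a sample pair shares no non-missing SNPs", "overlap")
  }
  dist <- abs_d / (2 * m_pair)
  dist[dist < 0] <- 0
  diag(dist) <- 0
  dimnames(dist) <- list(geno$samples$sample_id, geno$samples$sample_id)
  dist
}

#' Classical multidimensional scaling of a genetic distance matrix
#'
#' Double-centered Gram eigendecomposition (via [stats::cmdscale()]);
#' returns the top-`k` principal coordinates with a deterministic sign
#' convention (the largest-magnitude loading of each axis is positive).
#' The captured-variance fraction is the sum of the top-`k` positive
#' eigenvalues over the sum of all positive eigenvalues.
#'
#' @param dist Symmetric distance matrix.
#' @param k Number of coordinates (default 10); must be `< n`.
#' @return List of class `pcoords`: `points` (n x k), `eig`, `var_frac`
#'   (cumulative per-axis fractions), `captured` (total for k axes).
#' @export
classical_mds <- function(dist, k = 10) {
  n <- nrow(dist)
  if (k >= n) stop_dyad("k must be smaller than the number of samples", "dim")
  mds <- cmdscale(as.dist(dist), k = k, eig = TRUE)
  pts <- mds$points
  # sign convention: largest |loading| per axis is positive
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("C", seq_len(ncol(pts)))
  pos <- mds$eig[mds$eig > 0]
  var_frac <- pos[seq_len(min(k, length(pos)))] / sum(pos)
  structure(
    list(points = pts, eig = mds$eig, var_frac = var_frac,
         captured = sum(var_frac)),
    class = "pcoords"
  )
}

#' @export
print.pcoords <- function(x, ...) {
  cat(sprintf("<pcoords> %d samples x %d axes, %.1f%% variance captured\n",
              nrow(x$points), ncol(x$points), 100 * x$captured))
  invisible(x)
}

#' Tidy principal coordinates into a tibble
#'
#' @param x A `pcoords` object.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per coordinate axis.
#' @export
tidy.pcoords <- function(x, ...) {
  out <- as_tibble(x$points)
  out$sample_id <- rownames(x$points) %||% as.character(seq_len(nrow(x$points)))
  dplyr::relocate(out, "sample_id")
}

#' Assign samples to sub-populations by k-means on MDS coordinates
#'
#' Operationalizes "homogeneous sub-populations" as k-means clusters of the
#' principal coordinates, with a fixed seed for determinism and bounded
#' re-seeding if a cluster comes back empty.
#'
#' @param pcs A `pcoords` object (or bare coordinate matrix).
#' @param n_groups Number of sub-populations (default 4).
#' @param seed Integer seed.
#' @param max_retry Re-seed attempts on an empty cluster.
#' @return Integer vector of group labels (1..n_groups).
#' @export
assign_subpopulations <- function(pcs, n_groups = 4, seed = 1L,
                                  max_retry = 5L) {
  pts <- if (inherits(pcs, "pcoords")) pcs$points else as.matrix(pcs)
  if (n_groups < 1) stop_dyad("n_groups must be >= 1", "config")
  if (n_groups == 1) return(rep(1L, nrow(pts)))
  for (attempt in seq_len(max_retry)) {
    km <- with_seed(seed + attempt - 1L, {
      kmeans(pts, centers = n_groups, nstart = 10, iter.max = 50)
    })
    if (all(tabulate(km$cluster, n_groups) > 0)) return(km$cluster)
  }
  stop_dyad("k-means produced an empty cluster in every retry", "cluster")
}

#' Plot principal coordinates
#'
#' @param object A `pcoords` object.
#' @param groups Optional vector of group labels for colouring.
#' @param axes Which two axes to plot (default first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoords <- function(object, groups = NULL, axes = c(1, 2), ...) {
  df <- tidy(object)
  ax <- paste0("C", axes)
  df$group <- if (is.null(groups)) "all" else factor(groups)
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], 100 * object$var_frac[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], 100 * object$var_frac[axes[2]]),
      colour = "group"
    ) +
    ggplot2::theme_minimal()
}
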