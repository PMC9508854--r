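#' Optimal-superposition RMSD between two configurations
#'
#' Root mean squared distance over nucleosome centers after optimal rigid
#' superposition (Kabsch: centroid removal plus the SVD rotation with the
#' standard determinant correction against improper rotations).  Symmetric
#' and zero for rigid-motion copies; note that superposition RMSD does not
#' satisfy the triangle inequality in general.
#'
#' @param a,b `chromatin_config`s with matching chain counts and lengths.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b) {
  A <- do.call(rbind, lapply(a$chains, `[[`, "centers"))
  B <- do.call(rbind, lapply(b$chains, `[[`, "centers"))
  if (!identical(dim(A), dim(B)) ||
      n_chains(a) != n_chains(b))
    stop("configurations must have the same chain count and lengths")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param configs list of `chromatin_config`s.
#' @return symmetric matrix of RMSDs, nm.
#' @export
rmsd_matrix <- function(configs) {
  n <- length(configs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- rmsd(configs[[i]], configs[[j]])
  D
}

#' Single-linkage clustering at a distance cutoff
#'
#' Clusters are the connected components of the graph whose edges join pairs
#' with distance strictly below `cutoff` — equivalent to cutting the
#' single-linkage dendrogram at that height.  Implemented by union-find so
#' the strict-`<` cutoff semantics are exact.
#'
#' @param dist_matrix symmetric distance matrix.
#' @param cutoff merge distance, nm.
#' @return an object of class `cluster_result`: `labels` (cluster id per
#'   configuration, 1 = largest cluster), `sizes` (per cluster id), and
#'   `n_clusters`.
#' @export
single_linkage <- function(dist_matrix, cutoff) {
  n <- nrow(dist_matrix)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(max(n - 1, 0)))
    for (j in (i + 1):n)
      if (dist_matrix[i, j] < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  roots <- vapply(seq_len(n), find, integer(1))
  # relabel by decreasing cluster size, ties by first occurrence
  tab <- table(roots)
  ord <- order(-as.integer(tab), match(names(tab), as.character(roots)))
  relab <- setNames(seq_along(ord), names(tab)[ord])
  labels <- as.integer(relab[as.character(roots)])
  structure(list(labels = labels,
                 sizes = as.integer(table(labels)),
                 n_clusters = length(tab)),
            class = "cluster_result")
}

#' Medoid (central configuration) of one cluster
#'
#' The cluster member minimizing the summed RMSD to all other members; ties
#' are broken by the lowest trajectory index.
#'
#' @param configs the clustered ensemble (list of `chromatin_config`s).
#' @param result a [single_linkage()] `cluster_result`.
#' @param cluster_id cluster label.
#' @param dist_matrix optional precomputed [rmsd_matrix()] of `configs`.
#' @return list with `config` (the medoid) and `index` (its position in
#'   `configs`).
#' @export
representative <- function(configs, result, cluster_id, dist_matrix = NULL) {
  members <- which(result$labels == cluster_id)
  if (!length(members)) stop("no members in cluster ", cluster_id)
  if (length(members) == 1)
    return(list(config = configs[[members]], index = members))
  if (is.null(dist_matrix)) dist_matrix <- rmsd_matrix(configs)
  sums <- rowSums(dist_matrix[members, members, drop = FALSE])
  idx <- members[which.min(sums)]   # which.min takes the first minimum: lowest index
  list(config = configs[[idx]], index = idx)
}

#' Representative structures near a target extension
#'
#' Filters the ensemble to configurations whose per-nucleosome end-to-end
#' distance lies within `tolerance` of `target_ee`, single-linkage clusters
#' the remainder under RMSD, and returns the medoids of the most populated
#' clusters — the protocol for extracting force-dependent representative
#' structures.
#'
#' @param configs list of `chromatin_config`s.
#' @param target_ee target per-nucleosome end-to-end distance, nm.
#' @param tolerance half-width of the extension filter, nm (`Inf` keeps
#'   everything).
#' @param cutoff single-linkage RMSD cutoff, nm.
#' @param n_rep number of representatives (largest clusters first).
#' @return list of `list(config, index, cluster_size)`; empty (with a
#'   warning) when no configuration passes the filter.
#' @export
select_representatives <- function(configs, target_ee, tolerance = 0.5,
                                   cutoff = 3, n_rep = 1) {
  ee <- vapply(configs, function(cfg)
    mean(vapply(seq_len(n_chains(cfg)), function(ci) ee_per_nuc(cfg, ci),
                numeric(1))), numeric(1))
  keep <- which(abs(ee - target_ee) <= tolerance)
  if (!length(keep)) {
    warning("no configurations within tolerance of the target extension")
    return(list())
  }
  sub <- configs[keep]
  D <- rmsd_matrix(sub)
  cl <- single_linkage(D, cutoff)
  ids <- seq_len(min(n_rep, cl$n_clusters))
  lapply(ids, function(id) {
    rep <- representative(sub, cl, id, D)
    list(config = rep$config, index = keep[rep$index],
         cluster_size = cl$sizes[id])
  })
}
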