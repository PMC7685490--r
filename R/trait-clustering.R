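#' Gower dissimilarity matrix for categorical traits
#'
#' Pairwise Gower distance over categorical trait columns: the fraction of
#' mutually observed traits on which two species differ. Missing trait
#' values are excluded pairwise (the denominator renormalizes to the traits
#' observed for both species). Computed with `cluster::daisy`, the standard
#' implementation for mixed/categorical data.
#'
#' @param traits data frame of factor columns, species as rownames; missing
#'   values allowed as long as every pair shares at least one observed
#'   trait.
#' @return symmetric matrix of distances in \[0, 1\] with zero diagonal.
#' @export
gower_matrix <- function(traits) {
  stopifnot(nrow(traits) >= 2L, ncol(traits) >= 1L)
  ids <- rownames(traits)
  traits <- as.data.frame(lapply(traits, as.factor))
  rownames(traits) <- ids
  d <- as.matrix(cluster::daisy(traits, metric = "gower"))
  rownames(d) <- colnames(d) <- ids
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pairs <- apply(bad, 1, function(ij)
      paste(rownames(d)[ij[1]], rownames(d)[ij[2]], sep = "/"))
    stop("species pair(s) with no shared observed trait: ",
         paste(pairs, collapse = ", "))
  }
  d
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering (`stats::hclust`) with average (default),
#' complete or single linkage. Height inversions - possible for some
#' linkages on non-ultrametric inputs - trigger a warning, not an error.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [gower_matrix()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an `hclust` object (merge list with heights).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  if (any(diff(hc$height) < -1e-10))
    warning("merge heights are not monotone under ", linkage, " linkage")
  hc
}

#' Cut a dendrogram where between-cluster dissimilarity is maximized
#'
#' Chooses the number of clusters k (within `k_range`) that maximizes the
#' gap between consecutive merge heights - i.e. cuts the tree across its
#' longest stem. Ties go to the smaller k. If all candidate gaps are equal
#' (degenerate, e.g. all pairwise distances identical) the lower bound of
#' `k_range` is returned with a warning.
#'
#' @param hc an `hclust` object.
#' @param k_range integer vector `c(k_min, k_max)`, within `[2, n - 1]`.
#' @return list with `k` (chosen number of clusters), `labels` (integer
#'   vector, contiguous 1..k in order of first appearance), and `gap` (the
#'   maximized height gap).
#' @export
cut_max_separation <- function(hc, k_range = c(2L, max(2L, length(hc$order) - 1L))) {
  n <- length(hc$order)
  k_min <- max(2L, k_range[1]); k_max <- min(n - 1L, k_range[2])
  if (k_min > k_max) stop("k_range must intersect [2, n - 1]")
  h <- hc$height
  # cutting into k clusters removes the top k - 1 merges; the gap for k is
  # the height jump crossed by that cut
  ks <- k_min:k_max
  gaps <- h[n - ks + 1L] - h[n - ks]
  if (length(ks) > 1L && diff(range(gaps)) < 1e-12) {
    warning("all merge-height gaps equal; returning k_min = ", k_min)
    k <- k_min
  } else {
    k <- ks[which.max(gaps)]  # which.max takes the first (smallest k) on ties
  }
  raw <- stats::cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  list(k = k, labels = stats::setNames(labels, names(raw)), gap = max(gaps))
}

#' Per-cluster trait profiles
#'
#' Summarizes a clustering for focal-species selection: cluster sizes, the
#' modal level of each trait within each cluster, and the mean within-
#' cluster Gower distance.
#'
#' @param labels integer cluster labels (named by species).
#' @param traits the trait table the clustering was built from.
#' @return data frame, one row per cluster: `cluster`, `size`,
#'   `mean_within_gower`, then one modal-level column per trait.
#' @export
cluster_summary <- function(labels, traits) {
  stopifnot(length(labels) == nrow(traits))
  d <- gower_matrix(traits)
  rows <- lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    modes <- vapply(traits[idx, , drop = FALSE], function(col) {
      tab <- table(col[!is.na(col)])
      if (length(tab) == 0L) NA_character_ else names(tab)[which.max(tab)]
    }, character(1))
    within <- if (length(idx) > 1L)
      mean(d[idx, idx][lower.tri(d[idx, idx])]) else 0
    cbind(data.frame(cluster = cl, size = length(idx),
                     mean_within_gower = within),
          as.data.frame(as.list(modes), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trait-based species clustering, end to end
#'
#' Convenience wrapper running [gower_matrix()], [hierarchical_cluster()]
#' and [cut_max_separation()] and attaching the [cluster_summary()].
#'
#' @inheritParams gower_matrix
#' @inheritParams hierarchical_cluster
#' @inheritParams cut_max_separation
#' @return a `trait_clustering` object with elements `dist`, `hclust`, `k`,
#'   `labels`, `summary`.
#' @export
trait_cluster <- function(traits, linkage = "average",
                          k_range = c(2L, max(2L, nrow(traits) - 1L))) {
  d <- gower_matrix(traits)
  hc <- hierarchical_cluster(d, linkage)
  cut <- cut_max_separation(hc, k_range)
  structure(list(dist = d, hclust = hc, k = cut$k, labels = cut$labels,
                 summary = cluster_summary(cut$labels, traits)),
            class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat(sprintf("Trait clustering: %d species in %d clusters (%s linkage)\n",
              length(x$labels), x$k, x$hclust$method))
  print(x$summary[, c("cluster", "size", "mean_within_gower")])
  invisible(x)
}
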