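#' Uncentered correlation distance
#'
#' The cosine-type dissimilarity used for expression clustering:
#' `d = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, i.e. one minus the
#' correlation computed without mean-centering. Ranges over `[0, 2]`: 0 for
#' parallel, 1 for orthogonal, 2 for antiparallel profiles.
#'
#' @param x,y Numeric vectors of equal length, not all-zero.
#' @return Distance in `[0, 2]`.
#' @export
#' @examples
#' uncentered_corr_distance(c(1, 0), c(0, 1))  # 1
uncentered_corr_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("vectors must have equal length >= 1", call. = FALSE)
  }
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero-norm vector: distance undefined",
                               call. = FALSE)
  d <- 1 - sum(x * y) / sqrt(nx * ny)
  min(max(d, 0), 2)   # guard rounding just outside [0, 2]
}

#' Pairwise uncentered-correlation distances between matrix columns
#'
#' @param m Numeric matrix; distances are between columns (samples).
#' @return A `dist` object.
#' @export
uncentered_corr_dist <- function(m) {
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) stop("zero-norm sample column", call. = FALSE)
  sim <- crossprod(m) / tcrossprod(norms)
  d <- 1 - sim
  d[d < 0] <- 0
  d[d > 2] <- 2
  stats::as.dist(d)
}

#' Complete-linkage agglomerative clustering of samples
#'
#' Agglomerates samples under the uncentered-correlation distance with
#' complete linkage (inter-cluster distance = maximum pairwise distance).
#' The agglomeration is computed explicitly: at each step the pair of
#' active clusters at minimal distance is merged, with exact ties broken by
#' the smallest pair of cluster indices (clusters indexed by creation
#' order, singletons first in sample order), so the merge sequence is fully
#' deterministic. Complete linkage guarantees non-decreasing merge heights.
#'
#' @param x An `integrated_matrix`, or a numeric matrix whose columns are
#'   samples, or a precomputed `dist` object.
#' @return A standard `hclust` object (usable with [stats::cutree()],
#'   `plot()`, and [ape::as.phylo()]).
#' @export
cluster_complete <- function(x) {
  if (inherits(x, "integrated_matrix")) {
    labels <- colnames(x$values)
    d <- uncentered_corr_dist(x$values)
  } else if (inherits(x, "dist")) {
    labels <- attr(x, "Labels")
    d <- x
  } else {
    x <- as.matrix(x)
    labels <- colnames(x)
    d <- uncentered_corr_dist(x)
  }
  n <- attr(d, "Size")
  if (is.null(n)) n <- as.integer((1 + sqrt(1 + 8 * length(d))) / 2)
  if (n < 2L) stop("clustering needs >= 2 samples", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  dm <- as.matrix(d)
  diag(dm) <- Inf
  # cluster bookkeeping in hclust encoding: negative = singleton leaf,
  # positive = merge step that created the cluster
  active <- seq_len(n)
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    sub <- dm[active, active, drop = FALSE]
    best <- min(sub)
    # smallest (i, j) pair among ties, i < j in creation order
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- active[hit[1, 1]]; j <- active[hit[1, 2]]

    merge[s, ] <- sort(c(code[i], code[j]))
    height[s] <- best
    # complete linkage update: new cluster lives in slot i
    newd <- pmax(dm[i, ], dm[j, ])
    dm[i, ] <- newd; dm[, i] <- newd
    dm[i, i] <- Inf
    active <- setdiff(active, j)
    code[i] <- s
  }

  order_leaves <- function(step) {
    unlist(lapply(merge[step, ], function(k)
      if (k < 0) -k else order_leaves(k)))
  }
  structure(list(merge = merge, height = height,
                 order = order_leaves(n - 1L),
                 labels = labels, method = "complete",
                 dist.method = "uncentered_correlation",
                 call = match.call()),
            class = "hclust")
}

#' Cut a tree into k clusters and test co-membership of query samples
#'
#' Cuts the dendrogram at the `k - 1` highest merges into `k` flat clusters
#' and reports whether all query samples fall in one cluster — the
#' quantitative form of "these samples cluster together" read off a figure.
#'
#' @param tree An `hclust` object.
#' @param k Number of flat clusters, `1 <= k <=` number of samples.
#' @param query Character vector of sample labels to test (default none).
#' @return List with `labels` (named integer cluster memberships) and
#'   `co_clustered` (logical; `TRUE` when all query samples share one
#'   cluster).
#' @export
co_cluster <- function(tree, k, query = character()) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must lie in [1, n samples]", call. = FALSE)
  labels <- stats::cutree(tree, k = k)
  unknown <- setdiff(query, names(labels))
  if (length(unknown)) {
    stop("unknown query samples: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  co <- length(query) == 0L || length(unique(labels[query])) == 1L
  list(labels = labels, co_clustered = co)
}
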