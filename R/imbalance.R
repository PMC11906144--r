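#' k-means++ center initialization
#'
#' The first center is drawn uniformly; each subsequent center is drawn
#' with probability proportional to the squared Euclidean distance to
#' the nearest already-chosen center.
#'
#' @param x numeric matrix (rows are samples).
#' @param k number of centers.
#' @param seed integer seed; fixes the draw.
#' @return integer vector of k row indices of `x`.
#' @export
kmeansppCenters <- function(x, k, seed) {
  stopifnot(k >= 1, k <= nrow(x))
  rng <- local({ set.seed(seed); function(n, prob = NULL)
    sample.int(n, 1L, prob = prob) })
  centers <- integer(k)
  centers[1] <- rng(nrow(x))
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], nrow(x), ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) centers[j] <- rng(nrow(x))
      else centers[j] <- rng(nrow(x), prob = d2)
      d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], nrow(x), ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Clustering undersampling of the majority class
#'
#' Rebalances a two-class dataset by k-means++ clustering of the
#' majority class into `k = n_minority` clusters (on standardized
#' features) and keeping, from each cluster, the one real sample nearest
#' its centroid; the minority class is kept in full, so the output is
#' exactly balanced. No synthetic points are created.
#'
#' @param features a [FeatureBlock-class] or numeric matrix whose rows
#'   align with `labels`.
#' @param labels vector with exactly two classes present.
#' @param seed integer seed; identical seeds reproduce identical
#'   selections.
#' @return an [UndersampleResult-class]; `keptIndices(x)` indexes the
#'   original rows (minority plus selected majority, ascending).
#' @export
clusterUndersample <- function(features, labels, seed = 1L) {
  x <- if (is(features, "FeatureBlock")) featureMatrix(features) else features
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2L)
    stop("labels must contain exactly two classes (got ",
         length(tab), ")")
  minorityClass <- names(tab)[which.min(tab)]
  majIdx <- which(labels != minorityClass)
  minIdx <- which(labels == minorityClass)
  k <- length(minIdx)

  if (k >= length(majIdx)) {
    warning("minority class is not smaller than majority; nothing to reduce")
    return(new("UndersampleResult",
               keptIndices = sort(c(majIdx, minIdx)),
               nMajorityBefore = length(majIdx),
               nMajorityAfter = length(majIdx),
               clusterAssignments = seq_along(majIdx)))
  }

  xm <- x[majIdx, , drop = FALSE]
  # standardize (constant columns dropped: zero variance carries no
  # distance information and breaks scaling)
  mu <- colMeans(xm); sdv <- apply(xm, 2, stats::sd)
  keepCol <- sdv > 0
  xs <- sweep(sweep(xm[, keepCol, drop = FALSE], 2, mu[keepCol]), 2,
              sdv[keepCol], "/")
  if (!ncol(xs)) xs <- matrix(0, nrow(xm), 1L)

  init <- kmeansppCenters(xs, k, seed = seed)
  km <- tryCatch(local({
    set.seed(deriveSeed(seed, "lloyd"))
    suppressWarnings(stats::kmeans(xs, centers = xs[init, , drop = FALSE],
                                   iter.max = 50L, algorithm = "Lloyd"))
  }), error = function(e) {
    # a Lloyd iteration emptied a cluster; fall back to a single
    # nearest-initial-center assignment (each center is a real sample,
    # so every cluster keeps at least its own seed point)
    d <- outer(rowSums(xs^2), rowSums(xs[init, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xs, xs[init, , drop = FALSE])
    cl <- max.col(-d, ties.method = "first")
    centers <- do.call(rbind, lapply(seq_len(k), function(c2)
      colMeans(xs[cl == c2, , drop = FALSE])))
    list(cluster = cl, centers = centers)
  })
  assign <- km$cluster
  kept <- vapply(seq_len(k), function(cl) {
    members <- which(assign == cl)
    d2 <- rowSums((xs[members, , drop = FALSE] -
                   matrix(km$centers[cl, ], length(members), ncol(xs),
                          byrow = TRUE))^2)
    members[which.min(d2)]   # which.min: ties -> smallest original index
  }, integer(1))
  new("UndersampleResult",
      keptIndices = sort(c(majIdx[kept], minIdx)),
      nMajorityBefore = length(majIdx),
      nMajorityAfter = length(kept),
      clusterAssignments = assign)
}
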