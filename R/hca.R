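#' Agglomerative clustering with Ward's criterion
#'
#' Lance-Williams agglomeration on squared Euclidean distances with the
#' Ward update
#' d2(ij,k) = ((n_i+n_k) d2_ik + (n_j+n_k) d2_jk - n_k d2_ij) / (n_i+n_j+n_k).
#' Merge heights are reported on the distance scale (sqrt of the merged
#' squared distance), matching the usual "ward.D2" convention; Ward is
#' reducible so heights are non-decreasing. Ties are broken by the smallest
#' pair indices, so the result is invariant to duplicated-distance order.
#'
#' @param data numeric matrix/data.frame, observations x variables; row
#'   names (or `labels`) identify observations and must be unique.
#' @param standardize z-score columns first (default `TRUE`).
#' @param labels optional observation labels.
#' @return list of class `hca_result`: `merge` (hclust-style signed merge
#'   matrix), `height`, `labels`, `n`.
#' @export
hca_ward <- function(data, standardize = TRUE, labels = NULL) {
  X <- as.matrix(data)
  stopifnot(is.numeric(X), nrow(X) >= 2)
  if (anyNA(X)) stop("missing values not allowed")
  labels <- labels %||% rownames(X) %||% sprintf("O%d", seq_len(nrow(X)))
  if (anyDuplicated(labels)) stop("duplicate observation ids")
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, colMeans(X)), 2, ifelse(s > 0, s, 1), "/")
  }
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  size <- rep(1, n)
  # id: positive = merge row, negative = singleton (hclust convention)
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[act > i]
      dij <- d2[i, js]
      jmin <- which.min(dij)
      if (dij[jmin] < bd - 1e-12) { bd <- dij[jmin]; best <- c(i, js[jmin]) }
    }
    i <- best[1]; j <- best[2]
    height[step] <- sqrt(bd)
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) rev(pair) else pair
    # Lance-Williams Ward update into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * bd) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "hca_result")
}

#' Cut a Ward clustering into k groups
#'
#' @param hca an [hca_result][hca_ward()].
#' @param k number of clusters (1..n).
#' @return named integer vector of cluster assignments (1..k, numbered by
#'   first appearance).
#' @export
cut_clusters <- function(hca, k) {
  stopifnot(inherits(hca, "hca_result"), k >= 1, k <= hca$n)
  n <- hca$n
  grp <- seq_len(n)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    side <- function(code) if (code < 0) -code else members[[code]]
    members[[step]] <- c(side(hca$merge[step, 1]), side(hca$merge[step, 2]))
    if (step <= n - k)
      grp[members[[step]]] <- min(grp[members[[step]]])
  }
  # relabel 1..k by first appearance
  out <- match(grp, unique(grp))
  names(out) <- hca$labels
  out
}

#' Convert to a base hclust object
#'
#' Allows plotting with [stats::plot.hclust()] / [stats::cutree()].
#'
#' @param hca an [hca_result][hca_ward()].
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(hca) {
  stopifnot(inherits(hca, "hca_result"))
  ord <- integer(0)
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(hca$merge[code, 1]), expand(hca$merge[code, 2]))
  }
  ord <- expand(nrow(hca$merge))
  structure(list(merge = hca$merge, height = hca$height, order = ord,
                 labels = hca$labels, method = "ward.D2",
                 dist.method = "euclidean", call = match.call()),
            class = "hclust")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("Ward hierarchical clustering of %d observations (%d merges)\n",
              x$n, length(x$height)))
  invisible(x)
}
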