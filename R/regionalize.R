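#' Per-cell species-change matrix
#'
#' Rows are cells carrying a community in both scenarios, columns are species,
#' entries are the change in relative biomass share (future - current). All
#' columns share units (proportions), so rows are clustered raw, without
#' standardization.
#'
#' @param shares_current,shares_future named lists of share matrices over the
#'   same pool and grid.
#' @return list: `X` (cells x species matrix), `cells` (linear indices of the
#'   retained cells), `dim` (grid dimensions).
#' @export
build_change_matrix <- function(shares_current, shares_future) {
  sp <- names(shares_current)
  if (!identical(sp, names(shares_future))) stop("pools differ between scenarios")
  d <- dim(shares_current[[1L]])
  if (!identical(d, dim(shares_future[[1L]]))) stop("grid dimensions differ")
  cur <- sapply(shares_current, as.vector)
  fut <- sapply(shares_future, as.vector)
  D <- fut - cur
  keep <- which(rowSums(!is.finite(D)) == 0)
  list(X = D[keep, , drop = FALSE], cells = keep, dim = d)
}

kmpp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (K > 1L) {
    d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = prob)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# squared distances of every row of X to every center row
dist2_to_centers <- function(X, centers) {
  xs <- rowSums(X^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * X %*% t(centers)
}

lloyd <- function(X, centers, tol, max_iter) {
  K <- nrow(centers)
  sse_prev <- Inf
  reassigned <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    sse <- sum(d2[cbind(seq_len(nrow(X)), labels)])
    # Lloyd monotonicity; suspended right after an empty-cluster repair
    if (!reassigned) stopifnot(sse <= sse_prev + 1e-8 * max(1, sse_prev))
    reassigned <- FALSE
    counts <- tabulate(labels, K)
    # empty cluster: seize the point farthest from the largest cluster's center
    while (any(counts == 0L)) {
      empty <- which(counts == 0L)[1L]
      big <- which.max(counts)
      members <- which(labels == big)
      far <- members[which.max(d2[cbind(members, rep(big, length(members)))])]
      labels[far] <- empty
      counts <- tabulate(labels, K)
      reassigned <- TRUE
    }
    new_centers <- t(vapply(seq_len(K),
                            function(k) colMeans(X[labels == k, , drop = FALSE]),
                            numeric(ncol(X))))
    if (is.finite(sse_prev) &&
        (sse_prev - sse) <= tol * max(sse_prev, .Machine$double.eps)) {
      centers <- new_centers
      break
    }
    centers <- new_centers
    sse_prev <- sse
  }
  d2 <- dist2_to_centers(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  list(labels = labels, centers = centers, sse = sse, iterations = it)
}

#' K-means clustering of species-change vectors into regions
#'
#' Lloyd's algorithm with k-means++ seeding and `n_init` restarts, keeping the
#' lowest within-cluster sum of squared errors (SSE). SSE is non-increasing
#' across Lloyd iterations within a run (asserted in-loop); the result is
#' deterministic given the seed. Labels are renumbered 1..K by descending
#' cluster size ([relabel_by_size()]).
#'
#' @param X numeric matrix (cells x species), e.g. from
#'   [build_change_matrix()].
#' @param K number of regions (the headline analysis uses 5); must not exceed
#'   the number of distinct rows.
#' @param n_init restarts; best SSE kept.
#' @param tol relative SSE-change convergence tolerance.
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed integer seed.
#' @return `region_partition`: `labels` (per row of `X`), `centers` (K x
#'   species), `sse`, `iterations`, `seed`.
#' @export
kmeans_regions <- function(X, K = 5L, n_init = 10L, tol = 1e-6,
                           max_iter = 300L, seed = 1) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (K < 1) stop("K must be >= 1")
  if (K > n_distinct) stop("K exceeds the number of distinct rows (", n_distinct, ")")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(X, kmpp_init(X, K), tol, max_iter)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  part <- structure(
    list(labels = best$labels, centers = best$centers, sse = best$sse,
         iterations = best$iterations, seed = seed),
    class = "region_partition"
  )
  relabel_by_size(part)
}

#' Renumber region labels by descending cluster size
#'
#' Stable region numbering: label 1 is the largest region. Ties in size are
#' broken by lexicographic order of the centroid coordinates.
#'
#' @param partition a `region_partition`.
#' @return the partition with labels and centers permuted accordingly.
#' @export
relabel_by_size <- function(partition) {
  K <- nrow(partition$centers)
  counts <- tabulate(partition$labels, K)
  ord <- do.call(order, c(list(-counts),
                          lapply(seq_len(ncol(partition$centers)),
                                 function(j) partition$centers[, j])))
  perm <- integer(K); perm[ord] <- seq_len(K)
  partition$labels <- perm[partition$labels]
  partition$centers <- partition$centers[ord, , drop = FALSE]
  partition
}

#' Paint a region partition back onto the grid
#'
#' @param partition a `region_partition`.
#' @param change a [build_change_matrix()] result supplying `cells` and `dim`.
#' @return integer matrix of region labels (NA off the community mask).
#' @export
region_grid <- function(partition, change) {
  m <- matrix(NA_integer_, change$dim[1L], change$dim[2L])
  m[change$cells] <- partition$labels
  m
}
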