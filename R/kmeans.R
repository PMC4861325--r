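# K-Means segmentation baseline on the same unnormalized pixel matrix given
# to NMF, with seeded k-means++ initialization, Lloyd iterations, an inertia
# trace (monotone non-increasing) and best-of-n_init restarts.

# Squared Euclidean distances between rows of X (possibly sparse) and rows
# of centers C: d2[i, j] = ||x_i||^2 + ||c_j||^2 - 2 x_i . c_j
row_dist2 <- function(X, rn2, C) {
  xc <- as.matrix(X %*% t(C))
  d2 <- outer(rn2, rowSums(C^2), `+`) - 2 * xc
  d2[d2 < 0] <- 0
  d2
}

kmeanspp_init <- function(X, rn2, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- as.numeric(X[first, ])
  d2 <- row_dist2(X, rn2, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = p)
    centers[j + 1L, ] <- as.numeric(X[nxt, ])
    d2 <- pmin(d2, row_dist2(X, rn2, centers[j + 1L, , drop = FALSE])[, 1])
  }
  centers
}

lloyd <- function(X, rn2, centers, max_iter) {
  k <- nrow(centers)
  n <- nrow(X)
  labels <- integer(n)
  inertia_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- row_dist2(X, rn2, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), new_labels)])
    # refill empty clusters with the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(new_labels))
    for (j in empty) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      centers[j, ] <- as.numeric(X[far, ])
      new_labels[far] <- j
    }
    converged <- identical(new_labels, labels) && it > 1L
    labels <- new_labels
    # centroid = mean spectrum of member pixels
    ind <- Matrix::sparseMatrix(i = labels, j = seq_len(n), x = 1,
                                dims = c(k, n))
    cnt <- as.numeric(ind %*% rep(1, n))
    centers <- as.matrix(ind %*% X) / cnt
    inertia_trace <- c(inertia_trace, inertia)
    if (converged) break
  }
  d2 <- row_dist2(X, rn2, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       inertia_trace = inertia_trace)
}

#' K-Means segmentation of the pixel matrix
#'
#' Standard Lloyd iterations with seeded k-means++ initialization, keeping
#' the best of `n_init` restarts by inertia. Distances are Euclidean on the
#' same unnormalized matrix given to NMF.
#'
#' @param V Pixels x channels matrix (dense or sparse).
#' @param k Number of clusters.
#' @param seed Seed; results are deterministic under (V, k, seed).
#' @param n_init Number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return Object of class `kmeans_result`: `labels` (per-pixel cluster
#'   index in 1..k), `centroids` (k x channels mean spectra), `inertia`,
#'   `inertia_trace` (of the winning restart; non-increasing), `seed`.
#' @export
kmeans_segment <- function(V, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  check_scalar_pos(k, "k")
  k <- as.integer(k)
  n <- nrow(V)
  if (k > n) stop_("k (%d) exceeds number of pixels (%d)", k, n)
  rn2 <- if (is(V, "sparseMatrix")) Matrix::rowSums(V^2) else rowSums(V^2)
  # distinctness check via two seeded random projections (cheap at any width)
  pr <- with_seed(seed + 101L, matrix(rnorm(2 * ncol(V)), ncol(V), 2))
  proj <- as.matrix(V %*% pr)
  n_distinct <- nrow(unique(round(cbind(proj, rn2), 9)))
  if (k > n_distinct) {
    stop_("k (%d) exceeds the number of distinct pixel spectra (~%d)",
          k, n_distinct)
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd(V, rn2, kmeanspp_init(V, rn2, k), max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(labels = best$labels, centroids = best$centers,
                 inertia = best$inertia, inertia_trace = best$inertia_trace,
                 k = k, seed = as.integer(seed)),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> k = %d, inertia = %.6g, %d Lloyd iterations\n",
              x$k, x$inertia, length(x$inertia_trace)))
  invisible(x)
}

#' Otsu threshold of a non-negative image
#'
#' Parameter-free histogram threshold maximizing between-class variance;
#' used to binarize soft NMF component images for overlap comparisons.
#'
#' @param x Numeric vector or matrix.
#' @param n_bins Histogram resolution (default 256).
#' @return Threshold value; pixels `> threshold` form the foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Compare K-Means clusters with NMF components and ground-truth masks
#'
#' For each hard K-Means cluster, reports the Jaccard overlap with each
#' ground-truth region mask and with each NMF component image binarized at
#' its Otsu threshold. K-Means labels are hard (binary membership); NMF
#' components are soft and only binarized here for the overlap bookkeeping —
#' the report keeps the two kinds apart.
#'
#' @param kmeans A [kmeans_segment()] result.
#' @param nmf An [nmf_als()] result on the same pixel grid.
#' @param masks Named list of logical rows x cols ground-truth masks.
#' @param rows,cols Pixel grid dimensions.
#' @return List with `jaccard_masks` (k_clusters x n_masks), `jaccard_nmf`
#'   (k_clusters x k_components, against Otsu-binarized soft components),
#'   `best_mask` (data.frame: cluster, best-matching mask, Jaccard).
#' @export
compare_segmentations <- function(kmeans, nmf, masks, rows, cols) {
  stopifnot(inherits(kmeans, "kmeans_result"), inherits(nmf, "nmf_result"))
  kcl <- kmeans$k
  cl_masks <- lapply(seq_len(kcl), function(j) kmeans$labels == j)
  mask_vecs <- lapply(masks, image_to_pixels)
  jm <- matrix(0, kcl, length(masks),
               dimnames = list(paste0("cluster", seq_len(kcl)), names(masks)))
  for (j in seq_len(kcl)) for (m in seq_along(masks)) {
    jm[j, m] <- jaccard(cl_masks[[j]], mask_vecs[[m]])
  }
  jn <- matrix(0, kcl, nmf$k,
               dimnames = list(paste0("cluster", seq_len(kcl)),
                               paste0("component", seq_len(nmf$k))))
  for (c in seq_len(nmf$k)) {
    img <- nmf$W[, c]
    bin <- img > otsu_threshold(img)
    for (j in seq_len(kcl)) jn[j, c] <- jaccard(cl_masks[[j]], bin)
  }
  best <- data.frame(cluster = seq_len(kcl),
                     mask = colnames(jm)[max.col(jm, ties.method = "first")],
                     jaccard = apply(jm, 1, max))
  list(jaccard_masks = jm, jaccard_nmf = jn, best_mask = best)
}
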