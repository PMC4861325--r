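# Alternating-least-squares non-negative matrix factorization of the pixel
# matrix: V (pixels x channels) ~ W (pixels x k) %*% H (k x channels),
# minimizing D = 1/2 * ||V - W H||_F^2. Each update solves the exact least
# squares problem for one factor via Moore-Penrose pseudoinverse and clamps
# negative entries to zero:
#   W <- V H' (H H')^#      then W[W < 0] <- 0
#   H <- (W' W)^# W' V      then H[H < 0] <- 0
# Columns of W are component images, rows of H component spectra.

# Moore-Penrose pseudoinverse via SVD with singular values below
# rtol * sigma_max treated as zero (stable for the rank-deficient k x k
# Gram matrices that clamping can produce).
pseudoinverse <- function(M, rtol = 1e-12) {
  s <- svd(M)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' ALS non-negative matrix factorization
#'
#' @param V Non-negative pixels x channels matrix (dense or
#'   `Matrix` sparse), e.g. from [pixel_matrix()].
#' @param k Number of components, `1 <= k <= min(dim(V))`.
#' @param seed Seed for the positive initialization of `H` (i.i.d. uniform
#'   on `[0.1, 1]`, bounded away from zero to avoid dead rows at start).
#' @param tol Convergence tolerance on the relative objective change
#'   `|D_t - D_{t-1}| / max(D_{t-1}, eps)` (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param on_iteration Optional callback `function(W, H, D, iter)` invoked
#'   after each iteration (used by tests to assert in-loop invariants).
#' @return Object of class `nmf_result`: `W` (pixels x k, >= 0), `H`
#'   (k x channels, >= 0), `k`, `objective_trace` (one `D` per iteration),
#'   `iterations`, `converged`, `seed`. If a component dies (all-zero W
#'   column or H row) it is re-seeded once from the generator, then left
#'   zero with a message if it dies again.
#' @export
nmf_als <- function(V, k, seed = 1L, tol = 1e-6, max_iter = 500L,
                    on_iteration = NULL) {
  check_scalar_pos(k, "k")
  check_scalar_pos(tol, "tol")
  k <- as.integer(k)
  np <- nrow(V); nc <- ncol(V)
  if (k > min(np, nc)) stop_("k (%d) exceeds min(dim(V)) = %d", k, min(np, nc))
  vmin <- if (is(V, "sparseMatrix")) min(0, min(V@x)) else min(V)
  if (vmin < 0) stop_("V must be elementwise non-negative")
  normV2 <- if (is(V, "sparseMatrix")) sum(V@x^2) else sum(V^2)
  if (normV2 == 0) {
    warning("all-zero V: returning W = 0, H = 0 with D = 0")
    return(structure(list(W = matrix(0, np, k), H = matrix(0, k, nc), k = k,
                          objective_trace = 0, iterations = 0L,
                          converged = TRUE, seed = as.integer(seed)),
                     class = "nmf_result"))
  }
  reseed_used_W <- logical(k); reseed_used_H <- logical(k)
  res <- with_seed(seed, {
    H <- matrix(runif(k * nc, 0.1, 1), k, nc)
    W <- matrix(0, np, k)
    trace <- numeric(0)
    D_prev <- Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      # W-step: W = V H' (H H')^#, clamp negatives
      W <- as.matrix(V %*% crossprod(H, pseudoinverse(tcrossprod(H))))
      W[W < 0] <- 0
      dead <- colSums(W) == 0
      for (j in which(dead)) {
        if (!reseed_used_W[j]) {
          W[, j] <- runif(np, 0.1, 1)
          reseed_used_W[j] <- TRUE
        } else {
          message(sprintf("component %d image died permanently", j))
        }
      }
      # H-step: H = (W'W)^# W' V, clamp negatives
      WtV <- as.matrix(Matrix::crossprod(W, V))
      H <- pseudoinverse(crossprod(W)) %*% WtV
      H[H < 0] <- 0
      dead <- rowSums(H) == 0
      for (j in which(dead)) {
        if (!reseed_used_H[j]) {
          H[j, ] <- runif(nc, 0.1, 1)
          reseed_used_H[j] <- TRUE
        } else {
          message(sprintf("component %d spectrum died permanently", j))
        }
      }
      # D = 1/2 ||V - WH||_F^2 without densifying V - WH:
      # ||V||^2 - 2 tr(H' W' V) + tr((W'W)(H H'))
      D <- 0.5 * (normV2 - 2 * sum(WtV * H) +
                    sum(crossprod(W) * tcrossprod(H)))
      trace <- c(trace, D)
      if (!is.null(on_iteration)) on_iteration(W, H, D, iter)
      if (is.finite(D_prev) &&
          abs(D - D_prev) / max(D_prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
      D_prev <- D
    }
    list(W = W, H = H, trace = trace, iterations = iter,
         converged = converged)
  })
  structure(list(W = res$W, H = res$H, k = k,
                 objective_trace = res$trace, iterations = res$iterations,
                 converged = res$converged, seed = as.integer(seed)),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> k = %d, %d iterations (%s), D = %.6g\n",
              x$k, x$iterations,
              if (x$converged) "converged" else "max_iter",
              tail(x$objective_trace, 1)))
  invisible(x)
}

#' Relative reconstruction error of an NMF result
#' @param result An `nmf_result`.
#' @param V The matrix that was factorized.
#' @return `||V - W H||_F / ||V||_F`.
#' @export
nmf_relative_error <- function(result, V) {
  normV2 <- if (is(V, "sparseMatrix")) sum(V@x^2) else sum(V^2)
  sqrt(2 * tail(result$objective_trace, 1) / normV2)
}

#' Normalize a component set for display
#'
#' Component images are reshaped to rows x cols (row-major pixel order) and
#' min-max scaled to `[0, 1]` individually; component spectra are jointly
#' scaled so the single largest peak across the whole set equals 100% (the
#' base peak of the component set).
#'
#' @param result An [nmf_als()] result.
#' @param rows,cols Cube pixel grid dimensions.
#' @return Object of class `normalized_components`: `images` (list of
#'   rows x cols matrices in `[0, 1]`) and `spectra` (k x channels matrix in
#'   percent of the set base peak).
#' @export
normalize_component_set <- function(result, rows, cols) {
  stopifnot(inherits(result, "nmf_result"))
  hmax <- max(result$H)
  if (hmax <= 0) stop_("all-zero H: nothing to normalize")
  images <- lapply(seq_len(result$k), function(j) {
    img <- pixels_to_image(result$W[, j], rows, cols)
    rng <- range(img)
    if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  })
  structure(list(images = images, spectra = result$H / hmax * 100),
            class = "normalized_components")
}

#' Match components to ground-truth region masks
#'
#' Greedy one-to-one matching of component images to masks by descending
#' Pearson correlation between the component image (a `W` column) and the
#' 0/1 mask indicator, flattened over pixels.
#'
#' @param result An [nmf_als()] result (or any list with a `W` matrix in
#'   row-major pixel order).
#' @param masks Named list of logical rows x cols matrices partitioning the
#'   pixel grid.
#' @return List with `matching` (data.frame: `component`, `mask`,
#'   `correlation`, in match order), `correlations` (k x n_masks matrix) and
#'   `unmatched_masks` (character; non-empty when `k <` number of masks).
#' @export
component_assignment <- function(result, masks) {
  W <- result$W
  k <- ncol(W)
  ind <- vapply(masks, function(m) as.numeric(image_to_pixels(m)),
                numeric(nrow(W)))
  cors <- suppressWarnings(cor(W, ind))  # NA for constant columns
  cors[is.na(cors)] <- 0
  rownames(cors) <- paste0("component", seq_len(k))
  avail_c <- seq_len(k); avail_m <- seq_along(masks)
  out <- list()
  while (length(avail_c) > 0 && length(avail_m) > 0) {
    sub <- cors[avail_c, avail_m, drop = FALSE]
    ij <- arrayInd(which.max(sub), dim(sub))
    ci <- avail_c[ij[1]]; mi <- avail_m[ij[2]]
    out[[length(out) + 1L]] <- data.frame(
      component = ci, mask = names(masks)[mi] %||% as.character(mi),
      correlation = cors[ci, mi])
    avail_c <- setdiff(avail_c, ci); avail_m <- setdiff(avail_m, mi)
  }
  list(matching = do.call(rbind, out), correlations = cors,
       unmatched_masks = names(masks)[avail_m] %||% character(0))
}

#' Region indicator masks from a phantom label image
#'
#' @param phantom A [make_phantom()] result.
#' @param include_background Include the label-0 background mask
#'   (default TRUE).
#' @return Named list of logical rows x cols matrices.
#' @export
phantom_masks <- function(phantom, include_background = TRUE) {
  stopifnot(inherits(phantom, "phantom"))
  labs <- seq_along(phantom$labels)
  m <- lapply(labs, function(l) phantom$label_image == l)
  names(m) <- phantom$labels
  if (include_background) m$background <- phantom$label_image == 0L
  m
}
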