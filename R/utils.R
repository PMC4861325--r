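#' @importFrom methods as is new
#' @importFrom stats approx cor rnorm rpois runif rexp sd t.test
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All randomized operations in the package go through this
# so that no function mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_("`%s` must be a single positive number (got %s)", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# Row-major pixel indexing shared by the cube, NMF and K-Means modules:
# pixel index p = (row - 1) * cols + col, row 1 = smallest y, col 1 = smallest x.
pixel_index <- function(row, col, cols) (row - 1L) * cols + col

# Reshape a length rows*cols pixel vector (row-major order) into a rows x cols
# matrix (row = y index, col = x index).
pixels_to_image <- function(x, rows, cols) {
  stopifnot(length(x) == rows * cols)
  matrix(x, nrow = rows, ncol = cols, byrow = TRUE)
}

image_to_pixels <- function(img) as.vector(t(img))
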