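## Internal numeric helpers shared across modules.

#' @import methods
#' @importFrom stats median quantile rnorm runif rgamma sd density aov
#'   TukeyHSD kruskal.test shapiro.test lm pf pnorm p.adjust coef cor
#'   complete.cases
#' @importFrom utils head tail write.csv
NULL

## Axis order convention for every volume: (scan, depth, lateral).
.AXES <- c("scan", "depth", "lateral")

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a stream of sub-seeds from one master seed so pipeline stages are
## independently reproducible. Values stay below 2^31.
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## ---- separable Gaussian smoothing --------------------------------------

## 1D Gaussian kernel; sigma in voxel units. sigma <= 0 -> identity kernel.
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolve along the first margin of a matrix with edge renormalization so
## constant inputs are preserved exactly.
.conv_axis1 <- function(mat, k) {
  if (length(k) == 1L) return(mat)
  n <- nrow(mat)
  r <- (length(k) - 1L) %/% 2L
  padded <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
  out <- matrix(0, n, ncol(mat))
  wt <- numeric(n)
  for (j in seq_along(k)) {
    idx <- seq_len(n) + (j - 1L)
    out <- out + k[j] * padded[idx, , drop = FALSE]
  }
  ones <- c(rep(0, r), rep(1, n), rep(0, r))
  for (j in seq_along(k)) wt <- wt + k[j] * ones[seq_len(n) + (j - 1L)]
  out / wt
}

## Separable anisotropic Gaussian blur of a 3D array; sigma_vox per axis.
.gauss_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  .assert(length(d) == 3L, "expected a 3D array")
  for (ax in 1:3) {
    k <- .gauss_kernel(sigma_vox[ax])
    if (length(k) == 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- .conv_axis1(matrix(a, dd[1], dd[2] * dd[3]), k)
    a <- array(m, dd)
    arr <- aperm(a, order(perm))
  }
  arr
}

## 2D variant used by per-slice operations.
.gauss_blur2 <- function(mat, sigma_vox) {
  k1 <- .gauss_kernel(sigma_vox[1])
  k2 <- .gauss_kernel(sigma_vox[2])
  t(.conv_axis1(t(.conv_axis1(mat, k1)), k2))
}

## ---- regridding between voxel lattices ---------------------------------

## Map destination voxel centers onto source indices (nearest neighbour).
.nn_index <- function(n_src, dx_src, n_dst, dx_dst) {
  centers <- (seq_len(n_dst) - 0.5) * dx_dst
  pmin(n_src, pmax(1L, floor(centers / dx_src) + 1L))
}

## Mean-aggregate source voxels into destination bins along one axis.
.bin_axis <- function(arr, axis, dx_src, dx_dst, n_dst) {
  d <- dim(arr)
  n_src <- d[axis]
  g <- pmin(n_dst, floor(((seq_len(n_src) - 0.5) * dx_src) / dx_dst) + 1L)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dd <- dim(a)
  m <- matrix(a, dd[1], dd[2] * dd[3])
  s <- rowsum(m, g)
  cnt <- as.vector(rowsum(rep(1, dd[1]), g))
  ## destination bins beyond the source extent keep the last filled bin
  filled <- as.integer(rownames(s))
  full <- matrix(0, n_dst, ncol(m))
  full[filled, ] <- s / cnt
  if (length(filled) < n_dst) {
    missing <- setdiff(seq_len(n_dst), filled)
    for (i in missing) full[i, ] <- full[max(filled[filled < i], 1L), ]
  }
  a2 <- array(full, c(n_dst, dd[2], dd[3]))
  aperm(a2, order(perm))
}

## Resample a 3D scalar array from one spacing to another over the same
## physical extent: block mean when coarsening, nearest neighbour when
## refining (per axis).
.resample3 <- function(arr, spacing_src, spacing_dst, dim_dst) {
  for (ax in 1:3) {
    if (dim(arr)[ax] == dim_dst[ax] && spacing_src[ax] == spacing_dst[ax]) next
    if (spacing_dst[ax] >= spacing_src[ax]) {
      arr <- .bin_axis(arr, ax, spacing_src[ax], spacing_dst[ax], dim_dst[ax])
    } else {
      idx <- .nn_index(dim(arr)[ax], spacing_src[ax], dim_dst[ax],
                       spacing_dst[ax])
      arr <- switch(ax,
                    arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
    }
  }
  arr
}

## Nearest-neighbour resample for label (integer) volumes.
.resample3_nn <- function(arr, spacing_src, spacing_dst, dim_dst) {
  i1 <- .nn_index(dim(arr)[1], spacing_src[1], dim_dst[1], spacing_dst[1])
  i2 <- .nn_index(dim(arr)[2], spacing_src[2], dim_dst[2], spacing_dst[2])
  i3 <- .nn_index(dim(arr)[3], spacing_src[3], dim_dst[3], spacing_dst[3])
  arr[i1, i2, i3, drop = FALSE]
}

## Grid dimension for a physical extent at a given spacing.
.grid_dim <- function(extent_mm, spacing_mm) {
  pmax(1L, as.integer(round(extent_mm / spacing_mm)))
}
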