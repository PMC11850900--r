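#' Low-resolution / high-resolution grid correspondence
#'
#' Low-resolution voxel `(i, j, k)` (1-based) corresponds to the disjoint
#' high-resolution 2x2x2 block `(2i-1..2i, 2j-1..2j, 2k-1..2k)`; on each axis
#' the high-resolution coordinates are the integers `x_i = i` and the
#' low-resolution voxel centers sit at `y_j = 2j - 0.5`, i.e. at the center
#' of the block they average. These coordinates drive both the spline
#' baselines and the scatter of network predictions.
#'
#' @name grid-mapping
NULL

# fixed flattening orders (documented contract): patch voxels are ordered
# voxel-major with the z offset varying fastest, then y, then x; within each
# voxel the coefficients are contiguous. HR block voxels use the same
# z-fastest order over the binary offsets.
patch_offsets <- function() {
  as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))[, c("dx", "dy", "dz")]
}
block_offsets <- function() {
  as.matrix(expand.grid(bz = 0:1, by = 0:1, bx = 0:1))[, c("bx", "by", "bz")]
}

# gather the 27-neighborhood input matrix (n_masked x 27*C) from a
# zero-padded copy of the LR volume
gather_patch_inputs <- function(lr_sh, mask) {
  d <- dim(lr_sh)
  C <- d[4]
  pad <- array(0, c(d[1:3] + 2L, C))
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- lr_sh
  sel <- which(mask)
  off <- patch_offsets()
  X <- matrix(0, length(sel), 27L * C)
  flat_dim <- prod(d[1:3])
  for (o in seq_len(27)) {
    sub <- pad[(2:(d[1] + 1)) + off[o, 1],
               (2:(d[2] + 1)) + off[o, 2],
               (2:(d[3] + 1)) + off[o, 3], , drop = FALSE]
    X[, ((o - 1L) * C + 1L):(o * C)] <- matrix(sub, flat_dim, C)[sel, , drop = FALSE]
  }
  X
}

#' Extract paired training patches from aligned SH volumes
#'
#' One training example per masked low-resolution voxel: the input is the
#' flattened 3x3x3 neighborhood of normalized SH coefficients (zero-padded at
#' the volume border), the target the flattened 2x2x2 high-resolution block
#' of the central voxel. With 44 coefficients per voxel the rows have length
#' 1188 and 352.
#'
#' @param lr_sh 4D array `(x, y, z, C)` of normalized low-resolution SH.
#' @param hr_sh 4D array at exactly double the spatial dimensions.
#' @param mask Optional 3D logical array on the low-resolution grid.
#' @param phantom_id Identifier recorded per example, used for subject-level
#'   train/validation/test splits.
#' @return A list of class `patch_dataset`: `inputs` (n x 27C), `targets`
#'   (n x 8C), `voxels` (n x 3 LR indices), `phantom_id` (length n),
#'   `dim_lr`, `n_coef`.
#' @export
extract_patches <- function(lr_sh, hr_sh, mask = NULL, phantom_id = 1L) {
  stopifnot(length(dim(lr_sh)) == 4, length(dim(hr_sh)) == 4)
  dl <- dim(lr_sh); dh <- dim(hr_sh)
  if (!all(dh[1:3] == 2L * dl[1:3]) || dh[4] != dl[4])
    stop("`hr_sh` must have exactly double the spatial dimensions of `lr_sh`",
         call. = FALSE)
  C <- dl[4]
  if (is.null(mask)) mask <- array(TRUE, dl[1:3])
  stopifnot(all(dim(mask) == dl[1:3]))

  X <- gather_patch_inputs(lr_sh, mask)
  sel <- which(mask)
  vox <- arrayInd(sel, dl[1:3])
  hr_flat_dim <- prod(dh[1:3])
  boff <- block_offsets()
  Y <- matrix(0, length(sel), 8L * C)
  for (o in seq_len(8)) {
    hi <- cbind(2L * vox[, 1] - 1L + boff[o, 1],
                2L * vox[, 2] - 1L + boff[o, 2],
                2L * vox[, 3] - 1L + boff[o, 3])
    lin <- hi[, 1] + (hi[, 2] - 1L) * dh[1] + (hi[, 3] - 1L) * dh[1] * dh[2]
    Y[, ((o - 1L) * C + 1L):(o * C)] <-
      matrix(hr_sh, hr_flat_dim, C)[lin, , drop = FALSE]
  }
  structure(list(inputs = X, targets = Y, voxels = vox,
                 phantom_id = rep(phantom_id, length.out = nrow(X)),
                 dim_lr = dl[1:3], n_coef = C),
            class = "patch_dataset")
}

#' Combine patch datasets from several phantoms or subjects
#'
#' @param ... `patch_dataset` objects (or a single list of them).
#' @return A `patch_dataset` with rows stacked; `dim_lr` is dropped when the
#'   sources disagree.
#' @export
bind_patch_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && !inherits(ds[[1]], "patch_dataset")) ds <- ds[[1]]
  stopifnot(all(vapply(ds, inherits, logical(1), "patch_dataset")))
  structure(list(
    inputs = do.call(rbind, lapply(ds, `[[`, "inputs")),
    targets = do.call(rbind, lapply(ds, `[[`, "targets")),
    voxels = do.call(rbind, lapply(ds, `[[`, "voxels")),
    phantom_id = unlist(lapply(ds, `[[`, "phantom_id")),
    dim_lr = NULL, n_coef = ds[[1]]$n_coef),
    class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d examples, input %d, target %d (%d coefficients/voxel)\n",
              nrow(x$inputs), ncol(x$inputs), ncol(x$targets), x$n_coef))
  invisible(x)
}

#' Scatter a target/prediction matrix back onto the high-resolution grid
#'
#' Inverse of the target layout of [extract_patches()]: row `r` of `pred`
#' fills the 2x2x2 block of LR voxel `voxels[r, ]`.
#'
#' @param pred n x 8C matrix.
#' @param voxels n x 3 LR voxel indices.
#' @param dim_lr LR grid dimensions.
#' @param n_coef Coefficients per voxel.
#' @return 4D array `(2x, 2y, 2z, n_coef)`; voxels not covered are zero.
#' @export
scatter_hr_blocks <- function(pred, voxels, dim_lr, n_coef) {
  dh <- c(2L * dim_lr, n_coef)
  out <- array(0, dh)
  flat <- matrix(out, prod(dh[1:3]), n_coef)
  boff <- block_offsets()
  for (o in seq_len(8)) {
    hi <- cbind(2L * voxels[, 1] - 1L + boff[o, 1],
                2L * voxels[, 2] - 1L + boff[o, 2],
                2L * voxels[, 3] - 1L + boff[o, 3])
    lin <- hi[, 1] + (hi[, 2] - 1L) * dh[1] + (hi[, 3] - 1L) * dh[1] * dh[2]
    flat[lin, ] <- pred[, ((o - 1L) * n_coef + 1L):(o * n_coef), drop = FALSE]
  }
  array(flat, dh)
}

#' Upsample a normalized SH volume with a trained DSR network
#'
#' Every masked low-resolution voxel's 3x3x3 neighborhood is pushed through
#' the network and the 8 predicted high-resolution voxels are scattered to
#' the corresponding 2x2x2 block; unmasked blocks are zero. Chaining the
#' call doubles resolution again (3 applications: 1.25 mm -> 156.25 um
#' voxels).
#'
#' @param model A trained [train_dsr()] model.
#' @param lr_sh 4D array `(x, y, z, C)` of normalized SH coefficients.
#' @param mask Optional 3D logical array on the LR grid.
#' @return 4D array with doubled spatial dimensions.
#' @export
apply_dsr <- function(model, lr_sh, mask = NULL) {
  stopifnot(inherits(model, "dsr_model"), length(dim(lr_sh)) == 4)
  d <- dim(lr_sh)
  C <- d[4]
  if (model$spec$input_dim != 27L * C)
    stop("model input dimension does not match 27 x coefficient count",
         call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  X <- gather_patch_inputs(lr_sh, mask)
  pred <- predict(model, X)
  vox <- arrayInd(which(mask), d[1:3])
  scatter_hr_blocks(pred, vox, d[1:3], C)
}

# quadratic B-spline kernel
bspline2 <- function(t) {
  a <- abs(t)
  ifelse(a <= 0.5, 0.75 - a^2,
         ifelse(a <= 1.5, 0.5 * (a - 1.5)^2, 0))
}

# causal/anticausal prefilter for quadratic B-spline interpolation, applied
# down the rows of a matrix (one signal per column), mirror boundary
bspline2_prefilter <- function(M) {
  z <- sqrt(8) - 3
  n <- nrow(M)
  if (n == 1) return(M)
  M <- M * ((1 - z) * (1 - 1 / z))  # gain = 8 for the quadratic spline
  K <- ceiling(log(1e-14) / log(abs(z)))
  # mirror initialization of the causal pass (wrapping the reflection)
  c0 <- M[1, ]
  for (k in seq_len(K)) c0 <- c0 + z^k * M[mirror_index(1L + k, n), ]
  C <- M
  C[1, ] <- c0
  for (k in 2:n) C[k, ] <- M[k, ] + z * C[k - 1, ]
  D <- C
  D[n, ] <- (z / (z^2 - 1)) * (C[n, ] + z * C[n - 1, ])
  for (k in (n - 1):1) D[k, ] <- z * (D[k + 1, ] - C[k, ])
  D
}

# reflect an index about nodes 1 and n (mirror extension)
mirror_index <- function(j, n) {
  if (n == 1) return(rep(1L, length(j)))
  p <- 2L * (n - 1L)
  j <- (j - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# double the first-axis length of a matrix of column signals using a spline
# defined at low-resolution coordinates y_j = 2j - 0.5, evaluated at the
# high-resolution integers x_i = i
spline_double_axis <- function(M, order) {
  n <- nrow(M)
  u <- (seq_len(2L * n) + 0.5) / 2   # query positions in LR index units
  if (order == 0) {
    return(M[mirror_index(round(u), n), , drop = FALSE])
  }
  if (order == 1) {
    j0 <- floor(u)
    t <- u - j0
    return(M[mirror_index(j0, n), , drop = FALSE] * (1 - t) +
             M[mirror_index(j0 + 1, n), , drop = FALSE] * t)
  }
  if (order == 2) {
    C <- bspline2_prefilter(M)
    out <- matrix(0, 2L * n, ncol(M))
    for (dk in -1:1) {
      k <- round(u) + dk
      w <- bspline2(u - k)
      out <- out + C[mirror_index(k, n), , drop = FALSE] * w
    }
    return(out)
  }
  stop("spline order must be 0, 1 or 2", call. = FALSE)
}

#' Spline upsampling of a scalar volume to double resolution
#'
#' Tensor-product spline interpolation (order 0 = nearest neighbor, 1 =
#' trilinear, 2 = quadratic with exact B-spline prefiltering) on the
#' half-voxel-offset grid: low-resolution samples sit at `y_j = 2j - 0.5`
#' and are evaluated at the high-resolution integers `x_i = i`, with mirror
#' boundary extension. Order 0 reproduces 2x2x2 block replication exactly.
#'
#' @param vol 3D numeric array.
#' @param order Spline order, one of 0, 1, 2.
#' @return 3D array with doubled dimensions.
#' @export
spline_upsample <- function(vol, order = 1) {
  stopifnot(length(dim(vol)) == 3)
  if (!(length(order) == 1 && order %in% 0:2))
    stop("spline order must be 0, 1 or 2", call. = FALSE)
  d <- dim(vol)
  # axis 1
  m <- spline_double_axis(matrix(vol, d[1], d[2] * d[3]), order)
  vol <- array(m, c(2L * d[1], d[2], d[3]))
  # axis 2
  a <- aperm(vol, c(2, 1, 3))
  m <- spline_double_axis(matrix(a, d[2], 2L * d[1] * d[3]), order)
  vol <- aperm(array(m, c(2L * d[2], 2L * d[1], d[3])), c(2, 1, 3))
  # axis 3
  a <- aperm(vol, c(3, 1, 2))
  m <- spline_double_axis(matrix(a, d[3], 4L * d[1] * d[2]), order)
  aperm(array(m, c(2L * d[3], 2L * d[1], 2L * d[2])), c(2, 3, 1))
}

#' @rdname spline_upsample
#' @param sh 4D array `(x, y, z, C)`; each coefficient volume is upsampled
#'   independently.
#' @export
spline_upsample_volume <- function(sh, order = 1) {
  stopifnot(length(dim(sh)) == 4)
  d <- dim(sh)
  out <- array(0, c(2L * d[1:3], d[4]))
  for (k in seq_len(d[4])) out[, , , k] <- spline_upsample(sh[, , , k], order)
  out
}
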