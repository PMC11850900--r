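#' Single-shell gradient schemes
#'
#' A gradient scheme pairs b-values with unit gradient directions, matching
#' the FSL bval/bvec convention (directions of b = 0 entries are ignored).
#'
#' @param bvals Numeric vector of b-values in s/mm^2.
#' @param bvecs `n x 3` matrix of gradient directions (unit norm for b > 0).
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals))
    stop("`bvecs` must be an n x 3 matrix matching `bvals`", call. = FALSE)
  dw <- bvals > 50
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dw] - 1) > 1e-3))
    stop("diffusion-weighted bvecs must be unit norm (within 1e-3)",
         call. = FALSE)
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

shell_indices <- function(scheme) which(scheme$bvals > 50)
b0_indices <- function(scheme) which(scheme$bvals <= 50)

check_single_shell <- function(scheme) {
  b <- unique(round(scheme$bvals[shell_indices(scheme)]))
  if (length(b) != 1)
    stop("a single-shell scheme is required (one nonzero b-value)",
         call. = FALSE)
  b
}

#' Near-uniform single-shell acquisition scheme
#'
#' Generates `n_dirs` directions by seeded electrostatic repulsion of
#' antipodal point pairs on the sphere, prepended by `n_b0` unweighted
#' volumes. The default emulates a 1 b0 + 60-direction b = 3000 s/mm^2
#' protocol.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param bval Shell b-value in s/mm^2.
#' @param n_b0 Number of b = 0 volumes.
#' @param seed RNG seed for the initial point set.
#' @param n_iter Repulsion iterations.
#' @return A [gradient_scheme()].
#' @export
make_gradient_scheme <- function(n_dirs = 60, bval = 3000, n_b0 = 1,
                                 seed = 42, n_iter = 200) {
  stopifnot(n_dirs >= 6, n_b0 >= 0, bval > 0)
  v <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_dirs), n_dirs, 3)
    m / sqrt(rowSums(m^2))
  })
  step <- 0.05
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n_dirs, 3)
    for (i in seq_len(n_dirs)) {
      d1 <- sweep(-v, 2, -v[i, ])          # v_i - v_j
      d2 <- sweep(v, 2, v[i, ], function(a, b) b + a)  # v_i + v_j
      r1 <- rowSums(d1^2); r2 <- rowSums(d2^2)
      r1[i] <- Inf
      force[i, ] <- colSums(d1 / r1^1.5) + colSums(d2 / r2^1.5)
    }
    disp <- step * force
    nrm <- sqrt(rowSums(disp^2))
    too_big <- nrm > 0.1      # cap the step: close pairs make 1/r^2 blow up
    disp[too_big, ] <- disp[too_big, , drop = FALSE] * (0.1 / nrm[too_big])
    v <- v + disp
    v <- v / sqrt(rowSums(v^2))
  }
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), v)
  gradient_scheme(bvals, bvecs)
}

#' Axially symmetric single-fiber response function
#'
#' Prolate-tensor response with axial and radial diffusivities. The defaults
#' are typical coherent white-matter values.
#'
#' @param lambda_par Axial diffusivity in mm^2/s.
#' @param lambda_perp Radial diffusivity in mm^2/s.
#' @return An object of class `response_function`.
#' @export
response_function <- function(lambda_par = 1.7e-3, lambda_perp = 0.2e-3) {
  if (!(lambda_par >= lambda_perp && lambda_perp > 0))
    stop("need lambda_par >= lambda_perp > 0", call. = FALSE)
  structure(list(lambda_par = lambda_par, lambda_perp = lambda_perp),
            class = "response_function")
}

#' Synthetic fiber-configuration phantom
#'
#' Builds a deterministic per-voxel fiber configuration on an even-sized grid
#' with three region types along the x axis: a single-fiber slab whose
#' orientation rotates smoothly in space, a 90-degree equal-weight (0.5/0.5)
#' crossing region, and an isotropic (free-water) region. Per-phantom random
#' offsets (drawn from `seed`) rotate the orientation fields and jitter the
#' region boundary so that phantoms with different seeds are distinct but
#' statistically alike — this provides subject-level train/test separation.
#'
#' @param shape Integer 3-vector of even grid dimensions.
#' @param seed Integer seed; the configuration is a pure function of
#'   `(shape, seed)`.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return An object of class `fiber_config`: orientations
#'   `(x, y, z, 5, 3)`, fractions `(x, y, z, 5)`, `n_fibers` `(x, y, z)`,
#'   integer `labels` (0 isotropic, 1 single-fiber WM, 2 crossing WM),
#'   `voxel_size`.
#' @export
make_phantom <- function(shape = c(24, 24, 24), seed = 1, voxel_size = 1.25) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 4))
  if (any(shape %% 2L != 0L))
    stop("phantom dimensions must be even so 2x downsampling is exact",
         call. = FALSE)
  rnd <- withr::with_seed(seed, stats::runif(6, 0, 2 * pi))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ori <- array(0, c(shape, 5L, 3L))
  frac <- array(0, c(shape, 5L))
  nfib <- array(0L, shape)
  labels <- array(0L, shape)

  b1 <- floor(nx / 3); b2 <- floor(2 * nx / 3)
  # seeded +-1 voxel jitter of the region boundaries (kept even-safe)
  j1 <- b1 + (seed %% 3L) - 1L
  j2 <- b2 + ((seed %/% 3L) %% 3L) - 1L
  j1 <- max(2L, min(nx - 4L, j1)); j2 <- max(j1 + 2L, min(nx - 2L, j2))

  for (ix in seq_len(nx)) for (iy in seq_len(ny)) for (iz in seq_len(nz)) {
    if (ix <= j1) {
      # single fiber in the xz-plane; the angle sweeps the full circle
      # across y so every phantom covers the whole orientation space
      # (mirroring whole-brain training data), while the seed shifts the
      # spatial arrangement
      a <- rnd[1] + 2 * pi * iy / ny +
        0.45 * cos(2 * pi * iz / nz + rnd[3])
      u <- c(sin(a), 0, cos(a))
      ori[ix, iy, iz, 1, ] <- u
      frac[ix, iy, iz, 1] <- 1
      nfib[ix, iy, iz] <- 1L
      labels[ix, iy, iz] <- 1L
    } else if (ix <= j2) {
      # orthogonal equal crossing; the pair sweeps its fundamental domain
      # (a quarter turn) across y
      a <- rnd[4] + (pi / 2) * iy / ny +
        0.3 * cos(2 * pi * ix / nx + rnd[6])
      u1 <- c(cos(a), sin(a), 0)
      u2 <- c(-sin(a), cos(a), 0)
      ori[ix, iy, iz, 1, ] <- u1
      ori[ix, iy, iz, 2, ] <- u2
      frac[ix, iy, iz, 1:2] <- 0.5
      nfib[ix, iy, iz] <- 2L
      labels[ix, iy, iz] <- 2L
    }
    # else isotropic: no fibers, label 0
  }
  structure(list(orientations = ori, fractions = frac, n_fibers = nfib,
                 labels = labels, voxel_size = voxel_size, seed = seed),
            class = "fiber_config")
}

#' Simulate single-shell diffusion signal from a fiber configuration
#'
#' Each fibered voxel contributes
#' `S(g) = sum_k f_k exp(-b (lambda_perp + (lambda_par - lambda_perp) (g . u_k)^2))`
#' and fiber-free voxels decay isotropically with diffusivity `d_iso`
#' (free-water default). The b = 0 signal is exactly 1, so the simulated
#' volumes are attenuations.
#'
#' @param config A [make_phantom()] fiber configuration.
#' @param response A [response_function()].
#' @param scheme A single-shell [gradient_scheme()].
#' @param d_iso Isotropic diffusivity for fiber-free voxels, mm^2/s.
#' @return An object of class `dwi_volume`: list with 4D `data`
#'   `(x, y, z, volume)`, `scheme`, `voxel_size`.
#' @export
simulate_signal <- function(config, response = response_function(),
                            scheme = make_gradient_scheme(),
                            d_iso = 3.0e-3) {
  stopifnot(inherits(config, "fiber_config"),
            inherits(response, "response_function"),
            inherits(scheme, "gradient_scheme"))
  b <- check_single_shell(scheme)
  sh_ix <- shell_indices(scheme)
  g <- scheme$bvecs[sh_ix, , drop = FALSE]
  nvol <- length(scheme$bvals)
  d <- dim(config$fractions)[1:3]
  nv <- prod(d)
  lam_perp <- response$lambda_perp
  dl <- response$lambda_par - lam_perp

  sig <- matrix(0, nv, length(sh_ix))
  fr <- matrix(config$fractions, nv, 5)
  has_fiber <- matrix(config$n_fibers, nv) > 0
  for (k in 1:5) {
    sel <- fr[, k] > 0
    if (!any(sel)) next
    u <- matrix(config$orientations[, , , k, ], nv, 3)[sel, , drop = FALSE]
    ct2 <- (u %*% t(g))^2
    sig[sel, ] <- sig[sel, ] +
      fr[sel, k] * exp(-b * (lam_perp + dl * ct2))
  }
  sig[!has_fiber, ] <- exp(-b * d_iso)

  data <- array(1, c(d, nvol))
  data[, , , sh_ix] <- array(sig, c(d, length(sh_ix)))
  structure(list(data = data, scheme = scheme,
                 voxel_size = config$voxel_size),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %dx%dx%d, %d volumes, voxel %.4g mm\n",
              d[1], d[2], d[3], d[4], x$voxel_size))
  invisible(x)
}

#' Add seeded Rician (or Gaussian) noise to a DWI volume
#'
#' The Rician model takes the magnitude of the signal after independent
#' Gaussian corruption of real and imaginary channels,
#' `|S + sigma (e1 + i e2)|` with `sigma = 1 / snr` — the SNR convention of a
#' unit noiseless b0 signal. A pure-Gaussian model is provided for
#' oracle/statistical tests.
#'
#' @param dwi A `dwi_volume`.
#' @param snr Positive signal-to-noise ratio `1 / sigma_g`.
#' @param seed Integer seed; one realization per call.
#' @param model `"rician"` or `"gaussian"`.
#' @return A `dwi_volume` with noisy data.
#' @export
add_noise <- function(dwi, snr, seed = 1, model = c("rician", "gaussian")) {
  stopifnot(inherits(dwi, "dwi_volume"))
  model <- match.arg(model)
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  sigma <- 1 / snr
  n <- length(dwi$data)
  noisy <- withr::with_seed(seed, {
    if (model == "rician") {
      sqrt((dwi$data + sigma * stats::rnorm(n))^2 +
             (sigma * stats::rnorm(n))^2)
    } else {
      dwi$data + sigma * stats::rnorm(n)
    }
  })
  dwi$data <- array(noisy, dim(dwi$data))
  dwi
}

#' Block-average downsampling of a DWI volume
#'
#' Averages the signal in each non-overlapping `factor^3` voxel region of
#' every diffusion volume, emulating acquisition at `factor`-times larger
#' voxels; voxel size is multiplied by `factor` (1.25 mm -> 2.5 mm at the
#' default factor 2).
#'
#' @param dwi A `dwi_volume` (spatial dims divisible by `factor`).
#' @param factor Integer downsampling factor per axis.
#' @return A `dwi_volume` at reduced resolution.
#' @export
block_downsample <- function(dwi, factor = 2L) {
  stopifnot(inherits(dwi, "dwi_volume"))
  factor <- as.integer(factor)
  d <- dim(dwi$data)
  if (any(d[1:3] %% factor != 0L))
    stop("spatial dimensions must be divisible by the downsampling factor",
         call. = FALSE)
  out_d <- d[1:3] %/% factor
  a <- array(dwi$data, c(factor, out_d[1], factor, out_d[2],
                         factor, out_d[3], d[4]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6, 7))
  m <- colMeans(matrix(a, factor^3, prod(out_d) * d[4]))
  structure(list(data = array(m, c(out_d, d[4])), scheme = dwi$scheme,
                 voxel_size = dwi$voxel_size * factor),
            class = "dwi_volume")
}

#' SNR of block-averaged low-resolution data
#'
#' Low-resolution acquisitions enjoy an 8-fold SNR gain from the 8-times
#' larger voxel volume and a further `sqrt(2)` gain from measurement
#' repetition: `SNR_lr = 8 * sqrt(2) * SNR_hr` (about 56.6 for
#' `snr_hr = 5`). Both factors are exposed.
#'
#' @param snr_hr High-resolution SNR (> 0).
#' @param volume_gain Voxel-volume SNR factor (default 8 for 2x2x2).
#' @param repeat_gain Repetition SNR factor (default `sqrt(2)`).
#' @return `volume_gain * repeat_gain * snr_hr`.
#' @export
lowres_snr <- function(snr_hr, volume_gain = 8, repeat_gain = sqrt(2)) {
  if (any(!is.finite(snr_hr)) || any(snr_hr <= 0))
    stop("`snr_hr` must be > 0", call. = FALSE)
  volume_gain * repeat_gain * snr_hr
}
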