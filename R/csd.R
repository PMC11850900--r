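#' CSD configuration
#'
#' Hyperparameters of the constrained spherical deconvolution fit. The
#' defaults follow standard published CSD practice: `lambda = 1` (scaled
#' internally by the response magnitude and matrix sizes), amplitude
#' threshold `tau = 0.1` of the mean initial fODF amplitude, up to 50
#' constraint-set iterations, and a ~321-direction hemisphere constraint
#' tessellation.
#'
#' @param lmax Even SH order of the fODF (default 8).
#' @param lambda Nonnegative regularization weight.
#' @param tau Amplitude-threshold fraction in (0, 1).
#' @param max_iter Maximum constraint-set iterations (>= 1).
#' @param constraint_tess Hemisphere [sphere_tessellation()] for the
#'   nonnegativity constraint.
#' @return A list of class `csd_config`.
#' @export
csd_config <- function(lmax = 8, lambda = 1, tau = 0.1, max_iter = 50,
                       constraint_tess = constraint_tessellation()) {
  check_lmax(lmax)
  stopifnot(lambda >= 0, tau > 0, tau < 1, max_iter >= 1,
            inherits(constraint_tess, "sphere_tess"))
  structure(list(lmax = lmax, lambda = lambda, tau = tau,
                 max_iter = max_iter, constraint_tess = constraint_tess),
            class = "csd_config")
}

#' Estimate a single-fiber response from masked voxels
#'
#' Fits a diffusion tensor (log-linear least squares) to every masked voxel
#' and averages the sorted eigenvalues, returning a prolate
#' [response_function()] with the mean first eigenvalue as the axial and the
#' mean of the remaining two as the radial diffusivity. The mask should
#' select highly anisotropic, coherent single-fiber voxels; no anatomical
#' localization is attempted.
#'
#' @param dwi A `dwi_volume` with at least one b = 0 volume.
#' @param mask 3D logical array of voxels to use.
#' @return A [response_function()].
#' @export
estimate_response <- function(dwi, mask) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  b0 <- b0_indices(scheme)
  if (length(b0) == 0) stop("no b = 0 volume in the data", call. = FALSE)
  sh_ix <- shell_indices(scheme)
  d <- dim(dwi$data)[1:3]
  stopifnot(all(dim(mask) == d))
  g <- scheme$bvecs[sh_ix, , drop = FALSE]
  b <- scheme$bvals[sh_ix]
  # design for log(S/S0) = -b g' D g
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                  2 * g[, 2] * g[, 3])
  flat <- matrix(dwi$data, prod(d), dim(dwi$data)[4])
  sel <- which(mask)
  s0 <- rowMeans(flat[sel, b0, drop = FALSE])
  ok <- is.finite(s0) & s0 > 0
  sel <- sel[ok]; s0 <- s0[ok]
  if (!length(sel)) stop("no usable voxels in the response mask", call. = FALSE)
  att <- pmax(flat[sel, sh_ix, drop = FALSE] / s0, 1e-6)
  coefs <- qr.coef(qr(X), t(log(att)))          # 6 x n_vox
  evs <- apply(coefs, 2, function(v) {
    D <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
    sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  })
  lam_par <- mean(evs[1, ])
  lam_perp <- max(mean(evs[2:3, ]), 1e-6)
  response_function(lambda_par = max(lam_par, lam_perp + 1e-9),
                    lambda_perp = lam_perp)
}

#' Per-degree response coefficients
#'
#' Computes the `m = 0` SH coefficients `r_l` of the axially symmetric
#' single-fiber response signal on the shell,
#' `r_l = 2 pi * int_{-1}^{1} R(t) Nbar_l^0(t) dt` (Gauss-Legendre
#' quadrature), together with the rotational-harmonic factors
#' `r_l * sqrt(4 pi / (2 l + 1))` by which convolution scales each fODF
#' coefficient of degree `l` (Funk-Hecke theorem). An isotropic response
#' (`lambda_par == lambda_perp`) has `r_l = 0` for all `l >= 2`.
#'
#' @param response A [response_function()].
#' @param scheme A single-shell [gradient_scheme()] (sets the b-value), or a
#'   single b-value.
#' @param lmax Even maximum degree.
#' @return A list with `l` (degrees), `rl` (SH coefficients) and `rh`
#'   (rotational-harmonic convolution factors).
#' @export
response_to_rl <- function(response, scheme, lmax = 8) {
  stopifnot(inherits(response, "response_function"))
  check_lmax(lmax)
  b <- if (inherits(scheme, "gradient_scheme")) check_single_shell(scheme)
       else as.numeric(scheme)
  gl <- pracma::gaussLegendre(64, -1, 1)
  t <- gl$x
  R <- exp(-b * (response$lambda_perp +
                   (response$lambda_par - response$lambda_perp) * t^2))
  p <- norm_assoc_legendre(t, lmax)
  ls <- seq(0L, lmax, by = 2L)
  rl <- vapply(ls, function(l) {
    2 * pi * sum(gl$w * R * p[[l + 1L]][[1L]])
  }, numeric(1))
  list(l = ls, rl = rl, rh = rl * sqrt(4 * pi / (2 * ls + 1)))
}

#' Forward convolution matrix of the CSD model
#'
#' Maps fODF SH coefficients to the predicted attenuation at the
#' diffusion-weighted gradient directions: the SH design matrix at the
#' gradients with each column scaled by the rotational-harmonic factor of its
#' degree.
#'
#' @inheritParams response_to_rl
#' @return `n_gradients x K` matrix.
#' @export
forward_conv_matrix <- function(response, scheme, lmax = 8) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  rh <- response_to_rl(response, scheme, lmax)
  g <- scheme$bvecs[shell_indices(scheme), , drop = FALSE]
  B <- build_basis(g, lmax)
  idx <- sh_index_table(lmax)
  fac <- rh$rh[match(idx$l, rh$l)]
  B * rep(fac, each = nrow(B))
}

#' Constrained spherical deconvolution of a single-shell DWI volume
#'
#' Estimates per-voxel fODF SH coefficients (order `lmax`, 45 coefficients at
#' the default 8) by iteratively reweighted Tikhonov-constrained
#' deconvolution: minimize `||F a - s||^2 + lambda_eff^2 ||B_neg a||^2` where
#' `B_neg` holds the constraint-tessellation rows whose current fODF
#' amplitude falls below `tau` times the mean amplitude of an initial
#' unconstrained order-4 fit, iterating until the constrained set is
#' unchanged. Signal is normalized to attenuation by the per-voxel mean b0.
#'
#' @param dwi A `dwi_volume` containing at least one b = 0 volume and a
#'   single nonzero shell.
#' @param response A [response_function()].
#' @param config A [csd_config()].
#' @param mask Optional 3D logical array of voxels to fit (default: all).
#' @return A list of class `sh_fit`: `sh` (4D array `(x, y, z, K)` of full SH
#'   coefficients), `valid` (3D logical: masked-in voxels with positive b0),
#'   `lmax`, `response`, `config`.
#' @export
fit_csd <- function(dwi, response = response_function(), config = csd_config(),
                    mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  b0 <- b0_indices(scheme)
  if (length(b0) == 0) stop("no b = 0 volume in the data", call. = FALSE)
  check_single_shell(scheme)
  sh_ix <- shell_indices(scheme)
  d <- dim(dwi$data)[1:3]
  nv <- prod(d)
  if (is.null(mask)) mask <- array(TRUE, d)
  stopifnot(all(dim(mask) == d))

  flat <- matrix(dwi$data, nv, dim(dwi$data)[4])
  s0 <- rowMeans(flat[, b0, drop = FALSE])
  valid <- as.vector(mask) & is.finite(s0) & s0 > 0
  K <- sh_basis_size(config$lmax)
  out <- matrix(0, nv, K)

  if (any(valid)) {
    atten <- t(flat[valid, sh_ix, drop = FALSE] / s0[valid])
    Fm <- forward_conv_matrix(response, scheme, config$lmax)
    Bc <- build_basis(config$constraint_tess, config$lmax)
    # initial estimate: unconstrained fit truncated at l = 4
    n4 <- sh_basis_size(4)
    F4 <- Fm[, seq_len(n4), drop = FALSE]
    A0 <- qr.coef(qr(F4), atten)
    Ainit <- rbind(A0, matrix(0, K - n4, ncol(A0)))
    rh0 <- response_to_rl(response, scheme, config$lmax)$rh[1]
    lambda_eff <- config$lambda * K * rh0 / nrow(Bc)
    A <- csd_fit_batch_cpp(atten, Fm, Bc, Ainit, lambda_eff, config$tau,
                           as.integer(config$max_iter))
    out[valid, ] <- t(A)
  }
  structure(list(sh = array(out, c(d, K)), valid = array(valid, d),
                 lmax = config$lmax, response = response, config = config),
            class = "sh_fit")
}
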