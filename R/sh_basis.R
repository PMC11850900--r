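#' Real symmetric spherical-harmonic basis
#'
#' The fODF representation used throughout the package is the real, symmetric
#' (even-order) spherical-harmonic basis popularized in q-ball imaging, indexed
#' by degree `l` ascending and order `m` ascending within each degree
#' (`m = -l, ..., l`). With the complex harmonics
#' `Y_l^m(theta, phi) = Nbar_l^m P_l^m(cos theta) exp(i m phi)` (Condon-Shortley
#' phase included), the real basis element for index `(l, m)` is
#' `sqrt(2) Re(Y_l^|m|)` for `m < 0`, `Y_l^0` for `m = 0`, and
#' `sqrt(2) Im(Y_l^m)` for `m > 0`. This basis is orthonormal on the sphere and
#' its first element is the constant `1 / sqrt(4 pi)`.
#'
#' @name sh-basis
NULL

#' Number of even-order SH basis functions
#'
#' @param lmax Even maximum degree (`lmax >= 2`).
#' @return `(lmax + 1) * (lmax + 2) / 2`; 45 for `lmax = 8`.
#' @export
sh_basis_size <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1 || !is.finite(lmax) || lmax < 2 || lmax %% 2 != 0)
    stop("`lmax` must be a single even integer >= 2", call. = FALSE)
  invisible(lmax)
}

#' (l, m) index table of the basis
#'
#' @inheritParams sh_basis_size
#' @return A tibble with columns `l` (even, ascending) and `m`
#'   (`-l, ..., l` ascending within each degree), one row per basis function.
#' @export
sh_index_table <- function(lmax) {
  check_lmax(lmax)
  ls <- seq(0L, lmax, by = 2L)
  tibble::tibble(
    l = rep(ls, times = 2L * ls + 1L),
    m = unlist(lapply(ls, function(l) seq(-l, l)))
  )
}

# Fully normalized associated Legendre functions Nbar_l^m P_l^m(x) for
# m = 0..lmax and l = m..lmax, with the Condon-Shortley phase, via the
# standard stable three-term recursion. Returns a list indexed by [l+1][m+1].
norm_assoc_legendre <- function(x, lmax) {
  p <- vector("list", lmax + 1L)
  for (l in 0:lmax) p[[l + 1L]] <- vector("list", l + 1L)
  s <- sqrt(pmax(0, 1 - x^2))
  p[[1L]][[1L]] <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in seq_len(lmax)) {    # P_m^m from P_{m-1}^{m-1}
    p[[m + 1L]][[m + 1L]] <- -sqrt((2 * m + 1) / (2 * m)) * s *
      p[[m]][[m]]
  }
  for (m in 0:(lmax - 1L)) {    # P_{m+1}^m
    p[[m + 2L]][[m + 1L]] <- x * sqrt(2 * m + 3) * p[[m + 1L]][[m + 1L]]
  }
  for (m in 0:lmax) {
    if (m + 2L > lmax) next
    for (l in (m + 2L):lmax) {
      a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
      p[[l + 1L]][[m + 1L]] <- a *
        (x * p[[l]][[m + 1L]] - b * p[[l - 1L]][[m + 1L]])
    }
  }
  p
}

#' Evaluate the real SH basis at a set of directions
#'
#' @param directions Either a [sphere_tessellation()] object or an `n x 3`
#'   matrix of unit vectors.
#' @param lmax Even maximum degree (default 8, giving 45 basis functions).
#' @return An `n x K` design matrix (`K = sh_basis_size(lmax)`) whose column
#'   `k` holds basis function `k` (see [sh_index_table()]) evaluated at each
#'   direction. Carries attributes `lmax` and `basis = "real_symmetric"`.
#' @examples
#' B <- build_basis(sphere_tessellation(1), lmax = 4)
#' dim(B)
#' @export
build_basis <- function(directions, lmax = 8) {
  check_lmax(lmax)
  dirs <- if (inherits(directions, "sphere_tess")) directions$dirs
          else as.matrix(directions)
  if (ncol(dirs) != 3 || nrow(dirs) < 1)
    stop("`directions` must be a nonempty n x 3 matrix", call. = FALSE)
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) dirs <- dirs / nrm
  x <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  p <- norm_assoc_legendre(x, lmax)
  idx <- sh_index_table(lmax)
  B <- matrix(0, nrow(dirs), nrow(idx))
  for (k in seq_len(nrow(idx))) {
    l <- idx$l[k]; m <- idx$m[k]
    plm <- p[[l + 1L]][[abs(m) + 1L]]
    B[, k] <- if (m < 0) sqrt(2) * plm * cos(abs(m) * phi)
              else if (m == 0) plm
              else sqrt(2) * plm * sin(m * phi)
  }
  attr(B, "lmax") <- as.integer(lmax)
  attr(B, "basis") <- "real_symmetric"
  B
}

#' Product quadrature rule on the sphere
#'
#' Gauss-Legendre nodes in `cos(theta)` crossed with equally spaced azimuths:
#' exact (to machine precision) for spherical polynomials of degree up to
#' `n_theta * 2 - 1` in `cos(theta)` and azimuthal frequency below
#' `n_phi / 2`, hence for all products of order-8 SH at the defaults. Used
#' for integral and variance oracles.
#'
#' @param n_theta Number of polar nodes.
#' @param n_phi Number of azimuthal nodes.
#' @return A list with `dirs` (`n x 3` unit vectors) and `weights` (summing
#'   to `4 pi`).
#' @export
sphere_quadrature <- function(n_theta = 32, n_phi = 64) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, n_theta)
  list(dirs = cbind(st * cos(ph), st * sin(ph), ct),
       weights = rep(gl$w, each = n_phi) * (2 * pi / n_phi))
}

#' Least-squares SH fit of per-direction samples
#'
#' Projects sampled values on the tessellation onto the basis by ordinary
#' least squares. Band-limited functions round-trip exactly (up to numerical
#' precision) provided the system is overdetermined.
#'
#' @param samples Numeric vector (one value per design row) or an
#'   `n_dirs x n_signals` matrix.
#' @param design Design matrix from [build_basis()].
#' @return Coefficient vector (or `K x n_signals` matrix) in the basis order.
#' @export
fit_sh <- function(samples, design) {
  samples <- as.matrix(samples)
  if (nrow(samples) != nrow(design))
    stop("number of samples must equal number of design directions",
         call. = FALSE)
  if (nrow(design) < ncol(design))
    stop("underdetermined SH fit: need at least as many directions as basis functions",
         call. = FALSE)
  coef <- qr.coef(qr(design), samples)
  if (ncol(coef) == 1L) coef <- drop(coef)
  coef
}

#' Evaluate SH coefficients on a tessellation
#'
#' @param coeffs Coefficient vector (length `ncol(design)`) or `K x n` matrix.
#' @inheritParams fit_sh
#' @return Per-direction values (vector or `n_dirs x n` matrix).
#' @export
evaluate_sh <- function(coeffs, design) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != ncol(design))
    stop("coefficient length does not match design matrix columns",
         call. = FALSE)
  out <- design %*% coeffs
  if (ncol(out) == 1L) out <- drop(out)
  out
}

#' fODF probability normalization
#'
#' Divides all SH coefficients by `sqrt(4 pi) * A0`, where `A0` is the first
#' (constant-term) coefficient, and drops the now-redundant first entry: the
#' implied constant coefficient of the normalized fODF is `1 / sqrt(4 pi)`, so
#' its integral over the sphere is exactly 1. For `lmax = 8` the 45-vector
#' becomes a 44-vector. Voxels with `|A0| <= eps` (background, CSF dropouts)
#' are degenerate: the result is an all-zero vector with attribute
#' `valid = FALSE`.
#'
#' @param coeffs Full coefficient vector (length `sh_basis_size(lmax)`).
#' @param eps Degeneracy threshold on `|A0|`.
#' @return Normalized coefficient vector of length `length(coeffs) - 1` with a
#'   logical attribute `valid`.
#' @seealso [denormalize_fodf()]
#' @export
normalize_fodf <- function(coeffs, eps = 1e-8) {
  coeffs <- as.numeric(coeffs)
  a0 <- coeffs[1]
  if (!is.finite(a0) || abs(a0) <= eps) {
    out <- numeric(length(coeffs) - 1L)
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- coeffs[-1] / (sqrt(4 * pi) * a0)
  attr(out, "valid") <- TRUE
  out
}

#' Invert the fODF probability normalization
#'
#' Prepends the implied constant coefficient `1 / sqrt(4 pi)`, recovering a
#' full coefficient vector whose fODF integrates to 1.
#'
#' @param coeffs Normalized coefficient vector (length `K - 1`).
#' @return Full coefficient vector of length `K`.
#' @export
denormalize_fodf <- function(coeffs) {
  c(1 / sqrt(4 * pi), as.numeric(coeffs))
}

#' Normalize a 4D SH coefficient volume
#'
#' Applies [normalize_fodf()] voxelwise to a 4D array with the coefficient
#' index on the 4th axis, carrying a per-voxel validity mask for degenerate
#' voxels (normalized coefficients set to zero there).
#'
#' @param sh 4D array `(x, y, z, K)` of full SH coefficients.
#' @param eps Degeneracy threshold on `|A0|`.
#' @return A list with `sh` (4D array `(x, y, z, K - 1)`) and `valid`
#'   (3D logical array).
#' @export
normalize_sh_volume <- function(sh, eps = 1e-8) {
  stopifnot(length(dim(sh)) == 4)
  d <- dim(sh)
  flat <- matrix(sh, prod(d[1:3]), d[4])
  a0 <- flat[, 1]
  valid <- is.finite(a0) & abs(a0) > eps
  scale <- ifelse(valid, 1 / (sqrt(4 * pi) * a0), 0)
  out <- flat[, -1, drop = FALSE] * scale
  out[!valid, ] <- 0
  list(sh = array(out, c(d[1:3], d[4] - 1L)),
       valid = array(valid, d[1:3]))
}

#' @rdname normalize_sh_volume
#' @param sh_norm 4D array `(x, y, z, K - 1)` of normalized coefficients.
#' @export
denormalize_sh_volume <- function(sh_norm) {
  stopifnot(length(dim(sh_norm)) == 4)
  d <- dim(sh_norm)
  out <- array(0, c(d[1:3], d[4] + 1L))
  out[, , , 1] <- 1 / sqrt(4 * pi)
  out[, , , -1] <- sh_norm
  out
}
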