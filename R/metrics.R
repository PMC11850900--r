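#' Generalized anisotropy from normalized SH coefficients
#'
#' The variance of the fODF values over the sphere follows analytically from
#' the SH expansion: for a probability-normalized fODF (implied constant
#' coefficient `1/sqrt(4 pi)`), `V_Y = sum(a^2) / (4 pi)` over the
#' degree >= 2 coefficients. The generalized anisotropy index is
#' `GA = tanh(V_Y)`, zero for an isotropic voxel and strictly increasing in
#' the magnitude of every coefficient.
#'
#' @param coeffs Normalized coefficient vector (length `K - 1`), or a matrix
#'   with one voxel per row.
#' @return GA value(s) in `[0, 1)`.
#' @export
generalized_anisotropy <- function(coeffs) {
  if (is.matrix(coeffs)) tanh(rowSums(coeffs^2) / (4 * pi))
  else tanh(sum(coeffs^2) / (4 * pi))
}

#' @rdname generalized_anisotropy
#' @param sh_norm 4D array `(x, y, z, K - 1)` of normalized SH coefficients.
#' @return For `ga_map()`: a 3D array of GA values.
#' @export
ga_map <- function(sh_norm) {
  stopifnot(length(dim(sh_norm)) == 4)
  d <- dim(sh_norm)
  array(generalized_anisotropy(matrix(sh_norm, prod(d[1:3]), d[4])), d[1:3])
}

# separable box filter with mirror boundary, window w (odd), along all 3 axes
box_filter3 <- function(vol, w) {
  half <- (w - 1L) %/% 2L
  one_axis <- function(M, n) {
    idx <- outer(seq_len(n), -half:half, `+`)
    idx <- matrix(mirror_index(idx, n), n)
    out <- matrix(0, n, ncol(M))
    for (k in seq_len(w)) out <- out + M[idx[, k], , drop = FALSE]
    out / w
  }
  d <- dim(vol)
  v <- array(one_axis(matrix(vol, d[1], d[2] * d[3]), d[1]), d)
  a <- aperm(v, c(2, 1, 3))
  v <- aperm(array(one_axis(matrix(a, d[2], d[1] * d[3]), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  a <- aperm(v, c(3, 1, 2))
  aperm(array(one_axis(matrix(a, d[3], d[1] * d[2]), d[3]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Structural similarity of two 3D maps
#'
#' Mean SSIM with a uniform cubic window (default 7^3), unbiased local
#' (co)variances, and stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where
#' `L` is the dynamic range. Window-sized margins are cropped before
#' averaging.
#'
#' @param x,y 3D arrays of equal dimensions.
#' @param data_range Dynamic range `L`; defaults to `max(x) - min(x)` of the
#'   first (reference) array.
#' @param window Odd window edge length.
#' @return Mean SSIM value.
#' @export
ssim3d <- function(x, y, data_range = NULL, window = 7L) {
  stopifnot(all(dim(x) == dim(y)), window %% 2 == 1)
  if (is.null(data_range)) data_range <- max(x) - min(x)
  if (data_range <= 0) return(NA_real_)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  np <- window^3
  corr <- np / (np - 1)  # unbiased local moments
  ux <- box_filter3(x, window); uy <- box_filter3(y, window)
  uxx <- box_filter3(x * x, window); uyy <- box_filter3(y * y, window)
  uxy <- box_filter3(x * y, window)
  vx <- corr * (uxx - ux^2); vy <- corr * (uyy - uy^2)
  cxy <- corr * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  half <- (window - 1L) %/% 2L
  d <- dim(x)
  if (all(d > 2 * half)) {
    S <- S[(half + 1):(d[1] - half), (half + 1):(d[2] - half),
           (half + 1):(d[3] - half)]
  }
  mean(S)
}

#' Per-coefficient similarity metrics between SH volumes
#'
#' Compares a predicted (upsampled) SH volume against ground truth, per SH
#' coefficient index and optionally per tissue label: MSE, Pearson
#' correlation and MAE over masked voxels, plus PSNR and SSIM computed on
#' each coefficient's 3D map (SSIM/PSNR use the per-coefficient ground-truth
#' dynamic range and are reported for the overall label only). Constant maps
#' have undefined correlation, reported as `NA`.
#'
#' @param gt_sh,pred_sh Aligned 4D arrays `(x, y, z, C)`.
#' @param mask Optional 3D logical array.
#' @param labels Optional 3D integer label array; metrics are then also
#'   reported per label.
#' @return Tibble with `metric`, `coef` (1-based SH index), `label`
#'   (`"all"` or the label value), `value`.
#' @export
sh_similarity <- function(gt_sh, pred_sh, mask = NULL, labels = NULL) {
  stopifnot(length(dim(gt_sh)) == 4, all(dim(gt_sh) == dim(pred_sh)))
  d <- dim(gt_sh)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  sel <- which(mask)
  G <- matrix(gt_sh, prod(d[1:3]), d[4])
  P <- matrix(pred_sh, prod(d[1:3]), d[4])

  groups <- list(all = sel)
  if (!is.null(labels)) {
    lab <- as.vector(labels)[sel]
    for (lv in sort(unique(lab)))
      groups[[as.character(lv)]] <- sel[lab == lv]
  }
  rows <- list()
  for (gname in names(groups)) {
    ix <- groups[[gname]]
    g <- G[ix, , drop = FALSE]; p <- P[ix, , drop = FALSE]
    diff <- p - g
    mse <- colMeans(diff^2)
    mae <- colMeans(abs(diff))
    cors <- vapply(seq_len(d[4]), function(k) {
      if (stats::sd(g[, k]) == 0 || stats::sd(p[, k]) == 0) NA_real_
      else stats::cor(g[, k], p[, k])
    }, numeric(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = rep(c("mse", "mae", "correlation"), each = d[4]),
      coef = rep(seq_len(d[4]), 3),
      label = gname,
      value = c(mse, mae, cors))
  }
  # map-level supplementary metrics on the full (masked-out voxels zeroed)
  # coefficient maps
  psnr <- numeric(d[4]); ssim <- numeric(d[4])
  for (k in seq_len(d[4])) {
    gk <- array(G[, k], d[1:3]); pk <- array(P[, k], d[1:3])
    rng <- max(gk[mask]) - min(gk[mask])
    msek <- mean((pk[mask] - gk[mask])^2)
    psnr[k] <- if (rng > 0 && msek > 0) 10 * log10(rng^2 / msek) else NA_real_
    ssim[k] <- ssim3d(gk, pk, data_range = if (rng > 0) rng else NULL)
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = rep(c("psnr", "ssim"), each = d[4]),
    coef = rep(seq_len(d[4]), 2), label = "all",
    value = c(psnr, ssim))
  do.call(rbind, rows)
}

#' Plot per-coefficient similarity metrics
#'
#' @param metrics Tibble from [sh_similarity()] (optionally with an added
#'   `method` column when comparing several upsamplers).
#' @param which_metric Metric to plot.
#' @return A ggplot object.
#' @export
plot_sh_metrics <- function(metrics, which_metric = "mse") {
  df <- metrics[metrics$metric == which_metric, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$coef, y = .data$value))
  if ("method" %in% names(df))
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$method))
  else p <- p + ggplot2::geom_line()
  p + ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "SH coefficient index", y = which_metric)
}
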