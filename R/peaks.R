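#' Extract fODF peaks
#'
#' Finds local maxima of the fODF over the tessellation adjacency
#' (antipodally deduplicated, since the tessellation is a hemisphere
#' representation), keeps those with amplitude at least `rel_thresh` times
#' the global maximum, greedily suppresses maxima within `min_sep` degrees of
#' an already accepted stronger peak, and truncates to `max_peaks`. The
#' defaults (0.5 / 25 degrees / 5) are the extraction settings used for all
#' peak statistics in the package. Equal-amplitude candidates are ordered
#' lexicographically by direction components (deterministic tie-break);
#' extraction is invariant to global positive rescaling of the fODF.
#'
#' @param fodf Either a numeric vector of amplitudes on `tess$dirs`, or SH
#'   coefficients (full length `sh_basis_size(lmax)`), evaluated internally.
#' @param tess A [sphere_tessellation()] with adjacency.
#' @param rel_thresh Relative amplitude threshold in (0, 1].
#' @param min_sep Minimum separation angle between peaks, degrees.
#' @param max_peaks Maximum number of peaks.
#' @param design Optional precomputed [build_basis()] matrix for `tess`.
#' @return An object of class `peak_set`: `directions` (k x 3 hemisphere unit
#'   vectors), `amplitudes` (descending).
#' @export
extract_peaks <- function(fodf, tess = peak_tessellation(), rel_thresh = 0.5,
                          min_sep = 25, max_peaks = 5, design = NULL) {
  stopifnot(inherits(tess, "sphere_tess"))
  n <- nrow(tess$dirs)
  amp <- if (length(fodf) == n) as.numeric(fodf) else {
    if (is.null(design)) design <- build_basis(tess, lmax_from_size(length(fodf)))
    as.numeric(design %*% fodf)
  }
  peak_set(peaks_from_amplitudes(amp, tess, rel_thresh, min_sep, max_peaks,
                                 neighbor_matrix(tess)))
}

lmax_from_size <- function(k) {
  l <- (-3 + sqrt(1 + 8 * k)) / 2
  if (abs(l - round(l)) > 1e-9 || round(l) %% 2 != 0)
    stop("length is not a valid even-order SH basis size", call. = FALSE)
  as.integer(round(l))
}

peak_set <- function(x) {
  structure(list(directions = x$directions, amplitudes = x$amplitudes),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)\n", n_peaks(x)))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param x A `peak_set`.
#' @export
n_peaks <- function(x) if (is.null(x$directions)) 0L else nrow(x$directions)

# neighbor index matrix (n x max_degree) padded with self indices, cached on
# the tessellation object via an attribute-free external cache
neighbor_matrix <- function(tess) {
  key <- paste0("nb", tess$subdiv, "_", nrow(tess$dirs))
  nb <- .tess_cache[[key]]
  if (is.null(nb)) {
    deg <- lengths(tess$adj)
    nb <- matrix(rep(seq_along(tess$adj), max(deg)), ncol = max(deg))
    for (i in seq_along(tess$adj)) {
      a <- tess$adj[[i]]
      if (length(a)) nb[i, seq_along(a)] <- a
    }
    .tess_cache[[key]] <- nb
  }
  nb
}

# core extraction from an amplitude vector; `nb` is the neighbor matrix
peaks_from_amplitudes <- function(amp, tess, rel_thresh, min_sep, max_peaks,
                                  nb) {
  gmax <- max(amp)
  if (!is.finite(gmax) || gmax <= 0)
    return(list(directions = matrix(0, 0, 3), amplitudes = numeric(0)))
  is_max <- amp > 0
  for (j in seq_len(ncol(nb))) is_max <- is_max & amp >= amp[nb[, j]]
  cand <- which(is_max & amp >= rel_thresh * gmax)
  if (!length(cand))
    return(list(directions = matrix(0, 0, 3), amplitudes = numeric(0)))
  dirs <- tess$dirs[cand, , drop = FALSE]
  o <- order(-amp[cand], dirs[, 1], dirs[, 2], dirs[, 3])
  cand <- cand[o]; dirs <- dirs[o, , drop = FALSE]
  cos_sep <- cos(min_sep * pi / 180)
  acc <- integer(0)
  for (i in seq_along(cand)) {
    if (length(acc) >= max_peaks) break
    if (length(acc) == 0 ||
        all(abs(dirs[acc, , drop = FALSE] %*% dirs[i, ]) < cos_sep))
      acc <- c(acc, i)
  }
  list(directions = dirs[acc, , drop = FALSE],
       amplitudes = amp[cand][acc])
}

#' Peak extraction over a whole SH volume
#'
#' Vectorized evaluation of fODF amplitudes in voxel chunks followed by
#' per-voxel peak selection. Degenerate or unmasked voxels yield zero peaks.
#'
#' @param sh 4D array of full SH coefficients `(x, y, z, K)`.
#' @param tess A [sphere_tessellation()].
#' @param mask Optional 3D logical array.
#' @inheritParams extract_peaks
#' @param chunk Number of voxels evaluated per block.
#' @return A list of class `peak_volume`: `directions` `(x, y, z, max_peaks, 3)`,
#'   `amplitudes` `(x, y, z, max_peaks)`, `counts` `(x, y, z)` (zero-padded).
#' @export
peaks_from_sh_volume <- function(sh, tess = peak_tessellation(), mask = NULL,
                                 rel_thresh = 0.5, min_sep = 25, max_peaks = 5,
                                 chunk = 1024L) {
  stopifnot(length(dim(sh)) == 4)
  d <- dim(sh)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  design <- build_basis(tess, lmax_from_size(d[4]))
  nb <- neighbor_matrix(tess)
  nv <- prod(d[1:3])
  flat <- matrix(sh, nv, d[4])
  sel <- which(mask)
  dirs_out <- array(0, c(d[1:3], max_peaks, 3L))
  amps_out <- array(0, c(d[1:3], max_peaks))
  counts <- array(0L, d[1:3])
  dflat <- matrix(dirs_out, nv, max_peaks * 3L)
  aflat <- matrix(amps_out, nv, max_peaks)
  for (start in seq(1, length(sel), by = chunk)) {
    ix <- sel[start:min(start + chunk - 1L, length(sel))]
    A <- tcrossprod(flat[ix, , drop = FALSE], design)  # voxels x dirs
    for (r in seq_along(ix)) {
      pk <- peaks_from_amplitudes(A[r, ], tess, rel_thresh, min_sep,
                                  max_peaks, nb)
      k <- nrow(pk$directions)
      counts[ix[r]] <- k
      if (k > 0) {
        dflat[ix[r], ] <- as.vector(rbind(pk$directions,
                                          matrix(0, max_peaks - k, 3)))
        aflat[ix[r], seq_len(k)] <- pk$amplitudes
      }
    }
  }
  structure(list(directions = array(dflat, c(d[1:3], max_peaks, 3L)),
                 amplitudes = array(aflat, c(d[1:3], max_peaks)),
                 counts = counts, max_peaks = max_peaks),
            class = "peak_volume")
}

#' Ground-truth peak volume from a phantom fiber configuration
#'
#' Converts a [make_phantom()] configuration into the same `peak_volume`
#' layout produced by [peaks_from_sh_volume()], with volume fractions as
#' amplitudes.
#'
#' @param config A `fiber_config`.
#' @return A `peak_volume`.
#' @export
peaks_from_config <- function(config) {
  stopifnot(inherits(config, "fiber_config"))
  structure(list(directions = config$orientations,
                 amplitudes = config$fractions,
                 counts = config$n_fibers, max_peaks = 5L),
            class = "peak_volume")
}

# peak set of one voxel of a peak_volume
voxel_peaks <- function(pv, i, j, k) {
  n <- pv$counts[i, j, k]
  if (n == 0)
    return(peak_set(list(directions = matrix(0, 0, 3),
                         amplitudes = numeric(0))))
  peak_set(list(
    directions = matrix(pv$directions[i, j, k, seq_len(n), ], n, 3),
    amplitudes = pv$amplitudes[i, j, k, seq_len(n)]))
}

#' Mean peak count per tissue label
#'
#' @param peaks A `peak_volume`.
#' @param labels 3D integer array of tissue labels.
#' @param mask Optional 3D logical array.
#' @return Tibble with `label`, `mean_peaks`, `n_voxels`; labels absent from
#'   the mask are omitted.
#' @export
average_peak_count <- function(peaks, labels, mask = NULL) {
  stopifnot(inherits(peaks, "peak_volume"),
            all(dim(labels) == dim(peaks$counts)))
  if (is.null(mask)) mask <- array(TRUE, dim(labels))
  sel <- which(mask)
  lab <- as.vector(labels)[sel]
  cnt <- as.vector(peaks$counts)[sel]
  agg <- tapply(cnt, lab, mean)
  tibble::tibble(label = as.integer(names(agg)),
                 mean_peaks = as.numeric(agg),
                 n_voxels = as.integer(table(lab)[names(agg)]))
}
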