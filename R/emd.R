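#' Exact solution of a small transportation problem
#'
#' Minimum-cost transport between discrete mass distributions, solved with
#' the classic transportation simplex (northwest-corner start, MODI duals,
#' stepping-stone pivots). Supplies are epsilon-perturbed to keep the basis
#' nondegenerate; with the peak-set sizes used here (at most 5 x 5) the
#' perturbation changes the optimum by well under 1e-8.
#'
#' @param cost `n x m` cost matrix.
#' @param supply Nonnegative supplies summing to the demand total.
#' @param demand Nonnegative demands.
#' @return List with `cost` (optimal value) and `flow` (n x m plan).
#' @export
transport_min_cost <- function(cost, supply, demand) {
  cost <- as.matrix(cost)
  n <- length(supply); m <- length(demand)
  stopifnot(nrow(cost) == n, ncol(cost) == m, all(supply >= 0),
            all(demand >= 0), abs(sum(supply) - sum(demand)) < 1e-9)
  eps <- 1e-11
  a <- supply + eps
  b <- demand; b[m] <- b[m] + n * eps

  # northwest-corner basic feasible solution: exactly n + m - 1 cells
  bi <- integer(0); bj <- integer(0); fl <- numeric(0)
  i <- 1L; j <- 1L; ar <- a; br <- b
  while (i <= n && j <= m) {
    f <- min(ar[i], br[j])
    bi <- c(bi, i); bj <- c(bj, j); fl <- c(fl, f)
    ar[i] <- ar[i] - f; br[j] <- br[j] - f
    if (ar[i] <= br[j]) i <- i + 1L else j <- j + 1L
  }

  for (iter in seq_len(500L)) {
    # duals from the spanning tree of basic cells
    u <- rep(NA_real_, n); v <- rep(NA_real_, m); u[bi[1]] <- 0
    repeat {
      done <- TRUE
      for (k in seq_along(bi)) {
        if (!is.na(u[bi[k]]) && is.na(v[bj[k]])) {
          v[bj[k]] <- cost[bi[k], bj[k]] - u[bi[k]]; done <- FALSE
        } else if (is.na(u[bi[k]]) && !is.na(v[bj[k]])) {
          u[bi[k]] <- cost[bi[k], bj[k]] - v[bj[k]]; done <- FALSE
        }
      }
      if (!anyNA(u) && !anyNA(v)) break
      if (done) stop("transportation basis is not spanning", call. = FALSE)
    }
    red <- cost - outer(u, v, "+")
    red[cbind(bi, bj)] <- 0
    kmin <- which.min(red)
    if (red[kmin] >= -1e-12) break
    ei <- (kmin - 1L) %% n + 1L
    ej <- (kmin - 1L) %/% n + 1L

    # unique path from row node ei to column node ej in the basis tree;
    # nodes: rows 1..n, columns n+1..n+m, edges are the basic cells
    nn <- n + m
    adj <- vector("list", nn)
    for (k in seq_along(bi)) {
      r <- bi[k]; c <- n + bj[k]
      adj[[r]] <- c(adj[[r]], k)
      adj[[c]] <- c(adj[[c]], k)
    }
    parent_edge <- rep(NA_integer_, nn)
    parent_node <- rep(NA_integer_, nn)
    visited <- rep(FALSE, nn); visited[ei] <- TRUE
    queue <- ei
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      for (k in adj[[node]]) {
        other <- if (bi[k] == node) n + bj[k] else if (n + bj[k] == node) bi[k] else NA
        if (is.na(other) || visited[other]) next
        visited[other] <- TRUE
        parent_edge[other] <- k; parent_node[other] <- node
        queue <- c(queue, other)
      }
    }
    stopifnot(visited[n + ej])
    path <- integer(0)
    node <- n + ej
    while (node != ei) {
      path <- c(path, parent_edge[node])
      node <- parent_node[node]
    }
    # entering cell takes +theta; along the path from ej back to ei the
    # edges alternate -, +, -, ...
    signs <- rep(c(-1, 1), length.out = length(path))
    minus <- path[signs < 0]
    theta <- min(fl[minus])
    leave <- minus[which.min(fl[minus])]
    fl[path] <- fl[path] + signs * theta
    bi[leave] <- ei; bj[leave] <- ej; fl[leave] <- theta
  }

  flow <- matrix(0, n, m)
  flow[cbind(bi, bj)] <- fl
  list(cost = sum(fl * cost[cbind(bi, bj)]), flow = flow)
}

#' Angular earth mover's distance between two peak sets
#'
#' Peak amplitudes are normalized to unit total mass per set and transported
#' over the ground cost `c(u, v) = acos(|u . v|)` in degrees — the antipodal
#' metric appropriate for orientations, bounded by 90. The returned value is
#' the minimum total angular "work" to morph one orientation distribution
#' into the other: symmetric, nonnegative, zero iff the sets coincide up to
#' antipodal flips and peak order.
#'
#' When exactly one set is empty the distance is defined as 90 (all mass at
#' maximal cost) and flagged with attribute `empty_mismatch = TRUE`; two
#' empty sets have distance 0.
#'
#' @param a,b `peak_set` objects (or lists with `directions`, `amplitudes`).
#' @return Angular work in degrees.
#' @export
angular_emd <- function(a, b) {
  na <- n_peaks(a); nb <- n_peaks(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0)
    return(structure(90, empty_mismatch = TRUE))
  wa <- a$amplitudes / sum(a$amplitudes)
  wb <- b$amplitudes / sum(b$amplitudes)
  # atan2(|u x v|, |u . v|) is exact near 0 where acos(|u . v|) loses
  # precision (identical peaks must cost exactly zero)
  cost <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    u <- a$directions[i, ]
    for (j in seq_len(nb)) {
      v <- b$directions[j, ]
      cr <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      d <- sum(u * v)
      cost[i, j] <- atan2(sqrt(sum(cr^2)), abs(d)) * 180 / pi
    }
  }
  transport_min_cost(cost, wa, wb)$cost
}

#' Voxelwise angular-error map between two peak volumes
#'
#' @param gt_peaks,pred_peaks Aligned `peak_volume` objects.
#' @param mask Optional 3D logical array; voxels outside are invalid.
#' @return A list of class `angular_error_map`: `emd` (3D array, degrees,
#'   `NA` outside the mask), `valid` (3D logical).
#' @export
emd_error_map <- function(gt_peaks, pred_peaks, mask = NULL) {
  stopifnot(inherits(gt_peaks, "peak_volume"),
            inherits(pred_peaks, "peak_volume"))
  d <- dim(gt_peaks$counts)
  if (!all(dim(pred_peaks$counts) == d))
    stop("peak volumes are on different grids", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d)
  emd <- array(NA_real_, d)
  sel <- which(mask)
  idx <- arrayInd(sel, d)
  for (r in seq_along(sel)) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    emd[sel[r]] <- angular_emd(voxel_peaks(gt_peaks, i, j, k),
                               voxel_peaks(pred_peaks, i, j, k))
  }
  structure(list(emd = emd, valid = mask), class = "angular_error_map")
}

#' Fraction of voxels where each method attains the smallest angular error
#'
#' Per masked voxel, every method whose error is within `tol` of the minimum
#' is marked best — ties count for all tied methods, so the fractions can
#' sum to more than 1.
#'
#' @param error_maps Named list of `angular_error_map` objects on one grid.
#' @param mask Optional 3D logical array (intersected with each map's
#'   validity).
#' @param tol Tie tolerance in degrees.
#' @return Tibble with `method` and `fraction`.
#' @export
best_method_fraction <- function(error_maps, mask = NULL, tol = 1e-9) {
  stopifnot(is.list(error_maps), length(error_maps) >= 2,
            !is.null(names(error_maps)))
  d <- dim(error_maps[[1]]$emd)
  for (m in error_maps) stopifnot(all(dim(m$emd) == d))
  if (is.null(mask)) mask <- array(TRUE, d)
  for (m in error_maps) mask <- mask & m$valid
  sel <- which(mask)
  if (!length(sel)) stop("empty evaluation mask", call. = FALSE)
  E <- vapply(error_maps, function(m) m$emd[sel], numeric(length(sel)))
  E <- matrix(E, nrow = length(sel))
  best <- apply(E, 1, min)
  frac <- colMeans(E <= best + tol)
  tibble::tibble(method = names(error_maps), fraction = as.numeric(frac))
}

#' Mean angular error of a map
#' @param map An `angular_error_map`.
#' @param mask Optional extra 3D logical mask.
#' @return Mean EMD in degrees over valid voxels.
#' @export
mean_angular_error <- function(map, mask = NULL) {
  sel <- map$valid
  if (!is.null(mask)) sel <- sel & mask
  mean(map$emd[sel], na.rm = TRUE)
}
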