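# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exhaustive transportation-LP solver: enumerates every basis (spanning tree
# of the bipartite supply/demand graph), solves the tree flows exactly and
# keeps the cheapest feasible one. Only viable for small problems (<= 3 x 3).
brute_transport <- function(cost, a, b) {
  n <- length(a); m <- length(b)
  cells <- expand.grid(i = seq_len(n), j = seq_len(m))
  nb <- n + m - 1
  combs <- utils::combn(nrow(cells), nb)
  rhs <- c(a, b)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    A <- matrix(0, n + m, nb)
    for (c2 in seq_len(nb)) {
      A[cells$i[sel[c2]], c2] <- 1
      A[n + cells$j[sel[c2]], c2] <- 1
    }
    sol <- tryCatch(solve(A[-1, , drop = FALSE], rhs[-1]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    if (abs(sum(sol[cells$i[sel] == 1]) - a[1]) > 1e-9) next
    if (any(sol < -1e-9)) next
    cst <- sum(sol * cost[cbind(cells$i[sel], cells$j[sel])])
    if (cst < best) best <- cst
  }
  best
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

random_peak_set <- function(n) {
  if (n == 0)
    return(list(directions = matrix(0, 0, 3), amplitudes = numeric(0)))
  w <- stats::runif(n, 0.2, 1)
  list(directions = random_unit_vectors(n), amplitudes = w)
}

orientation_cost <- function(ua, ub) {
  acos(pmin(abs(ua %*% t(ub)), 1)) * 180 / pi
}

angle_deg <- function(u, v) acos(min(1, abs(sum(u * v)))) * 180 / pi

# single-shell attenuation of a prolate-tensor fiber population
tensor_signal <- function(g, b, u, resp = response_function()) {
  exp(-b * (resp$lambda_perp +
              (resp$lambda_par - resp$lambda_perp) * (g %*% u)^2))
}

# one-voxel dwi_volume from an attenuation vector (b0 first)
voxel_dwi <- function(s_shell, scheme) {
  nb0 <- sum(scheme$bvals <= 50)
  structure(list(data = array(c(rep(1, nb0), s_shell),
                              c(1, 1, 1, length(scheme$bvals))),
                 scheme = scheme, voxel_size = 1.25),
            class = "dwi_volume")
}

# shared scheme for the suite (built once)
test_scheme <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) sc <<- make_gradient_scheme()
    sc
  }
})
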