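test_that("peak extraction applies threshold, separation and count rules", {
  tess <- peak_tessellation()
  B <- build_basis(tess, 8)
  # single band-limited lobe along z
  a1 <- build_basis(matrix(c(0, 0, 1), 1, 3), 8)[1, ]
  pk <- extract_peaks(a1, tess, design = B)
  expect_equal(n_peaks(pk), 1)
  expect_lt(angle_deg(pk$directions[1, ], c(0, 0, 1)), 3)
  # two lobes with amplitudes 1.0 and 0.4: the weak one is sub-threshold
  ax <- build_basis(matrix(c(1, 0, 0), 1, 3), 8)[1, ]
  pk2 <- extract_peaks(a1 + 0.4 * ax, tess, design = B)
  expect_equal(n_peaks(pk2), 1)
  # ... but both survive a lower threshold
  pk2b <- extract_peaks(a1 + 0.8 * ax, tess, design = B)
  expect_equal(n_peaks(pk2b), 2)
  # two maxima 10 degrees apart merge under the 25-degree separation rule
  u10 <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  a10 <- build_basis(matrix(u10, 1, 3), 8)[1, ]
  pk3 <- extract_peaks(a1 + a10, tess, design = B)
  expect_equal(n_peaks(pk3), 1)
  # invariant to global positive rescaling
  pk4 <- extract_peaks(7.3 * (a1 + 0.8 * ax), tess, design = B)
  expect_equal(pk4$directions, pk2b$directions)
  # all-nonpositive fODF (negative isotropic) gives an empty set
  neg_iso <- c(-1, numeric(44))
  expect_equal(n_peaks(extract_peaks(neg_iso, tess, design = B)), 0)
})

test_that("angular EMD reproduces hand-computable transport plans", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  u30 <- c(sin(pi / 6), 0, cos(pi / 6))
  p_z <- list(directions = matrix(z, 1, 3), amplitudes = 1)
  p_30 <- list(directions = matrix(u30, 1, 3), amplitudes = 0.4)
  expect_equal(angular_emd(p_z, p_z), 0)
  expect_equal(angular_emd(p_z, p_30), 30, tolerance = 1e-9)
  # {0, 90} equal mass vs single peak at 0: half the mass moves 90 degrees
  p_xz <- list(directions = rbind(z, x), amplitudes = c(1, 1))
  expect_equal(angular_emd(p_xz, p_z), 45, tolerance = 1e-9)
  # empty-set conventions
  empty <- list(directions = matrix(0, 0, 3), amplitudes = numeric(0))
  expect_equal(angular_emd(empty, empty), 0)
  v <- angular_emd(empty, p_z)
  expect_equal(as.numeric(v), 90)
  expect_true(attr(v, "empty_mismatch"))
})

test_that("angular EMD matches the exhaustive LP oracle on random pairs", {
  set.seed(21)
  for (r in 1:1000) {
    a <- random_peak_set(sample(1:3, 1))
    b <- random_peak_set(sample(1:3, 1))
    v <- angular_emd(a, b)
    orc <- brute_transport(orientation_cost(a$directions, b$directions),
                           a$amplitudes / sum(a$amplitudes),
                           b$amplitudes / sum(b$amplitudes))
    expect_lt(abs(v - orc), 1e-6)
  }
})

test_that("angular EMD satisfies the metric axioms", {
  set.seed(22)
  for (r in 1:300) {
    n <- sample(1:3, 1)
    a <- random_peak_set(n)
    b <- random_peak_set(sample(1:3, 1))
    cset <- random_peak_set(n)
    dab <- angular_emd(a, b)
    expect_gte(dab, 0)
    expect_lte(dab, 90 + 1e-9)
    expect_lt(abs(dab - angular_emd(b, a)), 1e-8)
    # identity residual is bounded by the anti-degeneracy perturbation
    expect_lt(angular_emd(a, a), 1e-7)
    # triangle inequality on equal-count, equal-mass sets
    aa <- a; aa$amplitudes <- rep(1 / n, n)
    cc <- cset; cc$amplitudes <- rep(1 / n, n)
    bb <- random_peak_set(n); bb$amplitudes <- rep(1 / n, n)
    expect_lte(angular_emd(aa, cc),
               angular_emd(aa, bb) + angular_emd(bb, cc) + 1e-9)
    # invariance to antipodal flips and permutations
    flip <- a
    flip$directions[1, ] <- -flip$directions[1, ]
    expect_equal(angular_emd(flip, b), dab, tolerance = 1e-9)
    if (n > 1) {
      perm <- a
      ix <- rev(seq_len(n))
      perm$directions <- perm$directions[ix, , drop = FALSE]
      perm$amplitudes <- perm$amplitudes[ix]
      expect_equal(angular_emd(perm, b), dab, tolerance = 1e-9)
    }
  }
})

test_that("1-vs-1 EMD equals the plain inter-peak angle", {
  set.seed(23)
  for (r in 1:100) {
    u <- random_unit_vectors(2)
    a <- list(directions = u[1, , drop = FALSE], amplitudes = runif(1, 0.1, 2))
    b <- list(directions = u[2, , drop = FALSE], amplitudes = runif(1, 0.1, 2))
    expect_equal(angular_emd(a, b), angle_deg(u[1, ], u[2, ]),
                 tolerance = 1e-9)
  }
})

test_that("error maps localize differences and respect bounds", {
  cfg <- make_phantom(c(4, 4, 4), seed = 5)
  gt <- peaks_from_config(cfg)
  pred <- gt
  m0 <- emd_error_map(gt, pred)
  expect_true(all(m0$emd < 1e-7))
  # perturb exactly one voxel
  w <- which(cfg$n_fibers == 1L, arr.ind = TRUE)[1, ]
  pred2 <- gt
  u <- pred2$directions[w[1], w[2], w[3], 1, ]
  rot <- c(u[3], u[2], -u[1])  # 90-degree rotation in the xz-plane
  pred2$directions[w[1], w[2], w[3], 1, ] <- rot / sqrt(sum(rot^2))
  m1 <- emd_error_map(gt, pred2)
  expect_equal(sum(m1$emd > 1e-6), 1)
  expect_true(all(m1$emd <= 90 + 1e-9))
  small <- peaks_from_config(make_phantom(c(6, 6, 6), seed = 5))
  expect_error(emd_error_map(gt, small), "grids")
})

test_that("best-method fractions implement tie semantics", {
  d <- c(2, 2, 1)
  mk <- function(vals) structure(list(emd = array(vals, d),
                                      valid = array(TRUE, d)),
                                 class = "angular_error_map")
  # identical maps: everyone is best everywhere
  bf <- best_method_fraction(list(a = mk(c(1, 2, 3, 4)),
                                  b = mk(c(1, 2, 3, 4))))
  expect_equal(bf$fraction, c(1, 1))
  # strict dominance
  bf2 <- best_method_fraction(list(a = mk(rep(0, 4)), b = mk(rep(1, 4))))
  expect_equal(bf2$fraction[bf2$method == "a"], 1)
  expect_equal(bf2$fraction[bf2$method == "b"], 0)
  # a smaller on 3 of 4 voxels, tie on one: fractions sum beyond 1
  bf3 <- best_method_fraction(list(a = mk(c(0, 0, 0, 5)),
                                   b = mk(c(1, 1, 1, 5))))
  expect_equal(bf3$fraction[bf3$method == "a"], 1)
  expect_equal(bf3$fraction[bf3$method == "b"], 0.25)
  expect_gt(sum(bf3$fraction), 1)
  expect_error(best_method_fraction(list(a = mk(1:4), b = mk(1:4)),
                                    mask = array(FALSE, d)), "mask")
})

test_that("SH similarity metrics match direct recomputation", {
  set.seed(24)
  d <- c(10, 10, 10, 3)
  gt <- array(rnorm(prod(d)), d)
  # identical volumes
  m0 <- sh_similarity(gt, gt)
  expect_true(all(m0$value[m0$metric == "mse"] == 0))
  expect_true(all(m0$value[m0$metric == "mae"] == 0))
  expect_equal(m0$value[m0$metric == "correlation"], rep(1, 3),
               tolerance = 1e-12)
  # constant shift: MSE = c^2, correlation unchanged
  mshift <- sh_similarity(gt, gt + 0.3)
  expect_equal(mshift$value[mshift$metric == "mse"], rep(0.09, 3),
               tolerance = 1e-12)
  expect_equal(mshift$value[mshift$metric == "correlation"], rep(1, 3),
               tolerance = 1e-12)
  # random pair: two-line oracle per coefficient
  pred <- gt + array(rnorm(prod(d), sd = 0.5), d)
  mr <- sh_similarity(gt, pred)
  for (k in 1:3) {
    expect_equal(mr$value[mr$metric == "mse" & mr$coef == k],
                 mean((pred[, , , k] - gt[, , , k])^2), tolerance = 1e-12)
    expect_equal(mr$value[mr$metric == "correlation" & mr$coef == k],
                 cor(as.vector(gt[, , , k]), as.vector(pred[, , , k])),
                 tolerance = 1e-12)
  }
  # constant ground-truth map: correlation undefined
  flat <- gt; flat[, , , 2] <- 1
  mflat <- sh_similarity(flat, pred)
  expect_true(is.na(mflat$value[mflat$metric == "correlation" &
                                  mflat$coef == 2]))
  # per-label subdivision agrees with direct masked recomputation
  labels <- array(rep(0:1, length.out = 1000), c(10, 10, 10))
  ml <- sh_similarity(gt, pred, labels = labels)
  sel <- labels == 1
  expect_equal(ml$value[ml$metric == "mse" & ml$coef == 1 & ml$label == "1"],
               mean((pred[, , , 1][sel] - gt[, , , 1][sel])^2),
               tolerance = 1e-12)
})

test_that("SSIM and PSNR behave as similarity measures", {
  set.seed(25)
  x <- array(rnorm(12^3), c(12, 12, 12))
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-9)
  near <- ssim3d(x, x + rnorm(12^3, sd = 0.05))
  far <- ssim3d(x, x + rnorm(12^3, sd = 1))
  expect_gt(near, far)
  m <- sh_similarity(array(x, c(12, 12, 12, 1)),
                     array(x + rnorm(12^3, sd = 0.1), c(12, 12, 12, 1)))
  psnr <- m$value[m$metric == "psnr"]
  expect_true(is.finite(psnr) && psnr > 0)
})

test_that("generalized anisotropy matches quadrature variance", {
  expect_equal(generalized_anisotropy(numeric(44)), 0)
  q <- sphere_quadrature()
  B <- build_basis(q$dirs, 8)
  set.seed(26)
  for (r in 1:100) {
    a <- rnorm(44, sd = 0.3)
    f <- evaluate_sh(denormalize_fodf(a), B)
    mu <- sum(f * q$weights) / (4 * pi)
    vy <- sum((f - mu)^2 * q$weights) / (4 * pi)
    expect_equal(generalized_anisotropy(a), tanh(vy), tolerance = 1e-4)
  }
  # strictly increasing in any coefficient magnitude
  a <- rnorm(44, sd = 0.1)
  a2 <- a; a2[17] <- a2[17] * 2
  expect_gt(generalized_anisotropy(a2), generalized_anisotropy(a))
  # volume wrapper
  vol <- array(rnorm(2 * 2 * 2 * 44, sd = 0.2), c(2, 2, 2, 44))
  g <- ga_map(vol)
  expect_equal(g[1, 1, 1], generalized_anisotropy(vol[1, 1, 1, ]))
})

test_that("average peak counts aggregate by tissue label", {
  pv <- structure(list(directions = array(0, c(2, 2, 2, 5, 3)),
                       amplitudes = array(0, c(2, 2, 2, 5)),
                       counts = array(c(1L, 1L, 1L, 1L, 3L, 3L, 3L, 3L),
                                      c(2, 2, 2)),
                       max_peaks = 5L),
                  class = "peak_volume")
  labels <- array(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), c(2, 2, 2))
  tab <- average_peak_count(pv, labels)
  expect_equal(tab$mean_peaks[tab$label == 0], 1)
  expect_equal(tab$mean_peaks[tab$label == 1], 3)
  # half 1, half 3 pooled
  tab2 <- average_peak_count(pv, array(0L, c(2, 2, 2)))
  expect_equal(tab2$mean_peaks, 2)
  # label absent from mask is omitted
  mask <- labels == 0L
  tab3 <- average_peak_count(pv, labels, mask)
  expect_false(1 %in% tab3$label)
})
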