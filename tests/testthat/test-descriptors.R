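test_that("cutoff function matches its closed form and boundary behavior", {
  Rc <- 1.7
  expect_equal(cutoff_value(Rc, Rc), 0)
  expect_equal(cutoff_value(0, Rc), 1)
  expect_equal(cutoff_value(Rc / 2, Rc), 0.5)
  expect_equal(cutoff_value(2 * Rc, Rc), 0)
  # value and slope continuous at Rc
  eps <- 1e-8
  expect_lt(abs(cutoff_value(Rc - eps, Rc) - cutoff_value(Rc + eps, Rc)), 1e-10)
  slope_in <- (cutoff_value(Rc - eps, Rc) - cutoff_value(Rc - 2 * eps, Rc)) / eps
  expect_lt(abs(slope_in), 1e-6)
  expect_error(cutoff_value(-1, Rc), "non-negative")
  expect_error(cutoff_value(1, -2), "positive")
})

test_that("radial symmetry function matches hand evaluation and direct sums", {
  Rc <- 2.0
  spec <- sf_spec("radial", mu = 1, Rs = 0, Rc = Rc)
  # empty neighbor sum
  expect_equal(radial_sf(configuration(matrix(0, 1, 3)), 1, spec), 0)
  # two particles at Rc/2: exp(-Rc^2/4) * fc(Rc/2) with fc = 0.5
  cf <- pair_configuration(Rc / 2)
  expect_equal(radial_sf(cf, 1, spec), exp(-Rc^2 / 4) * 0.5, tolerance = 1e-14)
  # translation invariance
  shift <- c(3.1, -2.2, 0.7)
  cfs <- configuration(sweep(cf$positions, 2, shift, "+"))
  expect_equal(radial_sf(cfs, 1, spec), radial_sf(cf, 1, spec))
  # direct-summation oracle on random configurations
  set.seed(1)
  for (rep in 1:10) {
    cfr <- random_config(sample(3:6, 1))
    for (sp in test_specs()) {
      if (sp$kind != "radial") next
      expect_equal(radial_sf(cfr, 2, sp),
                   radial_sf_ref(cfr$positions, 2, sp$mu, sp$Rs, sp$Rc),
                   tolerance = 1e-12)
    }
  }
})

test_that("angular symmetry function matches direct double-loop summation", {
  Rc <- 2.0
  spec <- sf_spec("angular", mua = 0.3, xi = 4, lambda = 1, Rc = Rc)
  # fewer than two neighbors
  expect_equal(angular_sf(pair_configuration(0.8), 1, spec), 0)
  # collinear triplet, J and K on the same side: angular factor is 2^xi,
  # so the value is 2^(1-xi) * 2^xi * Gaussian * cutoffs
  pos <- rbind(c(0, 0, 0), c(0.6, 0, 0), c(1.2, 0, 0))
  cf <- configuration(pos)
  r1 <- 0.6; r2 <- 1.2; r3 <- 0.6
  expected <- 2 * exp(-0.3 * (r1^2 + r2^2 + r3^2)) *
    cutoff_value(r1, Rc) * cutoff_value(r2, Rc) * cutoff_value(r3, Rc)
  expect_equal(angular_sf(cf, 1, spec), expected, tolerance = 1e-14)
  # brute-force oracle on random configurations, all angular test specs
  set.seed(2)
  for (rep in 1:10) {
    cfr <- random_config(sample(3:6, 1))
    for (sp in test_specs()) {
      if (sp$kind != "angular") next
      expect_equal(angular_sf(cfr, 1, sp),
                   angular_sf_ref(cfr$positions, 1, sp$mua, sp$xi,
                                  sp$lambda, sp$Rc),
                   tolerance = 1e-12)
    }
  }
  # coincident particles are rejected
  bad <- configuration(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(sf_values(bad, spec), "degenerate")
})

test_that("descriptor tables are permutation, translation and rotation invariant", {
  set.seed(3)
  specs <- test_specs()
  cf <- random_config(6)
  v <- sf_values(cf, specs)
  # permutation: rows permute, multiset of values unchanged
  perm <- sample(6)
  vp <- sf_values(configuration(cf$positions[perm, ]), specs)
  expect_equal(vp, v[perm, ], tolerance = 1e-13)
  # translation
  vt <- sf_values(configuration(sweep(cf$positions, 2, c(-1, 2, 5), "+")), specs)
  expect_equal(vt, v, tolerance = 1e-12)
  # rotation invariance of values
  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  vr <- sf_values(configuration(cf$positions %*% t(R)), specs)
  expect_equal(vr, v, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences and are equivariant", {
  set.seed(4)
  specs <- test_specs()
  for (rep in 1:8) {
    cf <- random_config(sample(2:6, 1))
    n <- nrow(cf$positions)
    G <- sf_gradients(cf, specs)
    # translational sum rule: sum_I grad_I G_J(K) = 0
    expect_lt(max(abs(apply(G, c(2, 3, 4), sum))), 1e-10)
    # finite differences
    for (I in seq_len(n)) for (d in 1:3) {
      fd <- fd_descriptor_gradient(cf, specs, I, d)
      an <- t(matrix(G[I, d, , ], nrow = dim(G)[3]))
      # floor the denominator at the finite-difference noise scale
      expect_lt(max(abs(an - fd) / pmax(abs(fd), 1e-3)), 1e-5)
    }
  }
  # rotation equivariance: grad(R x) = R grad(x)
  cf <- random_config(5)
  R <- qr.Q(qr(matrix(c(2, 0, 1, 1, 3, 0, 0, 1, 4), 3)))
  G <- sf_gradients(cf, specs)
  Gr <- sf_gradients(configuration(cf$positions %*% t(R)), specs)
  for (I in 1:5) for (j in seq_along(specs)) for (K in 1:5) {
    expect_equal(Gr[I, , j, K], as.numeric(R %*% G[I, , j, K]),
                 tolerance = 1e-10)
  }
})

test_that("values and gradients are smooth as a particle crosses the cutoff", {
  specs <- test_specs(Rc = 2.0)
  for (r0 in c(2.0)) {
    below <- pair_configuration(r0 - 5e-9)
    above <- pair_configuration(r0 + 5e-9)
    dv <- abs(sf_values(below, specs) - sf_values(above, specs))
    expect_lt(max(dv), 1e-10)
    dg <- abs(sf_gradients(below, specs) - sf_gradients(above, specs))
    expect_lt(max(dg), 1e-7)
  }
})

test_that("minimum image requires a box of at least twice the cutoff", {
  spec <- sf_spec("radial", mu = 1, Rs = 0, Rc = 2.5)
  cf <- configuration(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE),
                      box = c(4, 4, 4))
  expect_error(sf_values(cf, spec), "minimum-image")
  cf2 <- configuration(cf$positions, box = c(6, 6, 6))
  expect_silent(sf_values(cf2, spec))
  # periodic image actually used: pair across the boundary
  cfp <- configuration(rbind(c(0.2, 3, 3), c(5.8, 3, 3)), box = c(6, 6, 6))
  expect_equal(radial_sf(cfp, 1, spec),
               exp(-(0.4 - 0)^2) * cutoff_value(0.4, 2.5), tolerance = 1e-12)
})

test_that("descriptor pools are Cartesian products with the stated sizes", {
  expect_length(np_pair_pool(), 22 * 15)
  pool12 <- np_cluster_pool()
  kinds <- vapply(pool12, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "radial"), 100)
  expect_equal(sum(kinds == "angular"), 64)
  expect_length(build_pool(mu = 1, Rs = 0.5, Rc = 2), 1)
  # deduplication
  expect_length(build_pool(mu = c(1, 1), Rs = c(0.5, 0.5), Rc = 2), 1)
})

test_that("spec validation enforces field conventions", {
  expect_error(sf_spec("radial", mu = 1, Rs = 0, xi = 2, Rc = 1), "angular fields")
  expect_error(sf_spec("angular", mua = 1, xi = 2, lambda = 0.5, Rc = 1), "lambda")
  expect_error(sf_spec("radial", mu = 1, Rs = 0, Rc = -1), "positive")
})
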