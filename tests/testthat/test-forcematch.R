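test_that("pearson_r2 handles perfect, rescaled and orthogonal columns", {
  set.seed(10)
  y <- rnorm(200)
  expect_equal(pearson_r2(y, y), 1)
  expect_equal(pearson_r2(-2 * y, y), 1)
  # construct a column exactly orthogonal to the centered target
  x <- rnorm(200)
  yc <- y - mean(y)
  x <- x - mean(x) - sum((x - mean(x)) * yc) / sum(yc^2) * yc
  expect_equal(pearson_r2(x, y), 0, tolerance = 1e-20)
  # independently: cov-based computation
  expect_equal(pearson_r2(x + 3, y),
               (sum((x - mean(x)) * yc) / (199 * sd(x) * sd(y)))^2)
  z <- rep(2, 200)
  expect_equal(as.numeric(pearson_r2(z, y)), 0)
  expect_true(attr(pearson_r2(z, y), "degenerate"))
})

test_that("multiple correlation: both routes agree and reduce correctly", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 80
    X <- matrix(rnorm(n * 4), n)
    y <- X %*% rnorm(4) + rnorm(n)
    expect_equal(multiple_r2(X, y, "corrmatrix"),
                 multiple_r2(X, y, "residual"), tolerance = 1e-10)
  }
  # one column reduces to the squared Pearson correlation
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  expect_equal(multiple_r2(matrix(x), y), as.numeric(pearson_r2(x, y)),
               tolerance = 1e-12)
  # a set that spans the target exactly
  X <- matrix(rnorm(150), 50)
  y <- X %*% c(1, -2, 0.5)
  expect_equal(multiple_r2(X, y), 1, tolerance = 1e-12)
})

test_that("forward selection recovers planted descriptors and obeys stopping", {
  pool <- planted_pool()
  truth_idx <- c(2L, 4L, 6L)
  truth_w <- c(1.5, -2.0, 0.7)
  model <- cg_model(pool[truth_idx], truth_w)
  ds <- planted_dataset(model)
  design <- assemble_design(ds, pool)

  # single planted column
  m1 <- cg_model(pool[4], 1.0)
  d1 <- assemble_design(planted_dataset(m1, seed = 7), pool)
  tr1 <- select_features(d1)
  expect_equal(tr1$selected[1], 4L)
  expect_equal(max(tr1$r2_cumulative), 1, tolerance = 1e-9)

  # three planted columns, noiseless: exact subset, R^2 = 1
  tr <- select_features(design, delta_r2_min = 1e-8)
  expect_setequal(tr$selected, truth_idx)
  expect_equal(max(tr$r2_cumulative), 1, tolerance = 1e-9)
  expect_true(all(diff(tr$r2_cumulative) >= -1e-12))

  # stopping boundary: delta_r2_min = 1 keeps only the first pick
  tr_stop <- select_features(design, delta_r2_min = 1.0)
  expect_length(tr_stop$selected, 1)

  # noiseless refit recovers the weights
  fit <- fit_weights(design, tr)
  ord <- match(truth_idx, tr$selected)
  expect_equal(fit$weights[ord], truth_w, tolerance = 1e-8)
  expect_equal(fit$diagnostics$r2, 1, tolerance = 1e-10)
})

test_that("degenerate columns are dropped and zero targets handled", {
  pool <- c(planted_pool(),
            list(sf_spec("radial", mu = 1, Rs = 0, Rc = 0.01)))  # never fires
  model <- cg_model(pool[[2]], 1.0)
  ds <- planted_dataset(model, n_configs = 10, seed = 3)
  design <- assemble_design(ds, pool)
  tr <- select_features(design)
  expect_gte(tr$n_degenerate, 1)
  # all-zero forces: weights 0, RMSE 0, R^2 flagged undefined
  ds0 <- mean_force_dataset(ds$configs,
                            lapply(ds$configs, function(cf)
                              matrix(0, nrow(cf$positions), 3)))
  d0 <- assemble_design(ds0, planted_pool())
  f0 <- fit_weights(d0, 1:3)
  expect_equal(f0$weights, rep(0, 3))
  expect_equal(f0$diagnostics$rmse, 0)
  expect_true(is.na(f0$diagnostics$r2))
  expect_true(f0$diagnostics$zero_variance_target)
})

test_that("design matrix has the training-set row counts and isolated zeros", {
  pool <- planted_pool()
  # two-particle scan over 250 distances: 2 x 3 x 250 rows
  seps <- seq(1.0, 2.8, length.out = 250)
  configs <- lapply(seps, pair_configuration)
  forces <- lapply(configs, function(cf) matrix(0, 2, 3))
  ds <- mean_force_dataset(configs, forces)
  expect_equal(n_force_rows(ds), 1500)
  # 100 twelve-particle configurations: 3600 rows
  set.seed(12)
  cfgs12 <- lapply(1:100, function(i) random_config(12, spread = 6))
  ds12 <- mean_force_dataset(cfgs12, lapply(cfgs12, function(cf) matrix(0, 12, 3)))
  expect_equal(n_force_rows(ds12), 3600)
  d12 <- assemble_design(mean_force_dataset(cfgs12[1:3],
                                            lapply(cfgs12[1:3], function(cf)
                                              matrix(0, 12, 3))), pool)
  expect_equal(nrow(d12$X), 108)
  # mutually isolated particles: all entries zero
  iso <- configuration(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  dsi <- mean_force_dataset(iso, matrix(0, 3, 3))
  expect_true(all(assemble_design(dsi, pool)$X == 0))
  # unit mismatch is refused
  bad <- mean_force_dataset(iso, matrix(0, 3, 3), units = "kcal/mol/nm")
  expect_error(assemble_design(bad, pool), "unit")
})

test_that("predicted forces equal the negative PMF gradient and obey symmetry", {
  pool <- planted_pool()
  model <- cg_model(pool[c(1, 3, 5)], c(0.8, -1.2, 0.4))
  # isolated particle: zero force
  expect_equal(predict_forces(model, configuration(matrix(0, 1, 3))),
               matrix(0, 1, 3))
  # symmetric pair: equal and opposite along the axis
  cf <- pair_configuration(1.3)
  f <- predict_forces(model, cf)
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-12)
  expect_lt(max(abs(f[, 2:3])), 1e-12)
  # finite differences of the PMF on random configurations
  set.seed(13)
  for (rep in 1:4) {
    cfr <- random_config(sample(3:5, 1))
    f <- predict_forces(model, cfr)
    h <- 1e-5
    for (I in seq_len(nrow(cfr$positions))) for (d in 1:3) {
      pp <- cfr$positions; pp[I, d] <- pp[I, d] + h
      pm <- cfr$positions; pm[I, d] <- pm[I, d] - h
      fd <- -(evaluate_pmf(model, configuration(pp))$energy -
                evaluate_pmf(model, configuration(pm))$energy) / (2 * h)
      if (abs(fd) > 1e-6)
        expect_lt(abs(f[I, d] - fd) / abs(fd), 1e-5)
      else expect_lt(abs(f[I, d] - fd), 1e-6)
    }
  }
})

test_that("PMF vanishes at infinite dilution and is invariant under rigid motions", {
  pool <- planted_pool()
  model <- cg_model(pool[c(2, 4)], c(1.0, 0.5))
  far <- configuration(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 7, 0)))
  expect_identical(evaluate_pmf(model, far)$energy, 0)
  set.seed(14)
  cf <- random_config(5)
  e0 <- evaluate_pmf(model, cf)$energy
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- configuration(sweep(cf$positions %*% t(R), 2, c(1, -2, 3), "+"))
  expect_equal(evaluate_pmf(model, moved)$energy, e0, tolerance = 1e-10)
  perm <- sample(5)
  expect_equal(evaluate_pmf(model, configuration(cf$positions[perm, ]))$energy,
               e0, tolerance = 1e-10)
})

test_that("a radial-only model on two sites is a pure pair potential", {
  pool <- planted_pool()
  model <- cg_model(pool[c(1, 4, 7)], c(0.3, -0.9, 0.2))
  r <- seq(0.5, 2.6, by = 0.1)
  set.seed(15)
  for (ri in r) {
    base <- evaluate_pmf(model, pair_configuration(ri))$energy
    rot <- evaluate_pmf(model, pair_configuration(ri, rnorm(3)))$energy
    expect_equal(rot, base, tolerance = 1e-12)
  }
})

test_that("pair PMF from the fitted model matches integrated mean forces", {
  # train on a planted smooth pair force, then compare the closed-form PMF
  # of the model against trapezoid integration of the training forces
  pool <- planted_pool()
  gen <- cg_model(pool[c(2, 5)], c(-1.3, 0.6))
  seps <- seq(0.8, 2.6, by = 0.02)
  ds <- planted_dataset_pairs <- mean_force_dataset(
    lapply(seps, pair_configuration),
    lapply(seps, function(r) predict_forces(gen, pair_configuration(r))))
  design <- assemble_design(ds, pool)
  fit <- fit_weights(design, select_features(design, delta_r2_min = 1e-9))
  curve <- data.frame(
    r = seps,
    force = vapply(seps, function(r) {
      f <- predict_forces(gen, pair_configuration(r))
      0.5 * sum((f[1, ] - f[2, ]) * c(-1, 0, 0))
    }, numeric(1)))
  curve <- integrate_pmf(curve)
  fitted <- model_pair_pmf(fit, seps)
  expect_lt(max(abs(fitted$phi - curve$phi)), 5e-3)  # trapezoid O(dr^2)
})

test_that("model files round-trip bit-exactly", {
  pool <- np_cluster_pool()
  model <- cg_model(pool[c(5, 120, 150)], c(pi, -exp(1), 1 / 3),
                    diagnostics = list(r2 = 0.999123456789, rmse = 12.345678))
  path <- tempfile(fileext = ".json")
  write_model(model, path, provenance = list(seed = 42))
  m2 <- read_model(path)
  expect_identical(m2$weights, model$weights)
  expect_identical(m2$Rc, model$Rc)
  expect_identical(vapply(m2$specs, `[[`, numeric(1), "mua"),
                   vapply(model$specs, `[[`, numeric(1), "mua"))
  expect_identical(m2$diagnostics$r2, model$diagnostics$r2)
  # evaluations identical through the round trip
  set.seed(16)
  cf <- random_config(4)
  expect_identical(evaluate_pmf(m2, cf)$energy, evaluate_pmf(model, cf)$energy)
})
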