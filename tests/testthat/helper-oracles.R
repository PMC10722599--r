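# Independent reference implementations (plain R, direct summation) used as
# oracles against the C++ descriptor kernels, plus small fixture generators.

fc_ref <- function(r, Rc) ifelse(r <= Rc, 0.5 * (cos(pi * r / Rc) + 1), 0)

# radial Behler-Parrinello SF centered on site K, direct sum
radial_sf_ref <- function(pos, K, mu, Rs, Rc) {
  tot <- 0
  for (J in seq_len(nrow(pos))) {
    if (J == K) next
    r <- sqrt(sum((pos[K, ] - pos[J, ])^2))
    if (r <= Rc) tot <- tot + exp(-mu * (r - Rs)^2) * fc_ref(r, Rc)
  }
  tot
}

# angular Behler-Parrinello SF centered on site K, direct double loop
angular_sf_ref <- function(pos, K, mua, xi, lambda, Rc) {
  n <- nrow(pos)
  others <- setdiff(seq_len(n), K)
  tot <- 0
  if (length(others) < 2) return(0)
  for (a in seq_along(others)[-length(others)]) {
    for (b in (a + 1):length(others)) {
      J <- others[a]; L <- others[b]
      u <- pos[K, ] - pos[J, ]
      v <- pos[K, ] - pos[L, ]
      r1 <- sqrt(sum(u^2)); r2 <- sqrt(sum(v^2))
      r3 <- sqrt(sum((u - v)^2))
      if (r1 > Rc || r2 > Rc || r3 > Rc) next
      ct <- max(-1, min(1, sum(u * v) / (r1 * r2)))
      tot <- tot + 2^(1 - xi) * (1 + lambda * ct)^xi *
        exp(-mua * (r1^2 + r2^2 + r3^2)) *
        fc_ref(r1, Rc) * fc_ref(r2, Rc) * fc_ref(r3, Rc)
    }
  }
  tot
}

# random open-boundary configuration with a minimum pair distance
random_config <- function(n, spread = 2.2, min_dist = 0.35) {
  repeat {
    pos <- matrix(stats::runif(3 * n, 0, spread), n, 3)
    cf <- configuration(pos)
    if (n == 1) return(cf)
    d <- pair_distances(cf)
    if (min(d[upper.tri(d)]) > min_dist) return(cf)
  }
}

test_specs <- function(Rc = 2.0) {
  list(sf_spec("radial", mu = 2, Rs = 0.5, Rc = Rc),
       sf_spec("radial", mu = 8, Rs = 1.0, Rc = Rc),
       sf_spec("angular", mua = 0.5, xi = 4, lambda = 1, Rc = Rc),
       sf_spec("angular", mua = 1.0, xi = 1, lambda = -1, Rc = Rc),
       sf_spec("angular", mua = 0.1, xi = 8, lambda = 1, Rc = Rc))
}

# central finite-difference gradient of descriptor values w.r.t. site I
fd_descriptor_gradient <- function(config, specs, I, d, h = 1e-6) {
  pp <- config$positions; pp[I, d] <- pp[I, d] + h
  pm <- config$positions; pm[I, d] <- pm[I, d] - h
  (sf_values(configuration(pp, box = config$box), specs) -
     sf_values(configuration(pm, box = config$box), specs)) / (2 * h)
}

# a small well-conditioned radial pool for planted-model experiments
planted_pool <- function() {
  lapply(c(0.2, 0.5, 0.8, 1.1, 1.4, 1.7, 2.0, 2.3), function(rs)
    sf_spec("radial", mu = 8, Rs = rs, Rc = 2.5))
}

# dataset whose forces come exactly from a known linear model
planted_dataset <- function(model, n_configs = 40, n_min = 3, n_max = 6,
                            seed = 99) {
  set.seed(seed)
  configs <- lapply(seq_len(n_configs), function(i)
    random_config(sample(n_min:n_max, 1), spread = 2.6))
  forces <- lapply(configs, function(cf) predict_forces(model, cf))
  mean_force_dataset(configs, forces, source = "planted linear model")
}
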