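#' Asakura-Oosawa colloid-polymer parameters
#'
#' Hard-sphere colloids of diameter `sigma_c` mixed with mutually ideal
#' polymer coils of diameter `sigma_p = q sigma_c` at reservoir packing
#' fraction `eta_p`. A polymer center is excluded from a sphere of radius
#' `(sigma_c + sigma_p) / 2` around each colloid.
#'
#' @param q polymer-to-colloid size ratio `sigma_p / sigma_c`.
#' @param eta_p reservoir polymer packing fraction.
#' @param sigma_c colloid diameter (1 in reduced units).
#' @return an `ao_params` object.
#' @export
ao_params <- function(q = 1, eta_p = 0.5, sigma_c = 1) {
  if (q <= 0) stop("sigma_p must be positive")
  if (eta_p < 0) stop("eta_p must be non-negative")
  sigma_p <- q * sigma_c
  structure(list(sigma_c = sigma_c, sigma_p = sigma_p, q = q, eta_p = eta_p,
                 r_excl = (sigma_c + sigma_p) / 2,
                 rho_p = 6 * eta_p / (pi * sigma_p^3)),
            class = "ao_params")
}

#' Analytic Asakura-Oosawa depletion potential
#'
#' Closed-form pair potential between two hard-sphere colloids in an ideal
#' polymer bath (the overlap volume of the two exclusion shells times the
#' reservoir polymer density):
#' `beta W(r) = -eta_p (1+q)^3/q^3 [1 - 3r/(2(1+q)sigma_c) + r^3/(2(1+q)^3 sigma_c^3)]`
#' for `sigma_c <= r <= (1+q) sigma_c`, zero beyond, infinite (hard core)
#' below contact.
#'
#' @param r separation distance(s).
#' @param ao an [ao_params()].
#' @return potential in `k_B T`.
#' @export
ao_analytic_depletion <- function(r, ao) {
  s <- ao$sigma_c
  q <- ao$q
  range <- (1 + q) * s
  w <- ifelse(r < s, Inf,
       ifelse(r > range, 0,
              -ao$eta_p * (1 + q)^3 / q^3 *
                (1 - 3 * r / (2 * (1 + q) * s) + r^3 / (2 * (1 + q)^3 * s^3))))
  w
}

#' Analytic Asakura-Oosawa depletion force
#'
#' `-d beta W / dr`: negative (attractive) throughout the depletion range.
#'
#' @param r separation distance(s).
#' @param ao an [ao_params()].
#' @return radial force in `k_B T / sigma_c` (projection on the outward pair axis).
#' @export
ao_analytic_force <- function(r, ao) {
  re <- ao$r_excl
  ifelse(r >= 2 * re | r < ao$sigma_c, 0,
         -ao$rho_p * pi * (re^2 - r^2 / 4))
}

# Blocked phi-arc integrals on the cos-theta rings of colloid I's exclusion
# sphere, for one blocking neighbour at displacement u (length d): on each
# ring the blocked arc is |phi - phi0| < dphi, from the condition
# u . p_hat > d^2 / (2 r_excl). Returns an n_rings x 3 matrix of the arc
# integrals of (cos phi, sin phi, 1); vectorized over rings. Arcs from
# different neighbours are disjoint when the blocked caps are (checked by
# the caller), so contributions are summed without interval merging.
ao_ring_blocked <- function(ct, st, u, d, r_excl) {
  A <- u[1] * st
  B <- u[2] * st
  C <- d^2 / (2 * r_excl) - u[3] * ct
  rho <- sqrt(A^2 + B^2)
  out <- matrix(0, length(ct), 3)
  pole <- rho < 1e-14
  x <- ifelse(pole, Inf, C / pmax(rho, 1e-300))
  fullring <- (pole & C < 0) | (!pole & x <= -1)
  partial <- !pole & x > -1 & x < 1
  out[fullring, 3] <- 2 * pi
  if (any(partial)) {
    dphi <- acos(x[partial])
    phi0 <- atan2(B[partial], A[partial])
    a <- phi0 - dphi
    b <- phi0 + dphi
    out[partial, ] <- cbind(sin(b) - sin(a), cos(a) - cos(b), b - a)
  }
  out
}

#' Mean depletion forces on hard colloids in an ideal polymer bath
#'
#' Exploits polymer ideality: the polymer density at any accessible point is
#' the reservoir density, so the mean force on colloid I is the contact
#' integral of the ideal-polymer pressure over the accessible part of its
#' exclusion sphere,
#' `beta F_I = -rho_p * surface integral of chi(r) n(r) dA`,
#' with `chi` the indicator that the surface point lies outside every other
#' colloid's exclusion sphere. Deterministic ring quadrature (exact phi-arc
#' integrals per blocking neighbour, midpoint rule over cos theta) or Monte
#' Carlo surface sampling.
#'
#' @param config colloid [configuration()] (open boundaries or periodic).
#' @param ao an [ao_params()].
#' @param method `"quadrature"` (deterministic) or `"monte-carlo"`.
#' @param n_rings number of cos-theta rings for the quadrature.
#' @param n_samples sample count for the Monte Carlo route.
#' @param seed RNG seed (Monte Carlo route only).
#' @return N x 3 matrix of mean forces in `k_B T / sigma_c`.
#' @export
ao_mean_forces <- function(config, ao, method = c("quadrature", "monte-carlo"),
                           n_rings = 2000, n_samples = 20000, seed = 1) {
  method <- match.arg(method)
  pos <- config$positions
  n <- nrow(pos)
  re <- ao$r_excl
  dmat <- pair_distances(config)
  if (n > 1 && any(dmat[upper.tri(dmat)] < ao$sigma_c - 1e-9))
    stop("hard-core overlap between colloids")
  forces <- matrix(0, n, 3)
  if (n == 1) return(forces)

  # displacement helper honoring the periodic box if present
  dispv <- function(i, js) {
    u <- pos[js, , drop = FALSE] - matrix(pos[i, ], length(js), 3, byrow = TRUE)
    if (!is.null(config$box))
      for (k in 1:3) u[, k] <- u[, k] - config$box[k] * round(u[, k] / config$box[k])
    u
  }

  for (i in seq_len(n)) {
    js <- which(dmat[i, ] < 2 * re & seq_len(n) != i)
    if (length(js) == 0) next
    u <- dispv(i, js)              # vectors from colloid i to blockers
    d <- sqrt(rowSums(u^2))

    if (method == "quadrature") {
      # disjointness check: blocked caps (half-angle alpha_j around u_j)
      if (length(js) > 1) {
        ca <- d / (2 * re)              # cos alpha_j
        al <- acos(pmin(1, ca))
        for (a in seq_along(js)[-1]) for (b in seq_len(a - 1)) {
          cab <- sum(u[a, ] * u[b, ]) / (d[a] * d[b])
          gap <- acos(pmin(1, pmax(-1, cab)))
          if (gap < al[a] + al[b])
            stop(paste("overlapping blocked caps (triple exclusion overlap);",
                       "ring quadrature supports disjoint caps only -",
                       "use method = 'monte-carlo'"))
        }
      }
      ct <- seq(-1 + 1 / n_rings, 1 - 1 / n_rings, length.out = n_rings)
      h <- 2 / n_rings
      st <- sqrt(pmax(0, 1 - ct^2))
      blk <- matrix(0, n_rings, 3)
      for (j in seq_along(js))
        blk <- blk + ao_ring_blocked(ct, st, u[j, ], d[j], re)
      acc <- h * c(sum(st * blk[, 1]), sum(st * blk[, 2]), sum(ct * blk[, 3]))
      # -rho ( full-sphere integral (= 0) - blocked part ) = +rho * blocked
      forces[i, ] <- ao$rho_p * re^2 * acc
    } else {
      set.seed(seed + i)
      z <- stats::rnorm(n_samples)
      y <- stats::rnorm(n_samples)
      x <- stats::rnorm(n_samples)
      nrm <- sqrt(x^2 + y^2 + z^2)
      p <- cbind(x / nrm, y / nrm, z / nrm)
      blocked <- rep(FALSE, n_samples)
      for (j in seq_along(js)) {
        dd <- sweep(re * p, 2, u[j, ])
        blocked <- blocked | rowSums(dd^2) < re^2
      }
      area <- 4 * pi * re^2
      forces[i, ] <- ao$rho_p * area * colMeans(p * blocked)
    }
  }
  forces
}

#' Radial descriptor pool for depletion-model training
#'
#' The depletion interaction lives on the window `[sigma_c, (1+q) sigma_c]`,
#' so the pool spans that window with Gaussian shifts at `q/8` spacing and
#' widths from much broader than the window down to about a quarter of the
#' shift spacing (`mu` scales with `1/q^2`). A handful of near-flat
#' descriptors (`mu ~ 0`) cover the long-range baseline.
#'
#' @param q polymer-to-colloid size ratio.
#' @param Rc cutoff (sigma_c).
#' @return a list of radial `sf_spec`s.
#' @export
ao_pool <- function(q = 1, Rc = 2.5) {
  mu <- c(0.001, 8, 50, 100, 200, 400, 800, 1600, 3200) * (0.1 / q)^2
  Rs <- seq(max(0, 1 - q), min(Rc, 1 + 1.75 * q), by = q / 8)
  build_pool(mu = mu, Rs = Rs, Rc = Rc)
}

#' Separation ladder for two-colloid AO training
#'
#' Dense sampling across the depletion window plus sparser points out to
#' beyond the interaction range (where mean forces vanish), so the
#' infinite-dilution reference is anchored by the data.
#'
#' @param q polymer-to-colloid size ratio.
#' @return numeric separations (sigma_c).
#' @export
ao_separation_ladder <- function(q = 1) {
  c(seq(1, 1 + 1.4 * q, by = q / 40), seq(1 + 1.6 * q, 1 + 6 * q, by = 0.4 * q))
}

#' Build a two-colloid AO mean-force dataset
#'
#' Computes quadrature mean forces for pairs of colloids over a ladder of
#' separation distances with randomized orientations, the training input for
#' the pair (ML2-style) depletion model.
#'
#' @param separations separation distances (sigma_c).
#' @param ao an [ao_params()].
#' @param seed seed for the random orientations.
#' @param n_rings quadrature resolution.
#' @return a [mean_force_dataset()].
#' @export
ao_pair_dataset <- function(separations, ao, seed = 1, n_rings = 2000) {
  set.seed(seed)
  configs <- lapply(separations, function(r) {
    v <- stats::rnorm(3)
    pair_configuration(r, direction = v)
  })
  forces <- lapply(configs, ao_mean_forces, ao = ao, n_rings = n_rings)
  mean_force_dataset(configs, forces,
                     source = sprintf("AO pair quadrature q=%g eta_p=%g seed=%d",
                                      ao$q, ao$eta_p, seed))
}

#' Build a many-colloid AO mean-force dataset
#'
#' Generates hard-sphere colloid clusters in a spherical confinement ladder
#' (see [generate_training_configs()]) and computes quadrature mean forces on
#' every colloid.
#'
#' @param n_colloids colloids per cluster.
#' @param diameters confining-sphere diameter ladder (sigma_c).
#' @param n_per_diameter configurations recorded per ladder entry.
#' @param ao an [ao_params()].
#' @param seed RNG seed.
#' @param n_rings quadrature resolution.
#' @return a [mean_force_dataset()].
#' @export
ao_cluster_dataset <- function(n_colloids = 12, diameters = c(3.6, 4.5, 6, 10),
                               n_per_diameter = 5, ao = ao_params(q = 0.1, eta_p = 0.05),
                               seed = 1, n_rings = 2000) {
  # sample the confinement ladder with the two-body depletion attraction so
  # the recorded configurations include the near-contact pairs an equilibrium
  # colloid-polymer system actually visits
  u2 <- function(r) ao_analytic_depletion(pmax(r, ao$sigma_c), ao)
  configs <- generate_training_configs(n_colloids, diameters,
                                       n_per_diameter = n_per_diameter,
                                       hard_core = ao$sigma_c, pair_u = u2,
                                       seed = seed)
  forces <- lapply(configs, ao_mean_forces, ao = ao, n_rings = n_rings)
  mean_force_dataset(configs, forces,
                     source = sprintf("AO cluster quadrature q=%g eta_p=%g seed=%d",
                                      ao$q, ao$eta_p, seed))
}
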