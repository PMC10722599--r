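#' Fine-grained bead force-field parameters
#'
#' Martini-style bead interactions in reduced units (lengths in the bead
#' diameter `sigma_b`, energies in `k_B T` at the simulation temperature).
#' Real-unit defaults: `sigma_b = 0.47 nm`, `eps = 0.8365 kcal/mol`,
#' `r_c = 1.2 nm`, `K_b = 149.3787 kcal/mol/nm^2`, `b_0 = 0.47 nm`,
#' `K_theta = 2.9876 kcal/mol`, `theta_0 = 180 deg`, `T = 300 K`. Harmonic
#' terms use the `K (x - x0)^2` convention (no 1/2), matching the constants.
#'
#' @param s solvent-quality weight in `[0, 1]` scaling the attractive branch
#'   (`s = 0` purely repulsive WCA, `s = 1` full Lennard-Jones).
#' @param T_K temperature in Kelvin (converts the energy scale to k_B T).
#' @param eps_kcal bead interaction well depth in kcal/mol.
#' @param sigma_b_nm bead diameter in nm.
#' @param rc_nm bead interaction cutoff in nm.
#' @param Kb_kcal_nm2 bond constant in kcal/mol/nm^2.
#' @param b0_nm equilibrium bond length in nm.
#' @param Kth_kcal angle constant in kcal/mol.
#' @param theta0_deg equilibrium angle in degrees.
#' @return an `fg_params` object with reduced-unit fields (`beta_eps`, `Kb`,
#'   `b0`, `Kth`, `th0`, `rc_bead`, all per sigma_b and k_B T).
#' @export
fg_params <- function(s = 0.1, T_K = 300, eps_kcal = 0.8365, sigma_b_nm = 0.47,
                      rc_nm = 1.2, Kb_kcal_nm2 = 149.3787, b0_nm = 0.47,
                      Kth_kcal = 2.9876, theta0_deg = 180) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  kT <- 0.0019872041 * T_K  # kcal/mol
  structure(list(
    s = s, T_K = T_K,
    beta_eps = eps_kcal / kT,
    rc_bead = rc_nm / sigma_b_nm,
    Kb = Kb_kcal_nm2 * sigma_b_nm^2 / kT,
    b0 = b0_nm / sigma_b_nm,
    Kth = Kth_kcal / kT,
    th0 = theta0_deg * pi / 180,
    sigma_b_nm = sigma_b_nm), class = "fg_params")
}

#' Solvent-quality-modified Lennard-Jones potential
#'
#' Repulsive branch `u_LJ(r) + (1 - s) eps` below the minimum at
#' 2^(1/6) sigma_b, attractive branch `s u_LJ(r)` beyond, truncated at the
#' bead cutoff.
#' Continuous in value and slope at the minimum; `s = 0` is the purely
#' repulsive WCA form and `s = 1` the full (truncated) Lennard-Jones.
#'
#' @param r bead separation(s) in sigma_b, positive.
#' @param params an [fg_params()].
#' @return list with `energy` (k_B T) and `force` (`-du/dr`, k_B T/sigma_b).
#' @export
modified_lj <- function(r, params) {
  if (any(r <= 0)) stop("r must be positive (r = 0 diverges)")
  eps <- params$beta_eps
  s <- params$s
  rc <- params$rc_bead
  inv6 <- 1 / r^6
  ulj <- 4 * eps * inv6 * (inv6 - 1)
  flj <- 24 * eps * inv6 * (2 * inv6 - 1) / r
  rmin <- 2^(1 / 6)
  e <- ifelse(r < rmin, ulj + (1 - s) * eps, s * ulj)
  f <- ifelse(r < rmin, flj, s * flj)
  e[r >= rc] <- 0
  f[r >= rc] <- 0
  list(energy = e, force = f)
}

#' Harmonic bond energy
#' @param b bond length(s), sigma_b.
#' @param params an [fg_params()].
#' @return energy `K_b (b - b0)^2` in k_B T.
#' @export
bond_energy <- function(b, params) params$Kb * (b - params$b0)^2

#' Harmonic angle energy
#' @param theta angle(s) in radians.
#' @param params an [fg_params()].
#' @return energy `K_theta (theta - theta0)^2` in k_B T.
#' @export
angle_energy <- function(theta, params) params$Kth * (theta - params$th0)^2

#' Nanoparticle geometry
#'
#' A ligand-capped nanoparticle: a rigid spherical core of diameter `sigma_c`
#' (in sigma_b units) decorated with `n_ligands` chains of `beads_per_ligand`
#' beads grafted at quasi-uniform (Fibonacci lattice) surface sites. The
#' desk-scale default (42 ligands x 3 beads on a 3 sigma_b core) keeps the
#' surface coverage near the full-scale value of about 5 ligands/nm^2.
#'
#' @param sigma_c core diameter in sigma_b units.
#' @param n_core core bead count (bookkeeping: cores act as one rigid unit).
#' @param n_ligands ligand chains per particle.
#' @param beads_per_ligand beads per chain.
#' @param sigma_b_nm bead diameter in nm (for the coverage report).
#' @return an `np_geometry` object.
#' @export
np_geometry <- function(sigma_c = 3, n_core = 1, n_ligands = 42,
                        beads_per_ligand = 3, sigma_b_nm = 0.47) {
  if (n_ligands < 0 || beads_per_ligand < 1) stop("invalid ligand counts")
  area_nm2 <- pi * (sigma_c * sigma_b_nm)^2
  structure(list(sigma_c = sigma_c, n_core = n_core, n_ligands = n_ligands,
                 beads_per_ligand = beads_per_ligand,
                 n_beads = n_core + n_ligands * beads_per_ligand,
                 coverage_nm2 = n_ligands / area_nm2),
            class = "np_geometry")
}

#' Paper-scale nanoparticle geometry
#'
#' 275 core beads and 275 ligands of 5 beads on a 4.2 nm core
#' (1650 beads per particle). Long-running at mean-force sampling scale;
#' provided for completeness next to the desk-scale default.
#'
#' @return an `np_geometry`.
#' @export
np_geometry_full <- function() {
  np_geometry(sigma_c = 4.2 / 0.47, n_core = 275, n_ligands = 275,
              beads_per_ligand = 5)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a ligand-capped nanoparticle topology
#'
#' Places grafting sites on the core surface with a Fibonacci lattice, core
#' beads (when `n_core > 1`) on an inner Fibonacci shell, and ligand beads
#' radially outward at the equilibrium bond spacing. Initial overlaps are
#' relaxed later by the sampler's steepest-descent phase.
#'
#' @param geom an [np_geometry()].
#' @param center length-3 core center position (sigma_b units).
#' @param params an [fg_params()] (for the bond length).
#' @return list with `core_center`, `core_beads`, `grafts`, `beads`
#'   (ligand bead positions), `bonds`, `angles`, `anchor` (bead index bonded
#'   to each graft), all 1-based.
#' @export
build_nanoparticle <- function(geom, center = c(0, 0, 0), params = fg_params()) {
  rad <- geom$sigma_c / 2
  if (geom$n_ligands > 0) {
    grafts <- sweep(rad * fibonacci_sphere(geom$n_ligands), 2, center, "+")
  } else grafts <- matrix(0, 0, 3)
  core_beads <- if (geom$n_core > 1) {
    sweep(rad * fibonacci_sphere(geom$n_core), 2, center, "+")
  } else matrix(center, 1, 3)

  npl <- geom$beads_per_ligand
  beads <- matrix(0, geom$n_ligands * npl, 3)
  bonds <- NULL
  angles <- NULL
  anchor <- integer(geom$n_ligands)
  for (l in seq_len(geom$n_ligands)) {
    u <- (grafts[l, ] - center)
    u <- u / sqrt(sum(u^2))
    idx <- (l - 1) * npl + seq_len(npl)
    for (k in seq_len(npl))
      beads[idx[k], ] <- grafts[l, ] + k * params$b0 * u
    anchor[l] <- idx[1]
    if (npl > 1)
      bonds <- rbind(bonds, cbind(idx[-npl], idx[-1]))
    if (npl > 2)
      angles <- rbind(angles, cbind(idx[1:(npl - 2)], idx[2:(npl - 1)], idx[3:npl]))
  }
  list(core_center = center, core_beads = core_beads, grafts = grafts,
       beads = beads,
       bonds = if (is.null(bonds)) matrix(0L, 0, 2) else bonds,
       angles = if (is.null(angles)) matrix(0L, 0, 3) else angles,
       anchor = anchor, geom = geom)
}

# assemble several nanoparticles into one flat bead system for the sampler
assemble_np_system <- function(nps) {
  offs <- 0L
  beads <- NULL; grafts <- NULL; graft_core <- integer(0)
  anchor <- integer(0); bonds <- NULL; angles <- NULL; cores <- NULL
  for (i in seq_along(nps)) {
    np <- nps[[i]]
    cores <- rbind(cores, np$core_center)
    beads <- rbind(beads, np$beads)
    grafts <- rbind(grafts, np$grafts)
    graft_core <- c(graft_core, rep(i, nrow(np$grafts)))
    anchor <- c(anchor, np$anchor + offs)
    if (nrow(np$bonds) > 0) bonds <- rbind(bonds, np$bonds + offs)
    if (nrow(np$angles) > 0) angles <- rbind(angles, np$angles + offs)
    offs <- offs + nrow(np$beads)
  }
  list(cores = cores, beads = beads, grafts = grafts,
       graft_core = graft_core, anchor = anchor,
       bonds = if (is.null(bonds)) matrix(0L, 0, 2) else bonds,
       angles = if (is.null(angles)) matrix(0L, 0, 3) else angles)
}

#' Sample constrained mean forces on frozen nanoparticle cores
#'
#' Langevin (BAOAB) dynamics of the ligand beads with all cores frozen; the
#' mean force on each core is the time average of the total instantaneous
#' force on the rigid core unit (bead-core repulsion plus grafting-bond
#' reactions), with block-averaged standard errors.
#'
#' @param nps list of [build_nanoparticle()] topologies (frozen positions).
#' @param params an [fg_params()].
#' @param n_steps production steps.
#' @param n_equil equilibration steps.
#' @param n_min steepest-descent overlap-removal steps.
#' @param dt reduced time step.
#' @param gamma Langevin friction (1/tau).
#' @param n_blocks blocks for error estimation.
#' @param seed RNG seed.
#' @return list with `mean_force` (n_np x 3, k_B T/sigma_b), `se`, `beads`,
#'   `mean_epot`.
#' @export
md_sample_mean_forces <- function(nps, params, n_steps = 40000,
                                  n_equil = 10000, n_min = 300, dt = 0.004,
                                  gamma = 1.0, n_blocks = 10, seed = 1) {
  sys <- assemble_np_system(nps)
  set.seed(seed)
  sigma_c <- nps[[1]]$geom$sigma_c
  plist <- list(s = params$s, beta_eps = params$beta_eps, Kb = params$Kb,
                b0 = params$b0, Kth = params$Kth, th0 = params$th0,
                rc_bead = params$rc_bead, core_shift = (sigma_c - 1) / 2)
  res <- cpp_langevin_mean_forces(
    sys$beads, sys$cores, sys$grafts,
    as.integer(sys$graft_core - 1L), as.integer(sys$anchor - 1L),
    matrix(as.integer(sys$bonds - 1L), ncol = 2),
    matrix(as.integer(sys$angles - 1L), ncol = 3),
    plist, as.integer(n_min), as.integer(n_equil), as.integer(n_steps),
    dt, gamma, as.integer(n_blocks))
  list(mean_force = res$mean_force, se = res$mean_force_se,
       beads = res$beads, mean_epot = res$mean_epot)
}

#' Scan the two-body mean force over a ladder of core separations
#'
#' For each separation the projected pair mean force is the symmetrized
#' projection `F_m(R) = 0.5 <(F_I - F_J) . R_hat>` on the center-to-center
#' axis. Distances and forces are returned both in bead units and converted
#' to reduced core units (sigma_c, k_B T/sigma_c).
#'
#' @param geom an [np_geometry()].
#' @param params an [fg_params()].
#' @param distances core-center separations in sigma_b units.
#' @param seed RNG seed (distance index is folded in).
#' @param ... sampling controls passed to [md_sample_mean_forces()].
#' @return a `pmf_curve` data.frame with columns `r` (sigma_c), `force`
#'   (k_B T/sigma_c) and `se`.
#' @export
pair_mean_force_scan <- function(geom, params, distances, seed = 1, ...) {
  out <- data.frame(r = numeric(0), force = numeric(0), se = numeric(0))
  for (k in seq_along(distances)) {
    d <- distances[k]
    np1 <- build_nanoparticle(geom, center = c(-d / 2, 0, 0), params = params)
    np2 <- build_nanoparticle(geom, center = c(d / 2, 0, 0), params = params)
    res <- md_sample_mean_forces(list(np1, np2), params,
                                 seed = seed + 7919L * k, ...)
    rhat <- c(-1, 0, 0)  # unit vector from J (=2) to I (=1)
    fm <- 0.5 * sum((res$mean_force[1, ] - res$mean_force[2, ]) * rhat)
    se <- 0.5 * sqrt(sum(res$se[1, ]^2 + res$se[2, ]^2)) # conservative
    out <- rbind(out, data.frame(r = d, force = fm, se = se))
  }
  # convert sigma_b units -> sigma_c reduced units
  out$r <- out$r / geom$sigma_c
  out$force <- out$force * geom$sigma_c
  out$se <- out$se * geom$sigma_c
  class(out) <- c("pmf_curve", class(out))
  attr(out, "units") <- "kT/sigma_c"
  out
}

#' Integrate a mean-force curve into a pair potential
#'
#' `Phi2(R) = integral_R^inf F_m(R') dR'` by the trapezoid rule on the scanned
#' grid with `Phi2(R_max) = 0`.
#'
#' @param curve data.frame with columns `r` and `force` (ascending `r`).
#' @return the curve with an added `phi` column (k_B T).
#' @export
integrate_pmf <- function(curve) {
  o <- order(curve$r)
  r <- curve$r[o]
  f <- curve$force[o]
  n <- length(r)
  phi <- numeric(n)
  for (i in (n - 1):1)
    phi[i] <- phi[i + 1] + 0.5 * (f[i] + f[i + 1]) * (r[i + 1] - r[i])
  curve$phi[o] <- phi
  curve
}

#' Generate coarse-grained training configurations in spherical confinement
#'
#' Equilibrates N sites inside a harmonic spherical wall with Metropolis
#' moves at each confining diameter of the ladder, then records the wall-free
#' frozen configurations. Large diameters produce dilute configurations where
#' mean forces (and descriptors) vanish; small diameters produce dense
#' clusters with overlapping coronas.
#'
#' @param n_particles sites per configuration.
#' @param diameters confining-sphere diameter ladder (sigma_c).
#' @param n_per_diameter configurations recorded per ladder entry.
#' @param hard_core hard-core diameter rejected in the sampling (0 disables).
#' @param soft_sigma length scale of a soft WCA-like repulsion between sites
#'   (0 disables; used to emulate ligand coronas).
#' @param pair_u optional pair potential `function(r) -> k_B T` added to the
#'   sampling energy, so configurations are drawn near the equilibrium of the
#'   reference model (e.g. the depletion attraction, which populates
#'   near-contact pairs that a purely hard-sphere sampler rarely visits).
#' @param n_sweeps Metropolis sweeps per configuration.
#' @param wall_k harmonic wall stiffness (k_B T / sigma_c^2).
#' @param seed RNG seed.
#' @return list of open-boundary [configuration()]s.
#' @export
generate_training_configs <- function(n_particles = 12, diameters = c(4, 6, 10, 20),
                                      n_per_diameter = 25, hard_core = 0,
                                      soft_sigma = 0, pair_u = NULL,
                                      n_sweeps = 400, wall_k = 50, seed = 1) {
  set.seed(seed)
  configs <- list()
  pair_energy <- function(pos) {
    d <- pair_distances(configuration(pos))
    du <- d[upper.tri(d)]
    if (hard_core > 0 && any(du < hard_core)) return(Inf)
    e <- 0
    if (soft_sigma > 0) {
      x <- du[du < soft_sigma * 2^(1 / 6)]
      if (length(x) > 0) {
        inv6 <- (soft_sigma / x)^6
        e <- e + sum(4 * (inv6^2 - inv6) + 1)
      }
    }
    if (!is.null(pair_u)) e <- e + sum(pair_u(du))
    e
  }
  wall_energy <- function(pos, R) {
    rr <- sqrt(rowSums(pos^2))
    sum(wall_k * pmax(0, rr - R)^2)
  }
  for (D in diameters) {
    R <- D / 2
    for (rep in seq_len(n_per_diameter)) {
      # random non-overlapping start
      pos <- matrix(0, n_particles, 3)
      placed <- 0
      attempts <- 0
      while (placed < n_particles) {
        attempts <- attempts + 1
        if (attempts > 200000)
          stop(sprintf("cannot place %d particles in a sphere of diameter %g: confinement too tight",
                       n_particles, D))
        cand <- stats::runif(3, -R, R)
        if (sum(cand^2) > R^2) next
        if (hard_core > 0 && placed > 0) {
          dd <- sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))
          if (any(dd < hard_core)) next
        }
        placed <- placed + 1
        pos[placed, ] <- cand
      }
      e <- pair_energy(pos) + wall_energy(pos, R)
      step <- 0.3
      for (sw in seq_len(n_sweeps)) {
        for (i in seq_len(n_particles)) {
          trial <- pos
          trial[i, ] <- pos[i, ] + stats::runif(3, -step, step)
          et <- pair_energy(trial) + wall_energy(trial, R)
          if (is.finite(et) && (et <= e || stats::runif(1) < exp(e - et))) {
            pos <- trial
            e <- et
          }
        }
      }
      configs[[length(configs) + 1L]] <- configuration(pos)
    }
  }
  configs
}
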