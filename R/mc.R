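#' Monte Carlo run parameters
#'
#' @param ensemble `"NVT"` or `"NPT"`.
#' @param n_particles particle count.
#' @param pressure reduced pressure `P sigma_c^3 / k_B T` (NPT only).
#' @param n_equil,n_prod equilibration / production sweeps (one sweep = N
#'   translation attempts, plus one volume attempt in NPT).
#' @param step initial maximum translation displacement (auto-tuned during
#'   equilibration to a 0.2-0.5 acceptance window, frozen for production).
#' @param lnv_step initial maximum ln-volume step (NPT).
#' @param frame_stride store a trajectory frame (and g(r) sample) every this
#'   many production sweeps.
#' @param gr_bin,gr_rmax g(r) histogram bin width and range (0 disables).
#' @param hard_core hard-core diameter; moves creating pair distances below
#'   it are rejected (0 disables). Used when the learned potential describes
#'   only the solvent- or polymer-mediated part of the interaction of hard
#'   particles.
#' @param seed RNG seed.
#' @return an `mc_params` object.
#' @export
mc_params <- function(ensemble = c("NVT", "NPT"), n_particles = 108,
                      pressure = NA, n_equil = 200, n_prod = 1000,
                      step = 0.3, lnv_step = 0.05, frame_stride = 10,
                      gr_bin = 0.05, gr_rmax = 0, hard_core = 0, seed = 1) {
  ensemble <- match.arg(ensemble)
  if (ensemble == "NPT" && (is.na(pressure) || pressure <= 0))
    stop("NPT needs a positive reduced pressure")
  structure(list(ensemble = ensemble, n_particles = n_particles,
                 pressure = pressure, n_equil = n_equil, n_prod = n_prod,
                 step = step, lnv_step = lnv_step, frame_stride = frame_stride,
                 gr_bin = gr_bin, gr_rmax = gr_rmax, hard_core = hard_core,
                 seed = seed), class = "mc_params")
}

#' Face-centered-cubic initial configuration
#'
#' A perfect FCC lattice of `N = 4 m^3` particles at the requested reduced
#' density in a cubic box.
#'
#' @param N particle count, restricted to `4 m^3`.
#' @param rho reduced density `rho sigma_c^3`.
#' @return a periodic [configuration()].
#' @export
fcc_init <- function(N, rho) {
  m <- round((N / 4)^(1 / 3))
  if (4 * m^3 != N) stop("N must be 4 m^3 for an FCC lattice")
  L <- (N / rho)^(1 / 3)
  a <- L / m
  base <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
  pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    sweep(base, 2, cells[i, ], "+"))) * a
  configuration(pos, box = c(L, L, L))
}

#' Random initial configuration
#'
#' Uniformly random positions; with `hard_core > 0`, random sequential
#' insertion without overlaps (practical up to packing fractions of roughly
#' 0.3).
#'
#' @param N particle count.
#' @param rho reduced density.
#' @param hard_core minimum pair distance (0 disables).
#' @param seed RNG seed.
#' @return a periodic [configuration()].
#' @export
random_init <- function(N, rho, hard_core = 0, seed = 1) {
  set.seed(seed)
  L <- (N / rho)^(1 / 3)
  if (hard_core <= 0)
    return(configuration(matrix(stats::runif(3 * N, 0, L), N, 3),
                         box = c(L, L, L)))
  pos <- matrix(0, N, 3)
  placed <- 0
  attempts <- 0
  while (placed < N) {
    attempts <- attempts + 1
    if (attempts > 500000)
      stop("random sequential insertion failed: density too high for the hard core")
    cand <- stats::runif(3, 0, L)
    if (placed > 0) {
      dk <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      dk <- dk - L * round(dk / L)
      if (any(rowSums(dk^2) < hard_core^2)) next
    }
    placed <- placed + 1
    pos[placed, ] <- cand
  }
  configuration(pos, box = c(L, L, L))
}

#' Metropolis Monte Carlo with a linear coarse-grained model
#'
#' Single-particle translations (plus ln-volume moves in NPT with the
#' `P dV` and `(N+1) ln(V'/V)` acceptance terms). Energy differences are
#' computed by local re-evaluation of the per-site contributions `Phi_K`
#' affected by the move (sites within `R_c` of the old or new position).
#'
#' @param model a `cg_model`, or a list `list(r=, u=)` tabulating a pair
#'   potential (cross-check back-end), or `NULL` for the ideal gas.
#' @param params an [mc_params()].
#' @param initial a periodic [configuration()]; defaults to an FCC lattice at
#'   the density implied by `rho_init`.
#' @param rho_init initial reduced density when `initial` is NULL.
#' @return an `mc_result`: observables, final configuration, trajectory
#'   frames, g(r) table, and the incremental vs recomputed total energies.
#' @export
mc_run <- function(model, params, initial = NULL, rho_init = 0.05) {
  if (is.null(initial)) {
    N <- params$n_particles
    m <- round((N / 4)^(1 / 3))
    initial <- if (4 * m^3 == N) fcc_init(N, rho_init)
               else random_init(N, rho_init, seed = params$seed)
  }
  if (is.null(initial$box)) stop("Monte Carlo requires a periodic box")
  L <- initial$box
  if (max(abs(L - L[1])) > 1e-12) stop("cubic box required")

  if (is.null(model)) {
    specmat <- spec_matrix(sf_spec("radial", mu = 1, Rs = 0, Rc = 1))
    weights <- 0
    pairtab <- list()
  } else if (inherits(model, "cg_model")) {
    specmat <- spec_matrix(model$specs)
    weights <- model$weights
    pairtab <- list()
  } else if (is.list(model) && !is.null(model$r)) {
    specmat <- matrix(0, 0, 7)
    weights <- numeric(0)
    pairtab <- list(r = as.numeric(model$r), u = as.numeric(model$u))
  } else stop("model must be a cg_model, a pair table, or NULL")

  set.seed(params$seed)
  res <- cpp_mc_run(initial$positions, L[1], specmat, weights, pairtab,
                    as.integer(params$ensemble == "NPT"),
                    ifelse(is.na(params$pressure), 0, params$pressure),
                    as.integer(params$n_equil), as.integer(params$n_prod),
                    params$step, params$lnv_step,
                    as.integer(params$frame_stride),
                    params$gr_bin, params$gr_rmax, params$hard_core)

  gr <- NULL
  if (params$gr_rmax > 0 && res$gr_frames > 0) {
    nb <- length(res$gr_hist)
    edges <- seq(0, by = res$gr_bin, length.out = nb + 1)
    rmid <- 0.5 * (edges[-1] + edges[-(nb + 1)])
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
    n <- nrow(initial$positions)
    ideal <- res$gr_rho_mean * shell * n
    gr <- data.frame(r = rmid, g = res$gr_hist / (res$gr_frames * ideal))
  }

  dens <- res$density_series
  nser <- length(dens)
  # standard error from 10 block means
  se <- NA_real_
  if (nser >= 20) {
    nb <- 10
    bm <- tapply(dens, cut(seq_len(nser), nb, labels = FALSE), mean)
    se <- stats::sd(bm) / sqrt(nb)
  }

  structure(list(
    final = configuration(res$positions, box = rep(res$L, 3)),
    mean_density = res$mean_density, density_se = se,
    mean_energy = res$mean_energy,
    energy_tracked = res$energy_tracked,
    energy_recomputed = res$energy_recomputed,
    acc_translation = res$acc_translation, acc_volume = res$acc_volume,
    gr = gr,
    frames = lapply(seq_along(res$frames), function(i)
      configuration(res$frames[[i]], box = rep(res$frame_L[i], 3))),
    params = params), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: <rho> = %.5f, <E> = %.4f kT, acc(tr) = %.2f%s\n",
              x$mean_density, x$mean_energy, x$acc_translation,
              if (!is.na(x$acc_volume)) sprintf(", acc(V) = %.2f", x$acc_volume)
              else ""))
  invisible(x)
}

#' Equation of state over a pressure ladder
#'
#' @param model a `cg_model` (or NULL for the ideal gas).
#' @param pressures reduced pressures.
#' @param params base [mc_params()] (ensemble forced to NPT).
#' @param rho_init starting density; `NULL` starts each state point at the
#'   ideal-gas guess `rho = beta P` so the box only has to relax locally.
#' @return data.frame with pressure, mean density and its standard error.
#' @export
mc_eos <- function(model, pressures, params = mc_params("NPT", pressure = 1),
                   rho_init = NULL) {
  rows <- lapply(seq_along(pressures), function(k) {
    p <- params
    p$ensemble <- "NPT"
    p$pressure <- pressures[k]
    p$seed <- params$seed + k
    r <- mc_run(model, p,
                rho_init = if (is.null(rho_init)) pressures[k] else rho_init)
    data.frame(pressure = pressures[k], density = r$mean_density,
               density_se = r$density_se)
  })
  do.call(rbind, rows)
}

#' Radial distribution function from trajectory frames
#'
#' Standard pair-histogram normalization against the ideal-gas shell count.
#'
#' @param frames list of periodic [configuration()]s.
#' @param bin_width histogram bin (sigma_c).
#' @param r_max histogram range; capped at half the smallest box edge.
#' @return data.frame with `r` and `g`.
#' @export
radial_distribution <- function(frames, bin_width = 0.05, r_max = NULL) {
  if (inherits(frames, "cg_configuration")) frames <- list(frames)
  Lmin <- min(vapply(frames, function(f) min(f$box), numeric(1)))
  if (is.null(r_max)) r_max <- Lmin / 2
  r_max <- min(r_max, Lmin / 2)
  nb <- floor(r_max / bin_width)   # whole bins only, all below r_max
  r_max <- nb * bin_width
  hist <- numeric(nb)
  norm <- numeric(nb)
  edges <- seq(0, by = bin_width, length.out = nb + 1)
  for (f in frames) {
    n <- nrow(f$positions)
    d <- pair_distances(f)
    du <- d[upper.tri(d)]
    counts <- graphics::hist(du[du < r_max], breaks = edges, plot = FALSE)$counts
    hist <- hist + 2 * counts
    rho <- n / prod(f$box)
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
    norm <- norm + n * rho * shell
  }
  data.frame(r = 0.5 * (edges[-1] + edges[-(nb + 1)]), g = hist / norm)
}

#' Rigid-geometry potential scans (triplet and quartet probes)
#'
#' Fixes two particles J, K at separation `d` and moves a probe particle I
#' along geometry-specific paths (open boundaries):
#' * `"T"`: I on the perpendicular bisector of JK, `h` = distance from the
#'   JK midpoint;
#' * `"L"`: I collinear with JK on the far side of J, `h` = distance from J;
#' * `"SQ"`: a second pair I, I' parallel to JK at lateral offset `h`
#'   (rectangle d x h).
#'
#' Both the many-body model and the pairwise reference (the pair model summed
#' over all pairs) are evaluated; their difference is the three-and-higher
#' body correction `Phi3plus`.
#'
#' @param model_many the many-body `cg_model`.
#' @param model_pair the two-body `cg_model` used pairwise.
#' @param geometry `"T"`, `"L"` or `"SQ"`.
#' @param d fixed pair separation (sigma_c).
#' @param h probe positions (sigma_c).
#' @return data.frame with `h`, `phi_many`, `phi_pairsum`, `phi3plus`.
#' @export
geometry_scan <- function(model_many, model_pair, geometry = c("T", "L", "SQ"),
                          d = 1.88, h = seq(1, 4, by = 0.1)) {
  geometry <- match.arg(geometry)
  make_config <- function(hh) {
    J <- c(-d / 2, 0, 0)
    K <- c(d / 2, 0, 0)
    pos <- switch(geometry,
      "T" = rbind(J, K, c(0, hh, 0)),
      "L" = rbind(J, K, c(-d / 2 - hh, 0, 0)),
      "SQ" = rbind(J, K, c(-d / 2, hh, 0), c(d / 2, hh, 0)))
    configuration(pos)
  }
  pair_sum <- function(config) {
    dm <- pair_distances(config)
    n <- nrow(config$positions)
    tot <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      tot <- tot + evaluate_pmf(model_pair, pair_configuration(dm[a, b]))$energy
    tot
  }
  rows <- lapply(h, function(hh) {
    cf <- make_config(hh)
    many <- evaluate_pmf(model_many, cf)$energy
    ps <- pair_sum(cf)
    data.frame(h = hh, phi_many = many, phi_pairsum = ps,
               phi3plus = many - ps)
  })
  do.call(rbind, rows)
}
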