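#' Symmetry-function specification
#'
#' One Behler-Parrinello descriptor. Radial descriptors are parameterized by
#' the Gaussian width parameter `mu` (units 1/sigma_c^2) and shift `Rs`
#' (sigma_c); angular descriptors by the radial width `mua` (1/sigma_c^2), the
#' angular resolution exponent `xi` and the sign `lambda` (+1 or -1). All
#' descriptors share a smooth cosine cutoff at `Rc`.
#'
#' @param kind `"radial"` or `"angular"`.
#' @param mu radial Gaussian width parameter (radial kind only).
#' @param Rs radial Gaussian shift (radial kind only).
#' @param mua angular radial width parameter (angular kind only).
#' @param xi angular resolution exponent, > 0 (angular kind only).
#' @param lambda +1 or -1 (angular kind only).
#' @param Rc cutoff radius, > 0.
#' @return an `sf_spec` object.
#' @export
sf_spec <- function(kind = c("radial", "angular"), mu = NA, Rs = NA,
                    mua = NA, xi = NA, lambda = NA, Rc) {
  kind <- match.arg(kind)
  if (!is.numeric(Rc) || Rc <= 0) stop("Rc must be positive")
  if (kind == "radial") {
    if (is.na(mu) || is.na(Rs)) stop("radial spec needs mu and Rs")
    if (mu < 0 || Rs < 0) stop("mu and Rs must be non-negative")
    if (!is.na(mua) || !is.na(xi) || !is.na(lambda))
      stop("radial spec must leave angular fields unset")
    mua <- xi <- lambda <- 0
  } else {
    if (is.na(mua) || is.na(xi) || is.na(lambda))
      stop("angular spec needs mua, xi and lambda")
    if (!is.na(mu) || !is.na(Rs))
      stop("angular spec must leave radial fields unset")
    if (xi <= 0) stop("xi must be positive")
    if (!(lambda %in% c(-1, 1))) stop("lambda must be +1 or -1")
    mu <- Rs <- 0
  }
  structure(list(kind = kind, mu = mu, Rs = Rs, mua = mua, xi = xi,
                 lambda = lambda, Rc = Rc), class = "sf_spec")
}

#' @export
print.sf_spec <- function(x, ...) {
  if (x$kind == "radial")
    cat(sprintf("radial SF: mu=%g Rs=%g Rc=%g\n", x$mu, x$Rs, x$Rc))
  else
    cat(sprintf("angular SF: mua=%g xi=%g lambda=%+d Rc=%g\n",
                x$mua, x$xi, as.integer(x$lambda), x$Rc))
  invisible(x)
}

# list of sf_spec -> 7-column matrix consumed by the C++ kernels
spec_matrix <- function(specs) {
  if (inherits(specs, "sf_spec")) specs <- list(specs)
  m <- t(vapply(specs, function(s) {
    c(if (s$kind == "radial") 0 else 1, s$mu, s$Rs, s$mua, s$xi, s$lambda, s$Rc)
  }, numeric(7)))
  colnames(m) <- c("kind", "mu", "Rs", "mua", "xi", "lambda", "Rc")
  m
}

#' Smooth cosine cutoff function
#'
#' `0.5 * (cos(pi r / Rc) + 1)` up to the cutoff radius, exactly zero
#' beyond. Both the value and the first derivative vanish at the cutoff.
#'
#' @param r distance(s), non-negative.
#' @param Rc cutoff radius, positive.
#' @return cutoff values in `[0, 1]`.
#' @export
cutoff_value <- function(r, Rc) {
  if (any(r < 0)) stop("r must be non-negative")
  if (!is.numeric(Rc) || Rc <= 0) stop("Rc must be positive")
  ifelse(r <= Rc, 0.5 * (cos(pi * r / Rc) + 1), 0)
}

#' Evaluate symmetry functions for all sites of a configuration
#'
#' @param config a [configuration()].
#' @param specs an `sf_spec` or list of them.
#' @return an N x M matrix of descriptor values (the descriptor table).
#' @export
sf_values <- function(config, specs) {
  cpp_sf_values(config$positions, box_or_na(config), spec_matrix(specs))
}

#' Radial symmetry function centered on one site
#'
#' @param config a [configuration()].
#' @param center site index (1-based).
#' @param spec a radial `sf_spec`.
#' @return the descriptor value.
#' @export
radial_sf <- function(config, center, spec) {
  if (spec$kind != "radial") stop("spec must be radial")
  sf_values(config, spec)[center, 1]
}

#' Angular symmetry function centered on one site
#'
#' @param config a [configuration()].
#' @param center site index (1-based).
#' @param spec an angular `sf_spec`.
#' @return the descriptor value.
#' @export
angular_sf <- function(config, center, spec) {
  if (spec$kind != "angular") stop("spec must be angular")
  sf_values(config, spec)[center, 1]
}

#' Analytic gradients of all symmetry functions
#'
#' Returns the dense tensor `dG_J(K)/dR_{I,alpha}` with dimensions
#' `(site I, component alpha, descriptor J, center K)`. Intended for
#' validation on small systems; the force-matching design block is assembled
#' by [sf_design()] without materializing this tensor.
#'
#' @param config a [configuration()] with at most 64 sites.
#' @param specs an `sf_spec` or list of them.
#' @return a 4-d array `(N, 3, M, N)`.
#' @export
sf_gradients <- function(config, specs) {
  sm <- spec_matrix(specs)
  if (nrow(sm) < 1) stop("specs must be non-empty")
  g <- cpp_sf_grad_tensor(config$positions, box_or_na(config), sm)
  array(g, dim = c(n_sites(config), 3, nrow(sm), n_sites(config)))
}

#' Force-matching design block for one configuration
#'
#' Row `3 (I - 1) + alpha`, column `J` holds
#' `-sum_K dG_J(K) / dR_{I,alpha}`: the model force on site I along alpha per
#' unit weight of descriptor J.
#'
#' @param config a [configuration()].
#' @param specs an `sf_spec` or list of them.
#' @return a `3N x M` matrix.
#' @export
sf_design <- function(config, specs) {
  cpp_sf_design(config$positions, box_or_na(config), spec_matrix(specs))
}

#' Build a descriptor pool from parameter value lists
#'
#' The pool is the Cartesian product of the radial parameters `mu x Rs` plus,
#' when angular lists are supplied, the product `mua x lambda x xi`,
#' deduplicated, all sharing the cutoff `Rc`.
#'
#' @param mu radial width values (1/sigma_c^2).
#' @param Rs radial shift values (sigma_c).
#' @param mua angular radial width values, or NULL for a radial-only pool.
#' @param xi angular exponents.
#' @param lambda angular signs (+1/-1).
#' @param Rc shared cutoff.
#' @return a list of `sf_spec` objects.
#' @export
build_pool <- function(mu, Rs, mua = NULL, xi = NULL, lambda = NULL, Rc = 2.5) {
  if (length(mu) < 1 || length(Rs) < 1) stop("parameter lists must be non-empty")
  rad <- unique(expand.grid(mu = mu, Rs = Rs))
  pool <- lapply(seq_len(nrow(rad)), function(i)
    sf_spec("radial", mu = rad$mu[i], Rs = rad$Rs[i], Rc = Rc))
  if (!is.null(mua)) {
    if (length(xi) < 1 || length(lambda) < 1)
      stop("angular pool needs xi and lambda lists")
    ang <- unique(expand.grid(mua = mua, lambda = lambda, xi = xi))
    pool <- c(pool, lapply(seq_len(nrow(ang)), function(i)
      sf_spec("angular", mua = ang$mua[i], xi = ang$xi[i],
              lambda = ang$lambda[i], Rc = Rc)))
  }
  pool
}

#' Descriptor pool used for two-nanoparticle training
#'
#' 22 radial widths times 15 shifts (330 radial candidates) with cutoff
#' `Rc = 2.5 sigma_c`.
#'
#' @param Rc cutoff radius.
#' @return a list of `sf_spec` objects.
#' @export
np_pair_pool <- function(Rc = 2.5) {
  mu <- c(0.00001, 0.0001, 0.001, 1.715, 3.429, 5.144, 6.858, 8.572, 10.286,
          12.000, 13.715, 15.429, 17.143, 18.857, 20.572, 22.286, 24.000,
          26.000, 28.000, 30.000, 32.000, 34.000)
  Rs <- seq(0, 1.4, by = 0.1)
  build_pool(mu, Rs, Rc = Rc)
}

#' Descriptor pool used for 12-nanoparticle training
#'
#' 10 x 10 radial candidates plus 8 x 2 x 4 angular candidates with cutoff
#' `Rc = 2.5 sigma_c`.
#'
#' @param Rc cutoff radius.
#' @return a list of `sf_spec` objects.
#' @export
np_cluster_pool <- function(Rc = 2.5) {
  mu <- c(0.001, 1.715, 3.429, 5.144, 6.858, 8.572, 10.286, 12.000, 13.715,
          15.429)
  Rs <- seq(0, 0.9, by = 0.1)
  mua <- c(0.0001, 0.001, 0.01, 0.1, 1.0, 2.0, 4.0, 8.0)
  build_pool(mu, Rs, mua = mua, xi = c(1, 4, 8, 12), lambda = c(1, -1), Rc = Rc)
}
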