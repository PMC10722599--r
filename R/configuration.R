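#' Particle configuration
#'
#' A configuration holds the positions of N sites (coarse-grained particles or
#' fine-grained beads) together with an optional orthorhombic periodic box.
#' Lengths are in reduced units of the core diameter \eqn{\sigma_c} unless a
#' different unit system is recorded by the caller. Open (non-periodic)
#' cluster geometries are represented by `box = NULL`.
#'
#' @param positions numeric matrix with N rows and 3 columns.
#' @param box either `NULL` for open boundaries or a numeric vector of three
#'   positive edge lengths.
#' @param species optional character or integer vector of length N.
#' @return an object of class `cg_configuration`.
#' @export
configuration <- function(positions, box = NULL, species = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (nrow(positions) < 1L) stop("a configuration needs at least one site")
  if (!all(is.finite(positions))) stop("positions must be finite")
  storage.mode(positions) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) == 1L) box <- rep(box, 3L)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive edge lengths (or NULL for open boundaries)")
  }
  if (!is.null(species) && length(species) != nrow(positions))
    stop("species must have one entry per site")
  structure(list(positions = positions, box = box, species = species),
            class = "cg_configuration")
}

#' @export
print.cg_configuration <- function(x, ...) {
  cat(sprintf("cg_configuration: %d sites, %s\n", nrow(x$positions),
              if (is.null(x$box)) "open boundaries"
              else sprintf("box %.4g x %.4g x %.4g", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

n_sites <- function(config) nrow(config$positions)

box_or_na <- function(config) {
  if (is.null(config$box)) NA_real_ else config$box
}

#' Pair distances under the minimum-image convention
#'
#' @param config a [configuration()].
#' @return a numeric matrix of all pairwise distances.
#' @export
pair_distances <- function(config) {
  pos <- config$positions
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    if (!is.null(config$box)) dk <- dk - config$box[k] * round(dk / config$box[k])
    d <- d + dk^2
  }
  sqrt(d)
}

#' Place two sites at a given separation
#'
#' Convenience constructor for pair geometries: two sites separated by `r`
#' along a (unit) direction, centered at the origin, open boundaries.
#'
#' @param r separation distance.
#' @param direction length-3 direction vector (normalized internally).
#' @return a [configuration()] with two sites.
#' @export
pair_configuration <- function(r, direction = c(1, 0, 0)) {
  u <- direction / sqrt(sum(direction^2))
  configuration(rbind(-0.5 * r * u, 0.5 * r * u))
}
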