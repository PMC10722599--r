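#' Mean-force dataset
#'
#' Pairs each configuration with the mean-force 3-vectors measured on its
#' sites. Forces are in `k_B T / sigma_c`, lengths in `sigma_c` (reduced
#' units) unless a different unit string is recorded.
#'
#' @param configs list of [configuration()] objects.
#' @param forces list of N x 3 matrices, one per configuration.
#' @param units unit string recorded in file headers.
#' @param beta inverse temperature of the sampling ensemble (1 in reduced units).
#' @param source free-text provenance (model, sampling lengths, seed).
#' @return a `mean_force_dataset`.
#' @export
mean_force_dataset <- function(configs, forces, units = "kT/sigma_c",
                               beta = 1, source = "") {
  if (inherits(configs, "cg_configuration")) configs <- list(configs)
  if (is.matrix(forces)) forces <- list(forces)
  if (length(configs) != length(forces))
    stop("configs and forces must have the same length")
  for (i in seq_along(configs)) {
    f <- as.matrix(forces[[i]])
    if (nrow(f) != n_sites(configs[[i]]) || ncol(f) != 3L)
      stop(sprintf("frame %d: forces must be one 3-vector per site", i))
    if (any(!is.finite(f))) stop(sprintf("frame %d: non-finite force", i))
    storage.mode(f) <- "double"
    forces[[i]] <- f
  }
  structure(list(configs = configs, forces = forces, units = units,
                 beta = beta, source = source),
            class = "mean_force_dataset")
}

#' @export
print.mean_force_dataset <- function(x, ...) {
  ns <- vapply(x$configs, n_sites, integer(1))
  cat(sprintf("mean_force_dataset: %d configurations, %d sites, %d force rows (%s)\n",
              length(x$configs), sum(ns), 3L * sum(ns), x$units))
  invisible(x)
}

#' Number of force-component training rows in a dataset
#' @param dataset a [mean_force_dataset()].
#' @return integer row count (3 per site per configuration).
#' @export
n_force_rows <- function(dataset) {
  3L * sum(vapply(dataset$configs, n_sites, integer(1)))
}

#' Write a mean-force table
#'
#' Tab-separated, one row per (configuration, site): frame id, site id and the
#' three force components. A comment header records units and beta so loaders
#' can refuse mismatched files.
#'
#' @param dataset a [mean_force_dataset()].
#' @param path output path.
#' @export
write_forces_table <- function(dataset, path) {
  rows <- do.call(rbind, lapply(seq_along(dataset$configs), function(i) {
    f <- dataset$forces[[i]]
    data.frame(frame = i, site = seq_len(nrow(f)),
               fx = f[, 1], fy = f[, 2], fz = f[, 3])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units: %s", dataset$units),
               sprintf("# beta: %.17g", dataset$beta),
               sprintf("# source: %s", dataset$source),
               "frame\tsite\tfx\tfy\tfz"), con)
  utils::write.table(format(rows, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a mean-force table
#'
#' @param path forces table written by [write_forces_table()].
#' @param configs the matching list of configurations.
#' @return a [mean_force_dataset()].
#' @export
read_forces_table <- function(path, configs) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  units <- sub("^# units:\\s*", "", grep("^# units:", hdr, value = TRUE))
  if (length(units) != 1L)
    stop("forces table is missing its units header; refusing to load")
  beta <- as.numeric(sub("^# beta:\\s*", "", grep("^# beta:", hdr, value = TRUE)))
  if (length(beta) != 1L || is.na(beta)) stop("forces table is missing beta")
  source <- sub("^# source:\\s*", "", grep("^# source:", hdr, value = TRUE))
  if (length(source) == 0L) source <- ""
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) <= 1L) stop("forces table contains no data rows")
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (inherits(configs, "cg_configuration")) configs <- list(configs)
  forces <- lapply(seq_along(configs), function(i) {
    sub <- tab[tab$frame == i, , drop = FALSE]
    sub <- sub[order(sub$site), , drop = FALSE]
    if (nrow(sub) != n_sites(configs[[i]]))
      stop(sprintf("frame %d: table has %d rows but configuration has %d sites",
                   i, nrow(sub), n_sites(configs[[i]])))
    as.matrix(sub[, c("fx", "fy", "fz")])
  })
  mean_force_dataset(configs, forces, units = units, beta = beta,
                     source = source)
}
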