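# Run configuration (YAML, nested sections) and the end-to-end pipeline.

RUNCONFIG_SECTIONS <- c("seed", "units", "geometry", "forcefield", "pools",
                        "selection", "sampling", "ladder", "ao", "mc",
                        "pipeline")

#' Read a run configuration file
#'
#' YAML with nested sections (`geometry`, `forcefield`, `pools`, `selection`,
#' `sampling`, `ladder`, `ao`, `mc`, `pipeline`) plus a global `seed` and
#' `units`. Unknown top-level sections are rejected.
#'
#' @param path YAML file.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUNCONFIG_SECTIONS)
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration section(s): %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$units)) cfg$units <- "reduced"
  structure(cfg, class = "run_config")
}

#' Derive a per-stage RNG seed from the global seed
#'
#' Deterministic and stage-tagged so every stochastic stage has its own
#' stream; kept below 2^31.
#'
#' @param seed global integer seed.
#' @param tag stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

pool_from_config <- function(pcfg, q = 1) {
  if (is.null(pcfg)) return(ao_pool(q))
  build_pool(mu = as.numeric(pcfg$mu), Rs = as.numeric(pcfg$Rs),
             mua = if (!is.null(pcfg$mua)) as.numeric(pcfg$mua),
             xi = if (!is.null(pcfg$xi)) as.numeric(pcfg$xi),
             lambda = if (!is.null(pcfg$lambda)) as.numeric(pcfg$lambda),
             Rc = if (!is.null(pcfg$Rc)) as.numeric(pcfg$Rc) else 2.5)
}

#' Run the AO coarse-graining pipeline
#'
#' Generates fine-grained reference data (quadrature depletion mean forces),
#' selects descriptors, fits the linear model, writes the artifacts, and
#' reports the learned pair potential against the closed-form depletion
#' potential.
#'
#' @param config a [read_run_config()] result (or a plain list with the same
#'   sections).
#' @param outdir output directory for artifacts.
#' @return list with the dataset, trace, model, and the comparison table.
#' @export
pipeline_run <- function(config, outdir = tempfile("cgpmf_run_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  aoc <- config$ao
  ao <- ao_params(q = if (is.null(aoc$q)) 1 else aoc$q,
                  eta_p = if (is.null(aoc$eta_p)) 0.5 else aoc$eta_p)
  seps <- if (!is.null(aoc$separations)) as.numeric(aoc$separations)
          else seq(1.0, 2.4, by = 0.02)
  t0 <- proc.time()[3]
  message(sprintf("[fgsim] AO pair scan: q=%g eta_p=%g, %d separations (seed %d)",
                  ao$q, ao$eta_p, length(seps), seed))
  dataset <- ao_pair_dataset(seps, ao, seed = derive_seed(seed, "fgsim"))
  write_forces_table(dataset, file.path(outdir, "mean_forces.tsv"))
  write_extxyz(dataset$configs, file.path(outdir, "configs.extxyz"))

  pool <- pool_from_config(config$pools, q = ao$q)
  delta <- if (!is.null(config$selection$delta_r2_min))
    config$selection$delta_r2_min else 1e-4
  message(sprintf("[forcematch] pool of %d descriptors, delta_r2_min = %g",
                  length(pool), delta))
  design <- assemble_design(dataset, pool)
  trace <- select_features(design, delta_r2_min = delta)
  model <- fit_weights(design, trace)
  write_model(model, file.path(outdir, "model.json"),
              provenance = list(seed = seed, stage = "ao-pair"))

  grid <- seq(min(seps), 2 * ao$r_excl, by = 0.01)
  cmp <- model_pair_pmf(model, grid)
  cmp$phi_analytic <- ao_analytic_depletion(grid, ao)
  cmp$abs_err <- abs(cmp$phi - cmp$phi_analytic)
  utils::write.table(cmp, file.path(outdir, "pmf_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("[report] %d descriptors selected, fit R^2 = %.6f, max |dPhi| = %.4f kT (%.1f s)",
                  length(trace$selected), model$diagnostics$r2,
                  max(cmp$abs_err), proc.time()[3] - t0))
  invisible(list(dataset = dataset, trace = trace, model = model,
                 comparison = cmp, outdir = outdir))
}
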