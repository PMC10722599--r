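# Versioned structured-text model files. Doubles are serialized via
# sprintf("%.17g"), which round-trips IEEE doubles bit-exactly.

MODEL_SCHEMA_VERSION <- 1L

num17 <- function(x) sprintf("%.17g", x)

#' Write a fitted model to a structured-text file
#'
#' JSON with schema version, unit system, cutoff, ordered specs, weights,
#' isolated-particle reference values, fit diagnostics and provenance.
#' Numeric fields are stored at full precision so that
#' `read_model(write_model(m))` reproduces `m` bit-exactly.
#'
#' @param model a `cg_model`.
#' @param path output path.
#' @param provenance optional list (dataset hash, seed, ...).
#' @export
write_model <- function(model, path, provenance = list()) {
  specs <- lapply(model$specs, function(s) list(
    kind = s$kind, mu = num17(s$mu), Rs = num17(s$Rs), mua = num17(s$mua),
    xi = num17(s$xi), lambda = num17(s$lambda), Rc = num17(s$Rc)))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    units = list(length = "sigma_c", energy = "kT"),
    Rc = num17(model$Rc),
    baseline = num17(model$baseline),
    specs = specs,
    weights = vapply(model$weights, num17, character(1)),
    isolated_reference = vapply(model$isolated_reference, num17, character(1)),
    diagnostics = lapply(model$diagnostics, function(v)
      if (is.numeric(v)) num17(v) else v),
    provenance = provenance)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' Read a model file
#'
#' @param path file written by [write_model()].
#' @return a `cg_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version > MODEL_SCHEMA_VERSION)
    stop("unsupported model schema version")
  specs <- lapply(obj$specs, function(s) {
    if (s$kind == "radial")
      sf_spec("radial", mu = as.numeric(s$mu), Rs = as.numeric(s$Rs),
              Rc = as.numeric(s$Rc))
    else
      sf_spec("angular", mua = as.numeric(s$mua), xi = as.numeric(s$xi),
              lambda = as.numeric(s$lambda), Rc = as.numeric(s$Rc))
  })
  diag <- lapply(obj$diagnostics, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  m <- cg_model(specs, as.numeric(unlist(obj$weights)), diagnostics = diag)
  m$isolated_reference <- as.numeric(unlist(obj$isolated_reference))
  m$baseline <- as.numeric(obj$baseline)
  m$provenance <- obj$provenance
  m
}
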