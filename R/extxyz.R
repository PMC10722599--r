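# Extended-XYZ reader/writer (ASE-style "Lattice=..." comment line).
# Open-boundary frames carry no Lattice record.

#' Read configurations from an extended-XYZ file
#'
#' Supports multi-frame files. The comment line may carry an orthorhombic
#' `Lattice="ax 0 0 0 by 0 0 0 cz"` record; frames without one are returned
#' as open-boundary configurations.
#'
#' @param path file path.
#' @return a list of [configuration()] objects.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(n) || n < 1L)
      stop(sprintf("extxyz parse error at line %d: bad atom count", i))
    if (i + 1L + n > length(lines))
      stop(sprintf("extxyz parse error: frame %d truncated (line %d)", frame, i))
    comment <- lines[i + 1L]
    box <- NULL
    m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(m) == 1L && nzchar(m)) {
      vals <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "[ \t]+")[[1]])
      vals <- vals[!is.na(vals)]
      if (length(vals) != 9L)
        stop(sprintf("extxyz parse error at line %d: Lattice needs 9 numbers", i + 1L))
      off <- abs(vals[c(2, 3, 4, 6, 7, 8)])
      if (any(off > 1e-10))
        stop("only orthorhombic lattices are supported")
      box <- vals[c(1, 5, 9)]
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[ \t]+")
    species <- vapply(toks, `[[`, "", 1L)
    pos <- t(vapply(toks, function(tk) {
      if (length(tk) < 4L) stop("extxyz parse error: atom line needs 4 fields")
      as.numeric(tk[2:4])
    }, numeric(3)))
    if (any(!is.finite(pos)))
      stop(sprintf("extxyz parse error in frame %d: non-numeric coordinate", frame))
    configs[[frame]] <- configuration(pos, box = box, species = species)
    i <- i + 2L + n
  }
  configs
}

#' Write configurations to an extended-XYZ file
#'
#' @param configs a [configuration()] or a list of them.
#' @param path output file path.
#' @param comment optional extra comment text per frame.
#' @export
write_extxyz <- function(configs, path, comment = NULL) {
  if (inherits(configs, "cg_configuration")) configs <- list(configs)
  out <- character(0)
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    n <- nrow(cf$positions)
    head <- if (is.null(cf$box)) "Properties=species:S:1:pos:R:3"
    else sprintf('Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" Properties=species:S:1:pos:R:3 pbc="T T T"',
                 cf$box[1], cf$box[2], cf$box[3])
    if (!is.null(comment)) head <- paste(head, comment[min(k, length(comment))])
    sp <- cf$species
    if (is.null(sp)) sp <- rep("X", n)
    body <- sprintf("%s %.17g %.17g %.17g", sp,
                    cf$positions[, 1], cf$positions[, 2], cf$positions[, 3])
    out <- c(out, as.character(n), head, body)
  }
  writeLines(out, path)
  invisible(path)
}
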