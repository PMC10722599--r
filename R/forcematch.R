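#' Assemble the linear force-matching design matrix
#'
#' Stacks per-configuration design blocks: the row for configuration c, site
#' I, Cartesian component alpha holds, in column J, the model force
#' `-sum_K dG_J(K)/dR_{I,alpha}` per unit weight; the target vector holds the
#' measured mean-force components in `k_B T / sigma_c`.
#'
#' @param dataset a [mean_force_dataset()].
#' @param pool list of `sf_spec` candidate descriptors.
#' @return a `design_matrix`: list with `X` (rows x M), `y`, `pool`,
#'   `row_index` (frame/site/component bookkeeping).
#' @export
assemble_design <- function(dataset, pool) {
  if (length(pool) < 1) stop("pool must be non-empty")
  if (length(dataset$configs) < 1) stop("dataset must be non-empty")
  if (!identical(dataset$units, "kT/sigma_c"))
    stop(sprintf("dataset units '%s' do not match the reduced-unit convention kT/sigma_c",
                 dataset$units))
  blocks <- lapply(dataset$configs, sf_design, specs = pool)
  X <- do.call(rbind, blocks)
  y <- unlist(lapply(dataset$forces, function(f) as.vector(t(f))),
              use.names = FALSE)
  stopifnot(nrow(X) == length(y))
  ri <- do.call(rbind, lapply(seq_along(dataset$configs), function(i) {
    n <- n_sites(dataset$configs[[i]])
    data.frame(frame = i, site = rep(seq_len(n), each = 3L),
               component = rep(1:3, n))
  }))
  structure(list(X = X, y = y, pool = pool, row_index = ri),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d rows x %d candidate descriptors\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Squared Pearson correlation between a candidate column and the target
#'
#' @param column numeric vector.
#' @param target numeric vector of the same length.
#' @return c^2 in `[0, 1]`; zero-variance columns return 0 with attribute
#'   `degenerate = TRUE`.
#' @export
pearson_r2 <- function(column, target) {
  if (length(column) != length(target) || length(column) < 2)
    stop("column and target must have equal length >= 2")
  sx <- stats::sd(column)
  sy <- stats::sd(target)
  if (sy == 0) stop("target has zero variance")
  if (sx == 0) return(structure(0, degenerate = TRUE))
  stats::cor(column, target)^2
}

#' Squared coefficient of multiple correlation
#'
#' Fraction of (centered) target variance explained by a linear fit with
#' intercept on the selected columns. Two routes: the regression-residual
#' formulation (default, numerically stable) and the correlation-matrix form
#' `c^T R^-1 c`.
#'
#' @param columns numeric matrix of selected columns.
#' @param target numeric vector.
#' @param method `"residual"` or `"corrmatrix"`.
#' @return R^2 in `[0, 1]`.
#' @export
multiple_r2 <- function(columns, target, method = c("residual", "corrmatrix")) {
  method <- match.arg(method)
  columns <- as.matrix(columns)
  if (ncol(columns) < 1) stop("selected set must be non-empty")
  if (method == "corrmatrix") {
    cc <- apply(columns, 2, stats::cor, y = target)
    R <- stats::cor(columns)
    sol <- try(solve(R, cc), silent = TRUE)
    if (inherits(sol, "try-error"))
      return(multiple_r2(columns, target, method = "residual"))
    return(max(0, min(1, sum(cc * sol))))
  }
  yc <- target - mean(target)
  fit <- stats::lm.fit(cbind(1, columns), target)
  rss <- sum(fit$residuals^2)
  tss <- sum(yc^2)
  max(0, min(1, 1 - rss / tss))
}

#' Stepwise forward selection of descriptors by correlation
#'
#' The first pick maximizes the squared Pearson correlation with the target;
#' every subsequent pick maximizes the increase of the squared coefficient of
#' multiple correlation; selection stops when the best available increase
#' falls below `delta_r2_min`. All-zero (degenerate) columns are removed
#' before selection. Ties break toward the lowest column index.
#'
#' Internally the greedy step residualizes candidates against the selected
#' set (Gram-Schmidt), which is algebraically the regression-residual
#' formulation of the multiple correlation.
#'
#' @param design a [assemble_design()] result.
#' @param delta_r2_min stopping threshold on the R^2 increase.
#' @param max_features optional cap on the number of selected descriptors.
#' @return a `selection_trace`: ordered selected column indices, per-step c^2
#'   and cumulative R^2, and the dropped degenerate-column count.
#' @export
select_features <- function(design, delta_r2_min = 1e-4, max_features = Inf) {
  X <- design$X
  y <- design$y
  n <- nrow(X)
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  alive <- which(sds > 0)
  n_degenerate <- ncol(X) - length(alive)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0) stop("target has zero variance; nothing to select")

  # centered, unit-norm candidate columns (correlations are scale-free)
  Z <- sweep(X[, alive, drop = FALSE], 2, colMeans(X[, alive, drop = FALSE]))
  Z <- sweep(Z, 2, sqrt(colSums(Z^2)), "/")
  yr <- yc                        # residual target
  selected <- integer(0)
  c2_step <- numeric(0)
  r2_cum <- numeric(0)
  r2 <- 0

  while (length(alive) > length(selected) &&
         length(selected) < max_features) {
    avail <- setdiff(seq_along(alive), match(selected, alive))
    znorm2 <- colSums(Z[, avail, drop = FALSE]^2)
    proj <- as.vector(crossprod(Z[, avail, drop = FALSE], yr))
    # columns fully explained by the selected set have znorm2 ~ 0
    ok <- znorm2 > 1e-12
    gain <- rep(-Inf, length(avail))
    gain[ok] <- proj[ok]^2 / znorm2[ok] / tss
    best <- which.max(gain)      # which.max breaks ties at the lowest index
    if (!is.finite(gain[best])) break
    # the first pick (largest c^2) is always taken; the stopping rule
    # applies to the subsequent increments of the multiple correlation
    if (length(selected) > 0 && gain[best] < delta_r2_min) break
    j <- avail[best]
    # plain squared Pearson correlation of the chosen raw column with the
    # target; the gain itself is the multiple-R^2 increase
    c2_step <- c(c2_step, pearson_r2(X[, alive[j]], y))
    r2 <- r2 + gain[best]
    r2_cum <- c(r2_cum, min(r2, 1))
    # orthogonalize the chosen column and update residuals
    q <- Z[, j] / sqrt(znorm2[match(j, avail)])
    yr <- yr - sum(q * yr) * q
    keep <- setdiff(avail, j)
    if (length(keep) > 0) {
      coefs <- as.vector(crossprod(Z[, keep, drop = FALSE], q))
      Z[, keep] <- Z[, keep, drop = FALSE] - outer(q, coefs)
    }
    selected <- c(selected, j)
    if (r2 >= 1 - 1e-12) break
  }

  structure(list(selected = alive[selected], c2_step = c2_step,
                 delta_r2_step = diff(c(0, r2_cum)),
                 r2_cumulative = r2_cum, n_degenerate = n_degenerate,
                 delta_r2_min = delta_r2_min),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d descriptors selected, final R^2 = %.6f (%d degenerate columns dropped)\n",
              length(x$selected),
              if (length(x$r2_cumulative)) max(x$r2_cumulative) else 0,
              x$n_degenerate))
  invisible(x)
}

#' Fit descriptor weights by ordinary least squares
#'
#' No intercept: the mean force vanishes at infinite dilution, so the model
#' force is a pure linear combination of descriptor gradients and the
#' reference constant of the potential of mean force is identically zero.
#'
#' @param design a [assemble_design()] result.
#' @param trace a [select_features()] result (or an integer vector of column
#'   indices).
#' @return a `cg_model` with ordered specs, weights (k_B T per descriptor
#'   unit), cutoff, and fit diagnostics (R^2, RMSE in k_B T / sigma_c).
#' @export
fit_weights <- function(design, trace) {
  idx <- if (inherits(trace, "selection_trace")) trace$selected else as.integer(trace)
  if (length(idx) < 1) stop("selection trace is empty")
  X <- design$X[, idx, drop = FALSE]
  y <- design$y

  qrX <- qr(X)
  dropped <- integer(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- idx[-keep]
    warning(sprintf("rank deficiency: dropping %d column(s)", length(dropped)))
    idx <- idx[keep]
    X <- design$X[, idx, drop = FALSE]
    qrX <- qr(X)
  }
  w <- qr.coef(qrX, y)
  resid <- y - X %*% w
  rmse <- sqrt(mean(resid^2))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_

  specs <- design$pool[idx]
  cg_model(specs, as.numeric(w),
           diagnostics = list(r2 = r2, rmse = rmse, n_rows = length(y),
                              dropped_columns = length(dropped),
                              zero_variance_target = tss == 0))
}

#' Linear coarse-grained model
#'
#' An ordered set of symmetry-function specs with fitted weights. The scalar
#' many-body potential of mean force is
#' `Phi(R^N) = sum_K sum_J w_J (G_J(K) - G_J(isolated))` with the isolated
#' single-particle descriptor values as the infinite-dilution reference (both
#' radial and angular descriptors vanish for an isolated particle, so the
#' reference is zero); the force on site I is exactly `-grad_I Phi`.
#'
#' @param specs list of `sf_spec`.
#' @param weights numeric weights, one per spec.
#' @param diagnostics optional list of fit diagnostics.
#' @return a `cg_model`.
#' @export
cg_model <- function(specs, weights, diagnostics = list()) {
  if (inherits(specs, "sf_spec")) specs <- list(specs)
  if (length(specs) != length(weights))
    stop("one weight per spec required")
  rc <- max(vapply(specs, `[[`, numeric(1), "Rc"))
  structure(list(specs = specs, weights = as.numeric(weights), Rc = rc,
                 isolated_reference = rep(0, length(specs)),
                 baseline = 0, diagnostics = diagnostics),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  kinds <- vapply(x$specs, `[[`, character(1), "kind")
  cat(sprintf("cg_model: %d descriptors (%d radial, %d angular), Rc = %g sigma_c\n",
              length(x$specs), sum(kinds == "radial"), sum(kinds == "angular"),
              x$Rc))
  if (!is.null(x$diagnostics$r2))
    cat(sprintf("  fit: R^2 = %.6f, RMSE = %.4f kT/sigma_c (%d rows)\n",
                x$diagnostics$r2, x$diagnostics$rmse, x$diagnostics$n_rows))
  invisible(x)
}

#' Predict coarse-grained forces
#'
#' Force on site I is `-sum_K sum_J w_J dG_J(K)/dR_I`, identically the
#' negative analytic gradient of [evaluate_pmf()] (same gradient code path).
#'
#' @param model a `cg_model`.
#' @param config a [configuration()].
#' @return an N x 3 matrix of forces in `k_B T / sigma_c`.
#' @export
predict_forces <- function(model, config) {
  D <- sf_design(config, model$specs)
  matrix(D %*% model$weights, ncol = 3, byrow = TRUE)
}

#' Evaluate the many-body potential of mean force
#'
#' @param model a `cg_model`.
#' @param config a [configuration()].
#' @return list with `energy` (k_B T, zero at infinite dilution) and
#'   `per_site` contributions Phi_K.
#' @export
evaluate_pmf <- function(model, config) {
  phi <- cpp_site_energies(config$positions, box_or_na(config),
                           spec_matrix(model$specs), model$weights)
  phi <- phi - sum(model$isolated_reference * model$weights)
  list(energy = sum(phi), per_site = phi)
}

#' Two-body potential curve predicted by a model
#'
#' Evaluates the model on isolated pair configurations over a separation grid.
#'
#' @param model a `cg_model`.
#' @param r numeric vector of separations.
#' @return data.frame with `r` and `phi`.
#' @export
model_pair_pmf <- function(model, r) {
  phi <- vapply(r, function(ri)
    evaluate_pmf(model, pair_configuration(ri))$energy, numeric(1))
  data.frame(r = r, phi = phi)
}
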