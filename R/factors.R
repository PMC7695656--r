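#' Minimum-residual (minres) factor extraction
#'
#' Estimates a k-factor loading matrix by direct minimization of the sum
#' of squared off-diagonal residuals of `R - Lambda Lambda'`, the
#' minimum-residual (unweighted least squares) criterion. Optimization is
#' quasi-Newton (BFGS) over the loadings with the analytic gradient
#' `-4 E Lambda` (E the off-diagonal residual matrix), started from the
#' principal-axis solution with squared-multiple-correlation
#' communalities, which makes the fit deterministic.
#'
#' @param R Correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite within tolerance).
#' @param k Number of factors, 1 <= k < ncol(R).
#' @param max_iter Iteration cap for the optimizer.
#' @param reltol Relative convergence tolerance of the objective.
#' @return Object of class `factor_solution`: `loadings` (p x k),
#'   `uniquenesses` (1 - communality, floored at a small positive value;
#'   a warning is issued on Heywood cases), `explained_variance_share`
#'   (percent of total variance per factor, non-increasing),
#'   `eigenvalues` (of R, for the scree plot), `objective`, and
#'   `rotation = "none"`.
#' @export
fit_minres <- function(R, k, max_iter = 1000, reltol = 1e-14) {
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("R must have unit diagonal")
  if (k < 1 || k >= p) stop("k must satisfy 1 <= k < ", p)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) stop("R must be positive semidefinite")

  # principal-axis start with SMC communalities (ridge if R is singular)
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) rep(0.5, p))
  R0 <- R
  diag(R0) <- pmin(pmax(smc, 0.05), 0.95)
  e0 <- eigen(R0, symmetric = TRUE)
  L0 <- e0$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e0$values[seq_len(k)], 1e-8)), k)

  # a negligible ridge on the loadings selects the minimum-norm solution
  # when the off-diagonal residual criterion is not uniquely minimized
  # (e.g. a diagonal R); the reported objective is the raw criterion
  ridge <- 1e-6
  raw_obj <- function(l) {
    La <- matrix(l, p, k)
    E <- R - tcrossprod(La); diag(E) <- 0
    sum(E^2)
  }
  obj <- function(l) raw_obj(l) + ridge * sum(l^2)
  grd <- function(l) {
    La <- matrix(l, p, k)
    E <- R - tcrossprod(La); diag(E) <- 0
    as.vector(-4 * E %*% La) + 2 * ridge * l
  }
  opt <- optim(as.vector(L0), obj, grd, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  if (opt$convergence != 0)
    stop(sprintf("minres did not converge (residual norm %.3e)",
                 sqrt(opt$value)))
  L <- matrix(opt$par, p, k,
              dimnames = list(rownames(R), paste0("factor", seq_len(k))))
  new_factor_solution(L, eigenvalues = ev, rotation = "none",
                      objective = raw_obj(opt$par))
}

new_factor_solution <- function(L, eigenvalues, rotation, objective = NA_real_) {
  p <- nrow(L)
  comm <- rowSums(L^2)
  if (any(comm > 1 + 1e-6))
    warning("Heywood case: communality above 1 for ",
            paste(rownames(L)[comm > 1 + 1e-6], collapse = ", "))
  structure(list(loadings = L,
                 uniquenesses = pmax(1 - comm, 1e-6),
                 explained_variance_share = 100 * colSums(L^2) / p,
                 eigenvalues = eigenvalues,
                 rotation = rotation,
                 objective = objective),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf("Factor solution: %d variables, %d factors, rotation = %s\n",
              nrow(x$loadings), ncol(x$loadings), x$rotation))
  cat("Explained variance share (%):",
      paste(round(x$explained_variance_share, 1), collapse = ", "),
      sprintf(" (total %.1f%%)\n", sum(x$explained_variance_share)))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Varimax rotation with canonical column order and sign
#'
#' Orthogonally rotates a loading matrix to maximize the (Kaiser-
#' normalized) varimax criterion via [stats::varimax()], then sorts the
#' columns by explained variance (descending) and fixes each column's
#' sign so its largest-magnitude loading is positive. Being orthogonal,
#' the rotation preserves communalities and `Lambda Lambda'` exactly.
#'
#' @param x A `factor_solution` or a numeric loading matrix.
#' @return Same type as the input, rotated.
#' @export
varimax_rotate <- function(x) {
  L <- if (inherits(x, "factor_solution")) x$loadings else as.matrix(x)
  if (ncol(L) > 1L) {
    vr <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    L <- L %*% vr$rotmat
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  colnames(L) <- paste0("factor", seq_len(ncol(L)))
  if (inherits(x, "factor_solution"))
    new_factor_solution(L, eigenvalues = x$eigenvalues, rotation = "varimax",
                        objective = x$objective)
  else L
}

#' Scree table and elbow heuristic for the number of factors
#'
#' Always returns the full scree table (eigenvalue, first difference,
#' curvature). The suggested number of factors is the documented elbow
#' heuristic: one less than the position of maximum positive curvature
#' (second difference) of the eigenvalue profile — the point where the
#' decline flattens most sharply. When the largest curvature does not
#' dominate the second-largest by at least 50% the profile has no clear
#' elbow and the result is flagged; `k_override` (e.g. 5 for the
#' replication configuration) takes precedence over the heuristic.
#'
#' @param eigenvalues Eigenvalues sorted in decreasing order.
#' @param k_override Optional fixed k overriding the heuristic.
#' @return List with `scree` (data frame), `suggested_k`, `k` (override
#'   or suggestion), and `clear_elbow` (logical).
#' @export
retain_k <- function(eigenvalues, k_override = NULL) {
  if (is.unsorted(rev(eigenvalues) - 1e-12))
    stop("eigenvalues must be sorted in decreasing order")
  p <- length(eigenvalues)
  d1 <- c(NA, -diff(eigenvalues))
  curv <- c(NA, diff(diff(eigenvalues)), NA)  # e[i-1] - 2 e[i] + e[i+1]
  scree <- data.frame(index = seq_len(p), eigenvalue = eigenvalues,
                      drop = d1, curvature = curv)
  cv <- curv[!is.na(curv)]
  suggested <- which.max(curv) - 1L
  clear <- length(cv) >= 2 && {
    top <- sort(cv, decreasing = TRUE)[1:2]
    top[1] >= 1.5 * max(top[2], 1e-12)
  }
  k <- if (!is.null(k_override)) as.integer(k_override) else suggested
  list(scree = scree, suggested_k = suggested, k = k, clear_elbow = clear)
}

#' Pattern adherence scores with baseline scaling
#'
#' Computes the raw adherence score of every row as the loading-weighted
#' sum of its observed food-group intakes (`Lambda' x`, raw intakes, as
#' the default; set `standardize_inputs = TRUE` to z-score the food
#' groups first). When `scaling` is absent the scores are standardized to
#' mean zero and SD one and the scaling parameters returned (baseline
#' path); when supplied, the stored parameters are applied unchanged so
#' that follow-up scores are on the baseline scale.
#'
#' @param loadings p x k loading matrix with row names matching food
#'   groups (`fg_` prefixes in the data are handled).
#' @param tbl Data frame or matrix containing the food-group columns.
#' @param scaling Optional `adherence_scaling` from a previous (baseline)
#'   call.
#' @param standardize_inputs Z-score intakes before weighting (off by
#'   default).
#' @return List with `scores` (data frame of standardized scores, one
#'   column per pattern, plus `id`/`visit` if present in `tbl`) and
#'   `scaling` (class `adherence_scaling`: per-pattern mean and SD; also
#'   input means/SDs when `standardize_inputs`).
#' @export
adherence_scores <- function(loadings, tbl, scaling = NULL,
                             standardize_inputs = FALSE) {
  grp <- rownames(loadings)
  if (is.null(grp)) stop("'loadings' must have row names")
  cols <- ifelse(grp %in% colnames(tbl), grp, paste0("fg_", grp))
  missing <- grp[!cols %in% colnames(tbl)]
  if (length(missing))
    stop("food group column(s) not found: ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(tbl)[, cols, drop = FALSE])
  if (standardize_inputs) {
    if (is.null(scaling)) {
      im <- colMeans(X); isd <- apply(X, 2L, sd)
    } else {
      im <- scaling$input_mean; isd <- scaling$input_sd
    }
    if (any(isd == 0)) stop("constant food group; cannot standardize inputs")
    X <- sweep(sweep(X, 2L, im), 2L, isd, `/`)
  } else im <- isd <- NULL
  raw <- X %*% loadings
  if (is.null(scaling)) {
    mu <- colMeans(raw)
    sdev <- apply(raw, 2L, sd)
    if (any(sdev <= 0)) stop("degenerate adherence score: SD is zero")
    scaling <- structure(list(mean = mu, sd = sdev,
                              input_mean = im, input_sd = isd,
                              standardize_inputs = standardize_inputs),
                         class = "adherence_scaling")
  } else {
    if (!inherits(scaling, "adherence_scaling")) stop("invalid 'scaling'")
    if (!identical(scaling$standardize_inputs, standardize_inputs))
      stop("'standardize_inputs' differs from the stored scaling")
  }
  std <- sweep(sweep(raw, 2L, scaling$mean), 2L, scaling$sd, `/`)
  colnames(std) <- paste0("score_", colnames(loadings))
  scores <- as.data.frame(std)
  for (nm in c("visit", "id"))
    if (is.data.frame(tbl) && nm %in% names(tbl))
      scores <- cbind(setNames(tbl[nm], nm), scores)
  list(scores = scores, scaling = scaling)
}

#' Persist / restore adherence scaling parameters
#'
#' @param scaling An `adherence_scaling`.
#' @param path JSON file path.
#' @return `write_scaling` invisibly returns `path`; `read_scaling`
#'   returns the `adherence_scaling`.
#' @export
write_scaling <- function(scaling, path) {
  jsonlite::write_json(list(mean = as.list(scaling$mean),
                            sd = as.list(scaling$sd),
                            input_mean = as.list(scaling$input_mean),
                            input_sd = as.list(scaling$input_sd),
                            standardize_inputs = scaling$standardize_inputs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = unlist(x$mean), sd = unlist(x$sd),
                 input_mean = if (length(x$input_mean)) unlist(x$input_mean),
                 input_sd = if (length(x$input_sd)) unlist(x$input_sd),
                 standardize_inputs = isTRUE(x$standardize_inputs)),
            class = "adherence_scaling")
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors, used to compare a
#' recovered factor with a generating one.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match recovered factors to reference factors
#'
#' Finds the column permutation of `recovered` maximizing the total
#' absolute Tucker congruence with `reference` (optimal assignment by
#' exhaustive enumeration; factor counts above 8 are refused), then
#' aligns signs.
#'
#' @param recovered,reference Loading matrices with equal dimensions.
#' @return List with `permutation` (recovered column for each reference
#'   column), `signs`, `congruence` (per reference factor, after sign
#'   alignment) and `matched` (the permuted, sign-aligned recovered
#'   matrix).
#' @export
match_factors <- function(recovered, reference) {
  k <- ncol(reference)
  if (ncol(recovered) != k) stop("factor counts differ")
  if (k > 8) stop("exhaustive matching supports at most 8 factors")
  C <- crossprod(recovered, reference) /
    outer(sqrt(colSums(recovered^2)), sqrt(colSums(reference^2)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_v <- -Inf
  for (pm in perms(seq_len(k))) {
    v <- sum(abs(C[cbind(pm, seq_len(k))]))
    if (v > best_v) { best_v <- v; best <- pm }
  }
  cg <- C[cbind(best, seq_len(k))]
  signs <- ifelse(cg < 0, -1, 1)
  matched <- sweep(recovered[, best, drop = FALSE], 2L, signs, `*`)
  colnames(matched) <- colnames(reference)
  list(permutation = best, signs = signs, congruence = abs(cg),
       matched = matched)
}

#' Defining food groups of each pattern
#'
#' Reports, per factor, the groups whose absolute loading exceeds the
#' reporting threshold used for heat-map display (default 0.2).
#'
#' @param solution A `factor_solution` or loading matrix.
#' @param threshold Absolute loading threshold.
#' @return Named list of character vectors.
#' @export
defining_groups <- function(solution, threshold = 0.2) {
  L <- if (inherits(solution, "factor_solution")) solution$loadings else solution
  lapply(setNames(seq_len(ncol(L)), colnames(L)), function(j)
    rownames(L)[abs(L[, j]) > threshold])
}
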