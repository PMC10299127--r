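# Symmetric-matrix functional calculus via eigendecomposition. All inputs
# are forced symmetric before decomposition; these back the tangent-space
# machinery and the SPD validity checks.

sym <- function(M) (M + t(M)) / 2

spd_fun <- function(M, f, what = "matrix", require_pd = TRUE) {
  ev <- eigen(sym(M), symmetric = TRUE)
  if (require_pd && min(ev$values) <= 0)
    stopf("%s is not positive definite (min eigenvalue %.3e)",
          what, min(ev$values))
  sym(ev$vectors %*% (f(ev$values) * t(ev$vectors)))
}

spd_sqrt <- function(M, what = "matrix") spd_fun(M, sqrt, what)
spd_invsqrt <- function(M, what = "matrix") spd_fun(M, function(v) 1 / sqrt(v), what)
spd_logm <- function(M, what = "matrix") spd_fun(M, log, what)
sym_expm <- function(M) spd_fun(M, exp, require_pd = FALSE)

min_eigval <- function(M) min(eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values)

#' Connectivity matrix container
#'
#' An N x N symmetric connectivity estimate tagged with its subject, atlas
#' and estimation method. Correlation matrices must have unit diagonal and
#' entries in `[-1, 1]`; covariance matrices must be positive semi-definite;
#' tangent coordinates are unbounded symmetric matrices.
#'
#' @param M Numeric symmetric matrix (asymmetry tolerance 1e-10).
#' @param method One of `"correlation"`, `"covariance"`, `"tangent"`.
#' @param subject_id,atlas Identification metadata.
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(M, method, subject_id = "", atlas = "") {
  method <- match.arg(method, c("correlation", "covariance", "tangent"))
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("M must be square")
  if (max(abs(M - t(M))) > 1e-10)
    stopf("connectivity matrix is asymmetric beyond 1e-10 (max deviation %.3e)",
          max(abs(M - t(M))))
  M <- sym(unname(M))
  if (method == "correlation") {
    if (max(abs(diag(M) - 1)) > 1e-10)
      stopf("correlation matrix must have unit diagonal")
    if (max(abs(M)) > 1 + 1e-10)
      stopf("correlation entries must lie in [-1, 1]")
    M <- pmin(pmax(M, -1), 1)
    diag(M) <- 1
  }
  if (method == "covariance" && min_eigval(M) < -1e-8)
    stopf("covariance matrix is not positive semi-definite (min eigenvalue %.3e)",
          min_eigval(M))
  structure(list(subject_id = as.character(subject_id),
                 atlas = as.character(atlas),
                 method = method, M = M, N = nrow(M)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %dx%d method=%s subject=%s atlas=%s\n",
              x$N, x$N, x$method, x$subject_id, x$atlas))
  invisible(x)
}

#' Pearson correlation connectivity
#'
#' Entry (i, j) is the Pearson correlation of ROI signals i and j across
#' time; the diagonal is exactly 1. Invariant to shifting or positively
#' rescaling any column.
#'
#' @param ts A [roi_timeseries()]; every column must have nonzero variance.
#' @return A `connectivity_matrix` with method `"correlation"`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- apply(ts$data, 2, stats::var)
  if (any(v == 0))
    stopf("zero-variance ROI column(s): %s",
          paste(which(v == 0), collapse = ", "))
  M <- stats::cor(ts$data)
  diag(M) <- 1
  connectivity_matrix(sym(M), "correlation", ts$subject_id, ts$atlas)
}

#' Covariance connectivity
#'
#' `estimator = "empirical"` is the unbiased sample covariance (denominator
#' T - 1). `estimator = "shrunk"` applies Ledoit-Wolf shrinkage toward a
#' scaled identity, `(1 - s) S + s mu I` with the oracle-approximating
#' intensity `s`, guaranteeing strict positive definiteness even when
#' T < N; the shrunk base covariance `S` uses denominator T, matching the
#' estimator's derivation.
#'
#' @param ts A [roi_timeseries()] with at least 2 timepoints.
#' @param estimator `"shrunk"` (default) or `"empirical"`.
#' @return A `connectivity_matrix` with method `"covariance"`.
#' @export
covariance_matrix <- function(ts, estimator = c("shrunk", "empirical")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  estimator <- match.arg(estimator)
  if (ts$T < 2L) stopf("covariance needs at least 2 timepoints")
  M <- if (estimator == "empirical") stats::cov(ts$data) else ledoit_wolf(ts$data)
  connectivity_matrix(sym(M), "covariance", ts$subject_id, ts$atlas)
}

# Ledoit-Wolf shrinkage toward mu*I (Ledoit & Wolf 2004 "well-conditioned
# estimator"): s = min(b2, d2)/d2 with d2 = ||S - mu I||^2_F/p and
# b2 = mean_t ||x_t x_t' - S||^2_F / (T p).
ledoit_wolf <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Tn <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / Tn
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 == 0) return(S + diag(1e-10, p))
  sq <- rowSums(X^2)
  b2bar <- (sum(sq^2) / Tn^2 - sum(S^2) / Tn) / p
  b2 <- min(b2bar, d2)
  s <- b2 / d2
  out <- (1 - s) * S + diag(s * mu, p)
  if (min_eigval(out) <= 0) out <- out + diag(1e-10, p)
  out
}

#' Fit a group tangent-space model
#'
#' Computes the affine-invariant (Karcher) geometric mean `G` of a set of
#' SPD covariance matrices by the fixed-point iteration
#' `G <- G^{1/2} exp(mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}`,
#' stopping when the Frobenius norm of the mean-log term drops below `tol`,
#' and the whitening factor `W = G^{-1/2}` (so `W G W' = I`).
#'
#' @param covs List of SPD `connectivity_matrix` objects (or plain SPD
#'   matrices) of a common dimension.
#' @param tol Convergence tolerance on the Frobenius norm of the mean log.
#' @param max_iter Maximum fixed-point iterations.
#' @return Object of class `group_tangent_model` with fields `G`, `W`,
#'   `n_fit`, `tol`, `residual` (final mean-log norm), `iterations`.
#' @export
fit_tangent <- function(covs, tol = 1e-8, max_iter = 200L) {
  if (!length(covs)) stopf("need at least one covariance matrix")
  mats <- lapply(seq_along(covs), function(i) {
    M <- covs[[i]]
    if (inherits(M, "connectivity_matrix")) M <- M$M
    if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("input %d is not square", i)
    if (min_eigval(M) <= 0)
      stopf("input %d is not symmetric positive definite", i)
    sym(M)
  })
  N <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == N)) stopf("matrices differ in dimension")

  G <- sym(Reduce(`+`, mats) / length(mats))   # arithmetic-mean start
  residual <- Inf
  for (iter in seq_len(max_iter)) {
    Gs <- spd_sqrt(G, "geometric-mean iterate")
    Gis <- spd_invsqrt(G, "geometric-mean iterate")
    meanlog <- Reduce(`+`, lapply(mats, function(C)
      spd_logm(Gis %*% C %*% Gis, "whitened covariance"))) / length(mats)
    residual <- sqrt(sum(meanlog^2))
    if (residual < tol) break
    G <- sym(Gs %*% sym_expm(meanlog) %*% Gs)
  }
  if (residual >= tol)
    stopf("geometric mean did not converge in %d iterations (residual %.3e)",
          max_iter, residual)
  structure(list(G = G, W = spd_invsqrt(G, "geometric mean"),
                 n_fit = length(mats), tol = tol,
                 residual = residual, iterations = iter),
            class = "group_tangent_model")
}

#' @export
print.group_tangent_model <- function(x, ...) {
  cat(sprintf("<group_tangent_model> %dx%d, fitted on %d matrices, residual %.2e (%d iterations)\n",
              nrow(x$G), ncol(x$G), x$n_fit, x$residual, x$iterations))
  invisible(x)
}

#' Tangent-space embedding of a covariance matrix
#'
#' Projects an SPD matrix `C` to the tangent space at the group geometric
#' mean: `log(W C W')` with `W = G^{-1/2}`. The map is inverted by
#' `C = G^{1/2} exp(.) G^{1/2}`.
#'
#' @param model A [fit_tangent()] model.
#' @param C SPD `connectivity_matrix` (or plain matrix) matching the model
#'   dimension.
#' @return A `connectivity_matrix` with method `"tangent"`.
#' @export
tangent_embed <- function(model, C) {
  stopifnot(inherits(model, "group_tangent_model"))
  subject_id <- ""; atlas <- ""
  if (inherits(C, "connectivity_matrix")) {
    subject_id <- C$subject_id; atlas <- C$atlas; C <- C$M
  }
  if (nrow(C) != nrow(model$G)) stopf("dimension mismatch with tangent model")
  if (min_eigval(C) <= 0) stopf("matrix to embed is not positive definite")
  out <- spd_logm(model$W %*% sym(C) %*% model$W, "whitened covariance")
  connectivity_matrix(out, "tangent", subject_id, atlas)
}

# Inverse of tangent_embed; used by round-trip tests.
tangent_reconstruct <- function(model, Tm) {
  if (inherits(Tm, "connectivity_matrix")) Tm <- Tm$M
  Gs <- spd_sqrt(model$G, "geometric mean")
  sym(Gs %*% sym_expm(sym(Tm)) %*% Gs)
}
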