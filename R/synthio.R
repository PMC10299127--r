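#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of Gaussian ROI time series with group-level
#' connectivity differences: in the case group, correlations at `over_edges`
#' are raised by `effect` (over-connectivity) and at `under_edges` lowered
#' by `effect` (under-connectivity), relative to a compound-symmetric
#' baseline with off-diagonal correlation `base_corr`.
#'
#' Defaults follow the package's smoke-test scale: 100 subjects per group,
#' 30 ROIs, 150 timepoints, effect 0.3, and 10 planted over- plus 10 planted
#' under-connected edges on disjoint ROI pairs.
#'
#' @param n_per_group Subjects per class.
#' @param n_rois Number of ROIs.
#' @param n_timepoints Timepoints per subject.
#' @param over_edges,under_edges Two-column integer matrices (or lists of
#'   pairs) of 1-based ROI index pairs; must be disjoint, with no self-pairs.
#' @param effect Correlation shift in `[0, 1)`.
#' @param base_corr Baseline off-diagonal correlation in `(-1, 1)`.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return Object of class `cohort_spec` carrying the fields above plus the
#'   two group target correlation matrices `R_control` and `R_case`.
#' @examples
#' sp <- cohort_spec(n_per_group = 5, n_rois = 10, n_timepoints = 50)
#' sp$R_case[1, 2] - sp$R_control[1, 2]
#' @export
cohort_spec <- function(n_per_group = 100L, n_rois = 30L, n_timepoints = 150L,
                        over_edges = default_edges(n_rois)$over,
                        under_edges = default_edges(n_rois)$under,
                        effect = 0.3, base_corr = 0.1, seed = 1L) {
  if (!is_count(n_per_group) || !is_count(n_rois) || !is_count(n_timepoints))
    stopf("n_per_group, n_rois and n_timepoints must be positive integers")
  if (!(effect >= 0 && effect < 1)) stopf("effect must lie in [0, 1)")
  if (!(base_corr > -1 && base_corr < 1)) stopf("base_corr must lie in (-1, 1)")
  over <- as_edge_matrix(over_edges, n_rois, "over_edges")
  under <- as_edge_matrix(under_edges, n_rois, "under_edges")
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (nrow(over) && nrow(under) && length(intersect(key(over), key(under))))
    stopf("over_edges and under_edges must be disjoint")

  R0 <- matrix(base_corr, n_rois, n_rois); diag(R0) <- 1
  R1 <- R0
  if (nrow(over))  R1[rbind(over,  over[, 2:1, drop = FALSE])]  <- base_corr + effect
  if (nrow(under)) R1[rbind(under, under[, 2:1, drop = FALSE])] <- base_corr - effect
  if (any(abs(R1[upper.tri(R1)]) >= 1))
    stopf("case group: planted effect drives a correlation outside (-1, 1)")

  spec <- structure(list(n_per_group = as.integer(n_per_group),
                         n_rois = as.integer(n_rois),
                         n_timepoints = as.integer(n_timepoints),
                         over_edges = over, under_edges = under,
                         effect = effect, base_corr = base_corr,
                         seed = as.integer(seed),
                         R_control = ensure_spd_target(R0, "control"),
                         R_case = ensure_spd_target(R1, "case")),
                    class = "cohort_spec")
  spec
}

default_edges <- function(n_rois) {
  # fixed planted structure: first 2k ROIs paired off, alternating over/under
  k <- min(10L, floor(n_rois / 4))
  idx <- seq_len(4L * k)
  pairs <- matrix(idx, ncol = 2, byrow = TRUE)       # (1,2),(3,4),...
  list(over = pairs[seq_len(k), , drop = FALSE],
       under = pairs[k + seq_len(k), , drop = FALSE])
}

as_edge_matrix <- function(e, n_rois, what) {
  if (is.null(e) || (is.matrix(e) && nrow(e) == 0))
    return(matrix(integer(), 0, 2))
  if (is.list(e) && !is.data.frame(e)) e <- do.call(rbind, lapply(e, as.integer))
  e <- matrix(as.integer(as.matrix(e)), ncol = 2)
  if (any(e < 1 | e > n_rois)) stopf("%s: ROI index out of 1..%d", what, n_rois)
  if (any(e[, 1] == e[, 2])) stopf("%s: self-pairs are not allowed", what)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(paste(e[, 1], e[, 2]))) stopf("%s: duplicate pairs", what)
  e
}

# Reject targets whose minimum eigenvalue is below -1e-8; clip tiny negative
# eigenvalues (numerical zeros) to a floor so the Cholesky factor exists.
ensure_spd_target <- function(R, group) {
  ev <- eigen(R, symmetric = TRUE)
  mineig <- min(ev$values)
  if (mineig < -1e-8)
    stopf("%s group: target correlation matrix is not positive definite (min eigenvalue %.3e)",
          group, mineig)
  if (mineig <= 1e-12) {
    vals <- pmax(ev$values, 1e-10)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- (R + t(R)) / 2
  }
  R
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d+%d subjects, %d ROIs, T=%d, effect=%.2f,",
                     " base_corr=%.2f, %d over / %d under edges, seed=%d\n"),
              x$n_per_group, x$n_per_group, x$n_rois, x$n_timepoints, x$effect,
              x$base_corr, nrow(x$over_edges), nrow(x$under_edges), x$seed))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Draws each subject's time series as i.i.d. rows from a zero-mean
#' multivariate Gaussian whose population correlation matrix is the group
#' target in `spec`. Controls come first, then cases. Deterministic given
#' the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (list of [roi_timeseries()]) and `labels`
#'   (factor, levels case/control), aligned by position.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_per_group = 3, n_rois = 8,
#'                                   n_timepoints = 40))
#' table(co$labels)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  Lc <- chol(spec$R_control)
  La <- chol(spec$R_case)
  atlas <- sprintf("synthetic%d", spec$n_rois)
  with_seed(spec$seed, {
    draw <- function(L, id) {
      Z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
                  spec$n_timepoints, spec$n_rois)
      roi_timeseries(Z %*% L, id, atlas)
    }
    controls <- lapply(seq_len(spec$n_per_group),
                       function(i) draw(Lc, sprintf("ctrl%03d", i)))
    cases <- lapply(seq_len(spec$n_per_group),
                    function(i) draw(La, sprintf("case%03d", i)))
    list(subjects = c(controls, cases),
         labels = factor(rep(c("control", "case"), each = spec$n_per_group),
                         levels = c("case", "control")))
  })
}

#' Write a simulated cohort to disk
#'
#' One whitespace-delimited time-series file per subject (`<id>.1D`) plus a
#' `phenotype.csv` with columns `subject_id,label` — exactly the dialect
#' [read_timeseries()] and [read_phenotype()] consume.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$subjects) {
    utils::write.table(format(ts$data, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, paste0(ts$subject_id, ".1D")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  ph <- data.frame(subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
                   label = as.character(cohort$labels))
  utils::write.csv(ph, file.path(dir, "phenotype.csv"), row.names = FALSE)
  invisible(dir)
}

#' Fixed 4-vertex weighted-graph fixture
#'
#' The complete graph on vertices 0..3 with weights (0,1)=1, (0,2)=4,
#' (0,3)=3, (1,2)=2, (1,3)=5, (2,3)=6, used throughout the test suite as a
#' hand-checkable spanning-tree case (MST weight 6, MaxST weight 15).
#'
#' @return A [weighted_graph()] with 4 vertices and 6 edges. Vertices are
#'   1-based (matching ROI indices), so the pairs above read (1,2)=1,
#'   (1,3)=4, (1,4)=3, (2,3)=2, (2,4)=5, (3,4)=6.
#' @export
toy_graph_fixture <- function() {
  e <- rbind(c(1, 2, 1), c(1, 3, 4), c(1, 4, 3),
             c(2, 3, 2), c(2, 4, 5), c(3, 4, 6))
  weighted_graph(4L, e)
}
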