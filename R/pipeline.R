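#' Pipeline configuration
#'
#' Describes the full classification grid: atlases x connectivity methods x
#' stacking strategies x backbones, plus cross-validation and seeding
#' controls. With three atlases, three methods, two strategies and seven
#' ImageNet backbones this is the 126-tuple grid; the stacking stage alone
#' yields 18 stack kinds per subject.
#'
#' @param atlases Character vector of atlas labels. For synthetic runs,
#'   supply `cohorts`, a named list mapping each atlas label to a
#'   [cohort_spec()].
#' @param methods Subset of `c("correlation", "covariance", "tangent")`.
#' @param strategies Subset of `c("plain", "enhanced")`.
#' @param backbones Subset of [list_backbones()].
#' @param folds Cross-validation folds (>= 2).
#' @param seed Master seed.
#' @param cohorts Named list of [cohort_spec()]s keyed by atlas label
#'   (synthetic mode), or `NULL` when `data_dirs` supplies on-disk cohorts.
#' @param data_dirs Named character vector of directories (one per atlas)
#'   containing `*.1D` time series plus `phenotype.csv`.
#' @param fine_tune Run the fine-tuning phase during training.
#' @param cache_dir Stage-cache directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(atlases, methods = c("correlation", "covariance",
                                                 "tangent"),
                            strategies = c("plain", "enhanced"),
                            backbones = setdiff(list_backbones(), "TinyConv"),
                            folds = 10L, seed = 1L, cohorts = NULL,
                            data_dirs = NULL, fine_tune = FALSE,
                            cache_dir = file.path(tempdir(), "connstack-cache")) {
  methods <- match.arg(methods, several.ok = TRUE)
  strategies <- match.arg(strategies, several.ok = TRUE)
  bad <- setdiff(backbones, list_backbones())
  if (length(bad)) stopf("unregistered backbone(s): %s", paste(bad, collapse = ", "))
  if (!is_count(folds) || folds < 2) stopf("folds must be an integer >= 2")
  if (!is.null(cohorts)) {
    if (is.null(names(cohorts)) || !all(atlases %in% names(cohorts)))
      stopf("cohorts must be a named list covering every atlas")
    lapply(cohorts, function(cs) stopifnot(inherits(cs, "cohort_spec")))
  }
  structure(list(atlases = atlases, methods = methods,
                 strategies = strategies, backbones = backbones,
                 folds = as.integer(folds), seed = as.integer(seed),
                 cohorts = cohorts, data_dirs = data_dirs,
                 fine_tune = isTRUE(fine_tune), cache_dir = cache_dir),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d atlases x %d methods x %d strategies x %d backbones = %d tuples, %d folds, seed %d\n",
              length(x$atlases), length(x$methods), length(x$strategies),
              length(x$backbones), nrow(enumerate_grid(x)), x$folds, x$seed))
  invisible(x)
}

#' Enumerate the classification grid
#'
#' Cartesian product atlases x methods x strategies x backbones in
#' deterministic order (backbone varying fastest).
#'
#' @param cfg A [pipeline_config()].
#' @return data.frame with columns atlas, method, strategy, backbone.
#' @export
enumerate_grid <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  g <- expand.grid(backbone = cfg$backbones, strategy = cfg$strategies,
                   method = cfg$methods, atlas = cfg$atlases,
                   stringsAsFactors = FALSE)
  g[, c("atlas", "method", "strategy", "backbone")]
}

#' Per-subject connectivity stacks for a cohort
#'
#' Computes one [stack3d()] per subject for a given connectivity method and
#' stacking strategy. For the tangent method, the group geometric mean is
#' fitted on the subjects indexed by `fit_idx` only (pass the training-fold
#' indices during cross-validation to avoid leakage) and then applied to
#' everyone.
#'
#' @param subjects List of [roi_timeseries()].
#' @param method `"correlation"`, `"covariance"` or `"tangent"`.
#' @param strategy `"plain"` or `"enhanced"`.
#' @param fit_idx Indices of the subjects used to fit group-level models.
#' @param absolute Rank spanning-tree edges by absolute weight.
#' @param estimator Covariance estimator feeding both the covariance and
#'   tangent methods.
#' @return List of [stack3d()] aligned with `subjects`.
#' @export
cohort_stacks <- function(subjects,
                          method = c("correlation", "covariance", "tangent"),
                          strategy = c("enhanced", "plain"),
                          fit_idx = seq_along(subjects), absolute = FALSE,
                          estimator = "shrunk") {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  cms <- switch(method,
    correlation = lapply(subjects, correlation_matrix),
    covariance = lapply(subjects, covariance_matrix, estimator = estimator),
    tangent = {
      covs <- lapply(subjects, covariance_matrix, estimator = estimator)
      model <- fit_tangent(covs[fit_idx])
      lapply(covs, function(cv) tangent_embed(model, cv))
    })
  lapply(cms, build_stack, strategy = strategy, absolute = absolute)
}

cache_get <- function(cache_dir, key, compute) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

load_cohort <- function(cfg, atlas) {
  if (!is.null(cfg$cohorts)) {
    spec <- cfg$cohorts[[atlas]]
    cache_get(cfg$cache_dir, paste0("cohort-", fingerprint(unclass(spec))),
              function() simulate_cohort(spec))
  } else if (!is.null(cfg$data_dirs)) {
    dir <- cfg$data_dirs[[atlas]]
    ph <- read_phenotype(file.path(dir, "phenotype.csv"))
    subjects <- lapply(ph$subject_id, function(id)
      read_timeseries(file.path(dir, paste0(id, ".1D")), atlas, id))
    list(subjects = subjects, labels = ph$label)
  } else stopf("pipeline_config has neither cohorts nor data_dirs")
}

#' Run the full pipeline over the grid
#'
#' Executes simulate/load -> connectivity -> stacking -> cross-validated
#' training for every grid tuple, with stage-level caching keyed by content
#' fingerprints. `through = "stack"` stops after stacking (returning the
#' per-subject stacks per tuple); `through = "train"` additionally runs
#' [cross_validate()] (TinyConv backbones only; tuples naming backbones
#' without available weights record the error and continue).
#'
#' @param cfg A [pipeline_config()].
#' @param through `"stack"` or `"train"`.
#' @return List with `grid` (the tuple table) and `results` (one entry per
#'   tuple: a list of stacks, a [cross_validate()] report, or an error
#'   message string).
#' @export
run_pipeline <- function(cfg, through = c("train", "stack")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  through <- match.arg(through)
  grid <- enumerate_grid(cfg)
  results <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    tuple <- grid[r, ]
    results[[r]] <- tryCatch({
      cohort <- load_cohort(cfg, tuple$atlas)
      if (through == "stack" || tuple$method != "tangent") {
        key <- paste0("stacks-", fingerprint(list(
          atlas = tuple$atlas, method = tuple$method,
          strategy = tuple$strategy, seed = cfg$seed)))
        stacks <- cache_get(cfg$cache_dir, key, function()
          cohort_stacks(cohort$subjects, tuple$method, tuple$strategy))
        if (through == "stack") stacks
        else cross_validate(stacks, cohort$labels,
                            backbone = backbone_spec(tuple$backbone),
                            k = cfg$folds, seed = cfg$seed,
                            schedule = training_schedule(
                              fine_tune = cfg$fine_tune, seed = cfg$seed))
      } else {
        # tangent: group mean must be re-fitted inside each training fold
        cross_validate(cohort$subjects, cohort$labels,
                       backbone = backbone_spec(tuple$backbone),
                       k = cfg$folds, seed = cfg$seed,
                       schedule = training_schedule(
                         fine_tune = cfg$fine_tune, seed = cfg$seed),
                       stack_fn = function(train_idx, x)
                         cohort_stacks(x, "tangent", tuple$strategy,
                                       fit_idx = train_idx))
      }
    }, error = function(e) conditionMessage(e))
  }
  list(grid = grid, results = results)
}
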