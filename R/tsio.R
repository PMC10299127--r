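#' ROI time series
#'
#' Container for one subject's parcellated signal table: `T` timepoints
#' (rows) by `N` regions of interest (columns), the layout used by the
#' ABIDE-preprocessed `.1D` exports.
#'
#' @param data Numeric matrix, timepoints x ROIs. All values must be finite.
#' @param subject_id Subject identifier string.
#' @param atlas Atlas label (e.g. `"AAL"`, `"Dosenbach"`, `"CC200"`). If the
#'   atlas is registered (see [atlas_registry()]), the column count must
#'   match its ROI count.
#' @return An object of class `roi_timeseries` with fields `subject_id`,
#'   `atlas`, `data`, `T`, `N`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 10, 4), "sub01", "toy4")
#' ts$N
#' @export
roi_timeseries <- function(data, subject_id, atlas) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("time-series data must be a numeric matrix")
  if (nrow(data) < 2L) stopf("need at least 2 timepoints, got %d", nrow(data))
  if (ncol(data) < 2L) stopf("need at least 2 ROIs, got %d", ncol(data))
  if (!all(is.finite(data)))
    stopf("time series for subject '%s' contains missing or non-finite values",
          subject_id)
  expected <- atlas_n_rois(atlas)
  if (!is.na(expected) && ncol(data) != expected)
    stopf("atlas '%s' has %d ROIs but table has %d columns",
          atlas, expected, ncol(data))
  structure(list(subject_id = as.character(subject_id),
                 atlas = as.character(atlas),
                 data = unname(data),
                 T = nrow(data), N = ncol(data)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject=%s atlas=%s T=%d N=%d\n",
              x$subject_id, x$atlas, x$T, x$N))
  invisible(x)
}

#' Read a parcellated time-series table
#'
#' Parses a whitespace- or tab-delimited numeric table with one row per
#' timepoint and one column per ROI. A single leading header row is
#' auto-detected (any non-numeric token) and skipped. Trailing whitespace
#' and blank trailing lines are ignored. Format violations report the
#' offending 1-based line number.
#'
#' @param path Path to the text file.
#' @param atlas Atlas label; checked against [atlas_registry()] if registered.
#' @param subject_id Subject id; defaults to the file name without extension.
#' @return A [roi_timeseries()].
#' @export
read_timeseries <- function(path, atlas,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # drop blank lines at the end only (an interior blank line is a format error)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stopf("format error in %s: file is empty", path)

  tokens <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  first <- suppressWarnings(as.numeric(tokens[[1]]))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(lines))
    stopf("format error in %s: header row but no data", path)

  ncols <- length(tokens[[start]])
  rows <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    tk <- tokens[[i]]
    if (!length(tk))
      stopf("format error in %s at line %d: blank line inside table", path, i)
    if (length(tk) != ncols)
      stopf("format error in %s at line %d: expected %d columns, found %d",
            path, i, ncols, length(tk))
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v))
      stopf("format error in %s at line %d: non-numeric or missing value",
            path, i)
    rows[[i - start + 1L]] <- v
  }
  m <- do.call(rbind, rows)
  expected <- atlas_n_rois(atlas)
  if (!is.na(expected) && ncol(m) != expected)
    stopf("format error in %s: atlas '%s' expects %d columns, file has %d",
          path, atlas, expected, ncol(m))
  if (!all(is.finite(m)))
    stopf("format error in %s: non-finite value in table", path)
  roi_timeseries(m, subject_id, atlas)
}

#' Read a phenotype table
#'
#' Reads a CSV with columns `subject_id` and `label`, normalizing labels to
#' `"case"`/`"control"`. Accepted tokens: the ABIDE numeric convention
#' (`1` = case, `2` = control), `"ASD"`/`"case"` and
#' `"control"`/`"TC"` (case-insensitive).
#'
#' @param path CSV path.
#' @return data.frame with character `subject_id` and factor `label` in
#'   levels `c("case", "control")`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(df)))
    stopf("phenotype file must have columns subject_id,label; found: %s",
          paste(names(df), collapse = ","))
  if (anyDuplicated(df$subject_id))
    stopf("duplicate subject_id in phenotype table: %s",
          paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df$label <- normalize_labels(df$label)
  df[, need]
}

normalize_labels <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- ifelse(lx %in% c("1", "asd", "case"), "case",
         ifelse(lx %in% c("2", "control", "tc"), "control", NA))
  if (anyNA(out))
    stopf("unknown label token(s): %s (accepted: 1, 2, ASD, case, control, TC)",
          paste(unique(x[is.na(out)]), collapse = ", "))
  factor(out, levels = c("case", "control"))
}

#' Persist / reload a 3-channel connectivity stack
#'
#' Stacks are written with R's native serialization (`.rds`), a lossless
#' binary container; `atlas`, `method`, `strategy` and `subject_id` metadata
#' travel with the array. The round trip is elementwise exact.
#'
#' @param stack A [stack3d()] object.
#' @param path Output path (conventionally `.rds`).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   [stack3d()].
#' @export
write_stack <- function(stack, path) {
  validate_stack3d(stack)
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- readRDS(path)
  if (!inherits(obj, "stack3d"))
    stopf("%s does not contain a connectivity stack", path)
  validate_stack3d(obj)
  obj
}
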