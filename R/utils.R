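#' @keywords internal
"_PACKAGE"

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream offset, kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

# FNV-1a hash of an R object's serialization; used for config fingerprints
# and stage-cache keys (no external digest dependency).
fingerprint <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' Atlas registry
#'
#' ROI counts for the parcellations the pipeline recognizes. Unregistered
#' atlas names are allowed (no ROI-count check is then possible).
#'
#' @return Named integer vector of ROI counts per registered atlas.
#' @examples
#' atlas_registry()[["AAL"]]
#' @export
atlas_registry <- function() {
  c(AAL = 116L, Dosenbach = 161L, CC200 = 200L)
}

atlas_n_rois <- function(atlas) {
  reg <- atlas_registry()
  if (atlas %in% names(reg)) reg[[atlas]] else NA_integer_
}
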