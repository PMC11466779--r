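#' State-specific open-chromatin regions
#'
#' Reproducible ("common") peaks per disease state are derived by
#' replicate-anchored overlap: the peaks of the first (reference)
#' replicate that overlap the second replicate. State-specific
#' regions are then obtained by whole-peak set difference between the
#' two common sets, and the regions active in all samples are the
#' common-diagnosis peaks that overlap common-relapse peaks
#' (reported in diagnosis-side coordinates).
#'
#' @name peak_states
NULL

#' Reproducible peaks across two replicates
#'
#' Keeps the peaks of `a` (the designated reference replicate) that
#' have at least one overlapping peak in `b`; peak boundaries remain
#' those called in `a`.
#'
#' @param a,b replicate peak data frames.
#' @param min_bp minimum overlap in bases.
#' @return subset of `a`.
#' @export
common_peaks <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  keep <- unique(overlap_pairs(a, b, min_bp = min_bp)$a)
  out <- a[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive state-specific peak sets
#'
#' @param d1,d2 diagnosis replicate peak data frames (d1 is the
#'   reference replicate).
#' @param r1,r2 relapse replicate peak data frames (r1 reference).
#' @param min_bp minimum overlap in bases.
#' @return list with `common_diagnosis`, `common_relapse`,
#'   `diagnosis_specific`, `relapse_specific`, `shared` (interval
#'   data frames) and a `counts` vector.
#' @export
derive_states <- function(d1, d2, r1, r2, min_bp = 1L) {
  cd <- common_peaks(d1, d2, min_bp)
  cr <- common_peaks(r1, r2, min_bp)
  shared <- common_peaks(cd, cr, min_bp)
  ds <- subtract_peaks(cd, cr, min_bp)
  rs <- subtract_peaks(cr, cd, min_bp)
  out <- list(common_diagnosis = cd, common_relapse = cr,
              diagnosis_specific = ds, relapse_specific = rs,
              shared = shared)
  out$counts <- vapply(out, nrow, integer(1))
  out$shared_side <- "diagnosis"
  out
}
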