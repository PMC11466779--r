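#' Differential chromatin-loop analysis
#'
#' Builds the loop x sample strength matrix from per-sample BEDPE
#' files and calls state-specific (diagnosis vs relapse)
#' interactions: TMM normalization, log2 CPM, selection of the most
#' variable loops by standard deviation, a moderated two-group test,
#' and BH adjustment; significant loops are partitioned by the sign
#' of the log2 fold change (relapse minus diagnosis).
#'
#' @name diff_loops
NULL

#' Build the loop strength matrix
#'
#' The loop universe is the union of loop ids across files; a loop
#' absent from a sample's file has strength 0 in that column. Columns
#' are ordered diagnosis samples first, then relapse.
#'
#' @param files character vector of BEDPE paths, or a list of loop
#'   data frames as returned by [read_bedpe_loops()].
#' @param groups per-file labels ("diagnosis"/"relapse").
#' @param sample_ids optional sample names (default file base names).
#' @return list with `loops` (anchor table keyed by loop_id),
#'   `matrix` (loops x samples) and `group`.
#' @export
build_loop_matrix <- function(files, groups, sample_ids = NULL) {
  stopifnot(length(files) == length(groups))
  groups <- as.character(groups)
  if (!all(groups %in% c("diagnosis", "relapse")))
    stop("groups must be 'diagnosis' or 'relapse'")
  if (!all(c("diagnosis", "relapse") %in% groups))
    stop("need at least one file per group")
  tabs <- if (is.character(files)) lapply(files, read_bedpe_loops) else files
  if (is.null(sample_ids))
    sample_ids <- if (is.character(files))
      make.unique(sub("\\.[^.]*$", "", basename(files)))
    else paste0("s", seq_along(tabs))
  ord <- order(match(groups, c("diagnosis", "relapse")))
  tabs <- tabs[ord]; groups <- groups[ord]; sample_ids <- sample_ids[ord]
  anchors <- unique(do.call(rbind, lapply(tabs, function(t)
    t[, c("loop_id", "chrom1", "start1", "end1",
          "chrom2", "start2", "end2")])))
  if (anyDuplicated(anchors$loop_id))
    stop("the same loop_id maps to different anchor pairs across files")
  rownames(anchors) <- NULL
  mat <- matrix(0, nrow = nrow(anchors), ncol = length(tabs),
                dimnames = list(anchors$loop_id, sample_ids))
  for (j in seq_along(tabs))
    mat[tabs[[j]]$loop_id, j] <- tabs[[j]]$strength
  list(loops = anchors, matrix = mat,
       group = stats::setNames(groups, sample_ids))
}

#' Call differential loops
#'
#' @param lm loop matrix from [build_loop_matrix()].
#' @param n_top number of most-variable loops tested (default
#'   100000, the full-scale pipeline setting; a value >= the number
#'   of loops tests all of them).
#' @param alpha BH-adjusted significance threshold (default 0.1).
#' @param weight_trend apply the mean-variance trend weighting
#'   (off by default for loop strengths).
#' @return list with `results` (moderated test table plus a
#'   `state_call` column), `relapse_specific` and
#'   `diagnosis_specific` loop id vectors, and `norm` factors.
#' @export
call_differential_loops <- function(lm, n_top = 100000, alpha = 0.1,
                                    weight_trend = FALSE) {
  m <- check_count_matrix(lm$matrix, lm$group)
  norm <- tmm_factors(m)
  logm <- log_cpm(m, norm)
  keep <- top_variable(logm, n_top)
  res <- moderated_test(logm[keep, , drop = FALSE], lm$group,
                        ref = "diagnosis", weight_trend = weight_trend)
  sig <- res$p_adj < alpha
  res$state_call <- ifelse(!sig, "ns",
                           ifelse(res$log_fc > 0, "relapse-specific",
                                  "diagnosis-specific"))
  list(results = res,
       relapse_specific = res$feature_id[sig & res$log_fc > 0],
       diagnosis_specific = res$feature_id[sig & res$log_fc < 0],
       alpha = alpha, n_top = length(keep), norm = norm)
}

#' Anchors of state-specific loops
#'
#' Both anchors of every loop called specific to `state`,
#' deduplicated by exact coordinates.
#'
#' @param dl output of [call_differential_loops()].
#' @param loops anchor table from [build_loop_matrix()].
#' @param state "diagnosis" or "relapse".
#' @return interval data frame (chrom, start, end, name = loop_id of
#'   one loop using the anchor).
#' @export
state_anchors <- function(dl, loops, state = c("diagnosis", "relapse")) {
  state <- match.arg(state)
  ids <- if (state == "diagnosis") dl$diagnosis_specific else dl$relapse_specific
  sub <- loops[loops$loop_id %in% ids, , drop = FALSE]
  anc <- rbind(
    data.frame(chrom = sub$chrom1, start = sub$start1, end = sub$end1,
               name = sub$loop_id, stringsAsFactors = FALSE),
    data.frame(chrom = sub$chrom2, start = sub$start2, end = sub$end2,
               name = sub$loop_id, stringsAsFactors = FALSE))
  anc <- anc[!duplicated(anc[, c("chrom", "start", "end")]), , drop = FALSE]
  sort_intervals(anc)
}
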