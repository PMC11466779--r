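#' Differential gene expression
#'
#' Two-group moderated test on a gene count table with the selection
#' thresholds adjusted p < 0.1 and |log2 fold change| > 1, and the
#' mean-variance trend weighting on by default (RNA-seq counts show a
#' strong mean-variance relationship; loop strengths do not).
#'
#' @name diff_expr
NULL

#' Read a gene count table
#'
#' TSV with the first column holding gene ids and a header of sample
#' ids.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a gene count table
#' @param m matrix with feature row names and sample column names.
#' @param path output path.
#' @param id_col name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-group differential expression
#'
#' Pipeline: minimal expression filter (counts-per-million > 1 in at
#' least `min_samples` samples, defining the gene universe used for
#' random-set sampling downstream), TMM normalization, log2 CPM,
#' moderated two-group test and BH adjustment. Up/down calls require
#' strictly `p_adj < alpha` and `|log_fc|` strictly beyond `lfc`.
#'
#' @param counts genes x samples matrix (or a TSV path).
#' @param group per-sample labels ("diagnosis"/"relapse").
#' @param alpha adjusted-p threshold (default 0.1).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param weight_trend mean-variance trend weighting (default TRUE).
#' @param cpm_filter CPM cutoff of the expression filter.
#' @param min_samples samples that must pass `cpm_filter`.
#' @return list with `results` (sorted by p then gene id),
#'   `upregulated`, `downregulated`, and `universe` gene ids.
#' @export
differential_expression <- function(counts, group, alpha = 0.1, lfc = 1,
                                    weight_trend = TRUE, cpm_filter = 1,
                                    min_samples = 2) {
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  m <- check_count_matrix(counts, group)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  keep <- rowSums(cpm > cpm_filter) >= min_samples
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 genes pass the expression filter")
  norm <- tmm_factors(m)
  logm <- log_cpm(m, norm)
  res <- moderated_test(logm, group, ref = "diagnosis",
                        weight_trend = weight_trend)
  res <- res[order(res$p, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  sig <- res$p_adj < alpha
  up <- res$feature_id[sig & res$log_fc > lfc]
  down <- res$feature_id[sig & res$log_fc < -lfc]
  res$state_call <- "ns"
  res$state_call[res$feature_id %in% up] <- "up"
  res$state_call[res$feature_id %in% down] <- "down"
  list(results = res, upregulated = up, downregulated = down,
       universe = rownames(m), alpha = alpha, lfc = lfc)
}
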