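#' Multi-omic integration
#'
#' Links state-specific loop anchors to state-specific open-chromatin
#' peaks and nearby genes, quantifies enrichment of differential
#' expression among linked genes against random size-matched gene
#' sets, and tests whether upregulated genes losing
#' diagnosis-specific contacts were disproportionately contacting
#' repressive-mark (H3K27me3) regions, using a width- and
#' chromosome-matched permutation null.
#'
#' @name integrate_omics
NULL

# evaluate expr with a local, restored-afterwards RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# derive an independent substream seed from a master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483629)
}

interval_id <- function(df) {
  if (!is.null(df$name) && !anyNA(df$name) && !anyDuplicated(df$name))
    df$name
  else sprintf("%s:%d-%d", df$chrom, df$start, df$end)
}

#' Anchors overlapped by state-specific peaks
#'
#' @param anchors interval data frame of state-specific loop anchors.
#' @param peaks state-specific peak data frame (same state).
#' @param min_bp minimum overlap in bases.
#' @return the accessible subset of `anchors` with a `peak_ids`
#'   list-column of overlapping peak identifiers.
#' @export
accessible_anchors <- function(anchors, peaks, min_bp = 1L) {
  if (nrow(anchors) == 0 || nrow(peaks) == 0) {
    out <- anchors[0, , drop = FALSE]
    out$peak_ids <- list()
    return(out)
  }
  ov <- overlap_pairs(anchors, peaks, min_bp = min_bp)
  keep <- sort(unique(ov$a))
  out <- anchors[keep, , drop = FALSE]
  pid <- interval_id(peaks)
  out$peak_ids <- lapply(keep, function(i) pid[ov$b[ov$a == i]])
  rownames(out) <- NULL
  out
}

#' Assign genes to regions by windowed overlap
#'
#' A gene is linked to a region when the region extended by `window`
#' bases on both sides overlaps the gene body by at least one base.
#' Links are deduplicated per (gene, region).
#'
#' @param regions interval data frame.
#' @param annotation gene annotation from [read_gene_annotation()].
#' @param window extension in bases (default 20000).
#' @return data.frame with columns `gene_id` and `region` (row index
#'   into `regions`).
#' @export
assign_genes <- function(regions, annotation, window = 20000) {
  if (nrow(regions) == 0 || nrow(annotation) == 0)
    return(data.frame(gene_id = character(), region = integer()))
  ext <- regions
  ext$start <- pmax(0, ext$start - window)
  ext$end <- ext$end + window
  ov <- overlap_pairs(ext, annotation[, c("chrom", "start", "end")])
  links <- data.frame(gene_id = annotation$gene_id[ov$b], region = ov$a,
                      stringsAsFactors = FALSE)
  links <- links[!duplicated(links), , drop = FALSE]
  rownames(links) <- NULL
  links
}

# gap between a gene body and an anchor on the same chromosome
anchor_gene_gap <- function(gs, ge, as, ae) {
  pmax(0, pmax(as - ge, gs - ae))
}

#' Build gene-anchor-peak integration records
#'
#' For every loop specific to `state`, each anchor is checked for
#' overlap with a state-specific peak ("accessible"); genes within
#' `window` of an accessible anchor are linked through it. The linked
#' (promoter-side) anchor of a record is the accessible anchor that
#' assigned the gene; the other end of the loop is the distal
#' anchor. When both anchors of a loop link the same gene, the
#' farther one (largest gap to the gene body) is taken as distal.
#' When H3K27me3 `marks` are supplied, each record is flagged for
#' distal-anchor overlap with a mark.
#'
#' @param dl output of [call_differential_loops()].
#' @param loops anchor table from [build_loop_matrix()].
#' @param state "diagnosis" or "relapse".
#' @param peaks state-specific peaks for the same state.
#' @param annotation gene annotation table.
#' @param de output of [differential_expression()] (adds `log_fc` and
#'   the DE call per gene); optional.
#' @param marks repressive-mark interval data frame; optional.
#' @param window gene-assignment window in bases.
#' @return data.frame, one row per (gene, loop) record: gene_id,
#'   state, loop_id, promoter/distal anchor coordinates, `peak_ids`
#'   list-column, `log_fc`, `de_call`, `repressive_overlap`.
#' @export
integration_records <- function(dl, loops, state, peaks, annotation,
                                de = NULL, marks = NULL, window = 20000) {
  state <- match.arg(state, c("diagnosis", "relapse"))
  anc <- state_anchors(dl, loops, state)
  acc <- accessible_anchors(anc, peaks)
  links <- assign_genes(acc[, c("chrom", "start", "end")], annotation,
                        window = window)
  empty <- data.frame(gene_id = character(), state = character(),
                      loop_id = character(),
                      promoter_chrom = character(),
                      promoter_start = numeric(), promoter_end = numeric(),
                      distal_chrom = character(),
                      distal_start = numeric(), distal_end = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(links) == 0) {
    empty$peak_ids <- list(); empty$log_fc <- numeric()
    empty$de_call <- character(); empty$repressive_overlap <- logical()
    return(empty)
  }
  ids <- if (state == "diagnosis") dl$diagnosis_specific else dl$relapse_specific
  sub <- loops[loops$loop_id %in% ids, , drop = FALSE]
  akey <- function(chrom, start, end) paste(chrom, start, end, sep = "|")
  acc_key <- akey(acc$chrom, acc$start, acc$end)
  rows <- list()
  for (k in seq_len(nrow(links))) {
    i <- links$region[k]
    key <- acc_key[i]
    # loops using this accessible anchor on either side
    useA <- akey(sub$chrom1, sub$start1, sub$end1) == key
    useB <- akey(sub$chrom2, sub$start2, sub$end2) == key
    for (li in which(useA | useB)) {
      if (useA[li]) {
        prom <- c(sub$chrom1[li], sub$start1[li], sub$end1[li])
        dist <- c(sub$chrom2[li], sub$start2[li], sub$end2[li])
      } else {
        prom <- c(sub$chrom2[li], sub$start2[li], sub$end2[li])
        dist <- c(sub$chrom1[li], sub$start1[li], sub$end1[li])
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = links$gene_id[k], state = paste0(state, "-specific"),
        loop_id = sub$loop_id[li],
        promoter_chrom = prom[1],
        promoter_start = as.numeric(prom[2]),
        promoter_end = as.numeric(prom[3]),
        distal_chrom = dist[1],
        distal_start = as.numeric(dist[2]),
        distal_end = as.numeric(dist[3]),
        acc_index = i,
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  # a loop whose both ends link the same gene appears twice; keep the
  # orientation whose distal anchor is farther from the gene body
  g <- annotation[match(rec$gene_id, annotation$gene_id), ]
  rec$dist_gap <- anchor_gene_gap(g$start, g$end,
                                  rec$distal_start, rec$distal_end)
  rec <- rec[order(rec$gene_id, rec$loop_id, -rec$dist_gap), , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("gene_id", "loop_id")]), , drop = FALSE]
  # drop degenerate records where both ends are the same interval
  rec <- rec[!(rec$promoter_chrom == rec$distal_chrom &
               rec$promoter_start == rec$distal_start &
               rec$promoter_end == rec$distal_end), , drop = FALSE]
  rec$peak_ids <- acc$peak_ids[rec$acc_index]
  rec$acc_index <- NULL
  rec$dist_gap <- NULL
  if (!is.null(de)) {
    idx <- match(rec$gene_id, de$results$feature_id)
    rec$log_fc <- de$results$log_fc[idx]
    rec$de_call <- de$results$state_call[idx]
    rec$de_call[is.na(rec$de_call)] <- "unexpressed"
  } else {
    rec$log_fc <- NA_real_; rec$de_call <- NA_character_
  }
  rec$repressive_overlap <- if (!is.null(marks) && nrow(marks) > 0) {
    d <- data.frame(chrom = rec$distal_chrom, start = rec$distal_start,
                    end = rec$distal_end, stringsAsFactors = FALSE)
    seq_len(nrow(d)) %in% overlap_pairs(d, marks)$a
  } else rep(FALSE, nrow(rec))
  rownames(rec) <- NULL
  rec
}

#' Enrichment of differential expression among linked genes
#'
#' Compares a summary statistic (median by default) of the log2 fold
#' changes of the linked genes with `n_random` random size-matched
#' gene sets drawn without replacement from `universe` excluding the
#' linked set. The empirical p-value uses the add-one rule with ties
#' counting as exceedances.
#'
#' @param linked_genes character vector of linked gene ids.
#' @param de output of [differential_expression()].
#' @param universe gene ids to sample from (default `de$universe`).
#' @param n_random number of random sets (default 10).
#' @param seed integer seed.
#' @param stat "median" (default) or "mean".
#' @return list: observed_stat, null_stats, n_random, p_empirical,
#'   seed.
#' @export
de_enrichment <- function(linked_genes, de, universe = de$universe,
                          n_random = 10, seed = 1337,
                          stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") stats::median else mean
  linked_genes <- unique(linked_genes)
  if (!all(linked_genes %in% universe))
    stop("linked genes must be a subset of the universe")
  pool <- setdiff(universe, linked_genes)
  if (length(pool) < length(linked_genes))
    stop("universe too small for size-matched sampling")
  lfc <- stats::setNames(de$results$log_fc, de$results$feature_id)
  observed <- fun(lfc[linked_genes])
  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n_random), function(i)
      fun(lfc[sample(pool, length(linked_genes))]), numeric(1))
  })
  list(observed_stat = unname(observed), null_stats = unname(null_stats),
       n_random = n_random,
       p_empirical = (sum(null_stats >= observed) + 1) / (n_random + 1),
       seed = seed, stat = stat)
}

# reduce marks to disjoint sorted intervals per chromosome
reduce_marks <- function(marks) {
  gr <- GenomicRanges::reduce(as_granges(marks))
  split(data.frame(start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr)),
        as.character(GenomicRanges::seqnames(gr)))
}

# vectorized: do [s, s+w) intervals overlap any reduced mark?
hits_marks <- function(s, w, mk) {
  if (is.null(mk) || nrow(mk) == 0) return(rep(FALSE, length(s)))
  idx <- findInterval(s, mk$start)
  hit <- idx >= 1 & mk$end[pmax(idx, 1)] > s
  nxt <- idx + 1
  hit | (nxt <= nrow(mk) & mk$start[pmin(nxt, nrow(mk))] < s + w)
}

#' Silencer-loss permutation test
#'
#' For candidate records (diagnosis-specific interactions of
#' upregulated genes), the observed statistic is the fraction of
#' candidate genes whose distal anchor overlaps at least one
#' repressive-mark interval. Each null replicate replaces every
#' candidate distal anchor with a uniformly placed interval of
#' identical width on the same chromosome and recomputes the
#' fraction; `p = (k_exceed + 1) / (n_perm + 1)` with ties counting
#' as exceedances.
#'
#' @param candidates integration-record data frame (see
#'   [integration_records()]).
#' @param marks repressive-mark interval data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list: observed_prop, genes (per-gene overlap flags),
#'   repressive_genes, n_perm, k_exceed, p_value, p_value_trunc
#'   (truncated to 3 significant figures, the convention used in
#'   reports), seed.
#' @export
silencer_loss_test <- function(candidates, marks, chrom_sizes,
                               n_perm = 10000, seed = 1337) {
  if (nrow(candidates) == 0) stop("no candidate records")
  if (nrow(marks) == 0) stop("no repressive-mark intervals")
  d <- data.frame(chrom = candidates$distal_chrom,
                  start = candidates$distal_start,
                  end = candidates$distal_end, stringsAsFactors = FALSE)
  w <- d$end - d$start
  L <- chrom_sizes[d$chrom]
  if (anyNA(L)) stop("chromosome missing from chrom_sizes: ",
                     d$chrom[which(is.na(L))[1]])
  if (any(L < w)) stop("chromosome shorter than an anchor width")
  genes <- candidates$gene_id
  ug <- unique(genes)
  mk <- reduce_marks(marks)
  obs_rec <- mapply(function(ch, s, wd) hits_marks(s, wd, mk[[ch]]),
                    d$chrom, d$start, w)
  gene_hit <- vapply(ug, function(g) any(obs_rec[genes == g]), logical(1))
  observed <- mean(gene_hit)
  null_props <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- floor(stats::runif(nrow(d), 0, L - w + 1))
      rec_hit <- vapply(seq_len(nrow(d)), function(i)
        hits_marks(s[i], w[i], mk[[d$chrom[i]]]), logical(1))
      mean(vapply(ug, function(g) any(rec_hit[genes == g]), logical(1)))
    }, numeric(1))
  })
  k <- sum(null_props >= observed)
  p <- (k + 1) / (n_perm + 1)
  list(observed_prop = observed,
       genes = stats::setNames(gene_hit, ug),
       repressive_genes = ug[gene_hit],
       n_perm = n_perm, k_exceed = k,
       p_value = p, p_value_trunc = trunc_signif(p, 3),
       seed = seed)
}

#' Truncate to significant figures
#'
#' Truncation (not rounding) to `digits` significant figures, the
#' convention used when printing permutation p-values, e.g.
#' `(0 + 1) / (10000 + 1)` prints as 9.99e-05.
#'
#' @param x numeric vector.
#' @param digits significant figures kept.
#' @return truncated values.
#' @export
trunc_signif <- function(x, digits = 3) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    e <- floor(log10(abs(v)))
    scale <- 10^(e - digits + 1)
    trunc(v / scale) * scale
  }, numeric(1))
}
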