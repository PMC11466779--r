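#' Synthetic multi-omic data with planted ground truth
#'
#' Generates a coupled dataset for a 2-diagnosis / 2-relapse design:
#' per-sample loop-strength BEDPE files (log-normal baseline
#' strengths, planted differential loops scaled by
#' `2^loop_effect_log2` in their favored group), replicate ATAC-seq
#' peak BED files (background peaks in all samples, planted
#' state-specific peaks inside planted loop anchors, realized in both
#' replicates with probability `peak_reproducibility`), a gene
#' annotation BED and negative-binomial count table with planted DE
#' genes, and an H3K27me3 BED covering the distal anchors of planted
#' silencer-loss genes plus uniform background marks. Truth tables
#' record every planted element.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome.
#' @param n_loops total loops.
#' @param frac_diff_loops fraction of loops planted differential.
#' @param loop_effect_log2 planted |log2 effect| on loop strengths.
#' @param loop_noise_sd natural-log SD of multiplicative loop noise.
#' @param n_genes total genes.
#' @param n_de_genes planted DE genes (half up, half down).
#' @param de_log2fc planted |log2 fold change| for DE genes.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param peak_reproducibility probability a planted peak appears in
#'   both replicates of its state (otherwise in one, chosen at
#'   random).
#' @param frac_silencer_loss_genes fraction of upregulated genes
#'   wired as silencer-loss genes (diagnosis-specific loop whose
#'   distal anchor carries a repressive mark).
#' @param seed master seed.
#' @return validated config list of class "sim_config".
#' @export
sim_config <- function(n_chrom = 2, chrom_length_bp = 1e7,
                       n_loops = 20000, frac_diff_loops = 0.05,
                       loop_effect_log2 = 2.0, loop_noise_sd = 0.3,
                       n_genes = 5000, n_de_genes = 200,
                       de_log2fc = 2.0, nb_dispersion = 0.1,
                       peak_reproducibility = 0.9,
                       frac_silencer_loss_genes = 0.1, seed = 1337) {
  cfg <- list(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
              n_loops = n_loops, frac_diff_loops = frac_diff_loops,
              loop_effect_log2 = loop_effect_log2,
              loop_noise_sd = loop_noise_sd, n_genes = n_genes,
              n_de_genes = n_de_genes, de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion,
              peak_reproducibility = peak_reproducibility,
              frac_silencer_loss_genes = frac_silencer_loss_genes,
              seed = seed,
              anchor_width = 5000, peak_width = 500,
              gene_width = 2000, mark_width = 1000,
              mark_background_frac = 0.01,
              n_background_peaks = 4000,
              n_noise_peaks = 500)
  fracs <- c(cfg$frac_diff_loops, cfg$peak_reproducibility,
             cfg$frac_silencer_loss_genes, cfg$mark_background_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  counts <- c(cfg$n_chrom, cfg$chrom_length_bp, cfg$n_loops, cfg$n_genes)
  if (any(counts <= 0)) stop("counts must be positive")
  if (!is.finite(cfg$loop_effect_log2) || !is.finite(cfg$de_log2fc))
    stop("effect sizes must be finite")
  if (cfg$n_de_genes > cfg$n_genes) stop("n_de_genes > n_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale default configuration
#'
#' Two chromosomes of 10 Mb, 20,000 loops (5% differential, effect
#' 2.0, noise SD 0.3), 5,000 genes (200 DE at |log2FC| 2, dispersion
#' 0.1), peak reproducibility 0.9, 10 silencer-loss genes, seed
#' 1337. Runs the full pipeline in well under five minutes on one
#' CPU.
#'
#' @return a [sim_config()].
#' @export
default_desk_config <- function() sim_config()

#' Simulate a loop-strength matrix
#'
#' Baseline strengths are log-normal per loop; loops with
#' `direction = -1` are multiplied by `2^effect` in diagnosis
#' samples, `+1` in relapse samples; multiplicative log-normal noise
#' and per-sample depth factors are applied.
#'
#' @param n_loops number of loops.
#' @param direction integer vector in \{-1, 0, 1\} per loop (drawn
#'   from `frac_diff` when NULL: half -1, half +1).
#' @param frac_diff fraction differential when `direction` is NULL.
#' @param effect planted |log2 effect|.
#' @param noise_sd natural-log noise SD.
#' @param n_per_group replicates per group.
#' @param depth_range range of per-sample depth multipliers.
#' @param seed integer seed.
#' @return list with `matrix` (loops x samples, diagnosis columns
#'   first), `group`, and `direction`.
#' @export
simulate_loop_strengths <- function(n_loops, direction = NULL,
                                    frac_diff = 0.05, effect = 2.0,
                                    noise_sd = 0.3, n_per_group = 2,
                                    depth_range = c(0.7, 1.4),
                                    seed = 1337) {
  with_local_seed(seed, {
    if (is.null(direction)) {
      n_diff <- round(frac_diff * n_loops)
      direction <- rep(0L, n_loops)
      if (n_diff > 0)
        direction[seq_len(n_diff)] <-
          rep(c(-1L, 1L), length.out = n_diff)
    }
    stopifnot(length(direction) == n_loops)
    base <- exp(stats::rnorm(n_loops, log(10), 1))
    group <- rep(c("diagnosis", "relapse"), each = n_per_group)
    depth <- stats::runif(length(group), depth_range[1], depth_range[2])
    m <- matrix(0, n_loops, length(group))
    for (j in seq_along(group)) {
      fold <- ifelse(direction == -1L & group[j] == "diagnosis", 2^effect,
              ifelse(direction == +1L & group[j] == "relapse", 2^effect, 1))
      m[, j] <- base * fold * depth[j] *
        exp(stats::rnorm(n_loops, 0, noise_sd))
    }
    rownames(m) <- sprintf("loop%05d", seq_len(n_loops))
    colnames(m) <- paste0(substr(group, 1, 1), rep(1:n_per_group, 2))
    list(matrix = m, group = stats::setNames(group, colnames(m)),
         direction = stats::setNames(direction, rownames(m)))
  })
}

#' Simulate a negative-binomial gene count matrix
#'
#' @param mu per-gene baseline means.
#' @param log2fc per-gene planted log2 fold change (relapse vs
#'   diagnosis; 0 for null genes).
#' @param dispersion common NB dispersion (variance = mu + disp*mu^2).
#' @param n_per_group replicates per group.
#' @param depth_range per-sample depth multiplier range.
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples) and `group`.
#' @export
simulate_gene_counts <- function(mu, log2fc = rep(0, length(mu)),
                                 dispersion = 0.1, n_per_group = 2,
                                 depth_range = c(0.7, 1.4),
                                 seed = 1337) {
  stopifnot(length(log2fc) == length(mu), dispersion > 0)
  with_local_seed(seed, {
    group <- rep(c("diagnosis", "relapse"), each = n_per_group)
    depth <- stats::runif(length(group), depth_range[1], depth_range[2])
    m <- matrix(0, length(mu), length(group))
    for (j in seq_along(group)) {
      mj <- mu * depth[j] *
        (if (group[j] == "relapse") 2^log2fc else rep(1, length(mu)))
      m[, j] <- stats::rnbinom(length(mu), mu = mj, size = 1 / dispersion)
    }
    rownames(m) <- if (!is.null(names(mu))) names(mu)
                   else sprintf("gene%05d", seq_along(mu))
    colnames(m) <- paste0(substr(group, 1, 1), rep(1:n_per_group, 2))
    list(matrix = m, group = stats::setNames(group, colnames(m)))
  })
}

#' Generate the full synthetic dataset on disk
#'
#' Chromosome layout: planted differential loops occupy regular,
#' non-overlapping slots; their promoter anchors lie in the first 40%
#' of each chromosome and their distal anchors 40% of a chromosome
#' length downstream, guaranteeing the >= 100 kb promoter-distal
#' separation. Genes wired to planted loops sit immediately
#' downstream of the promoter anchor (well inside the 20 kb
#' assignment window); all other genes, background peaks and
#' replicate-noise peaks live in the last 20% of each chromosome so
#' random placement cannot contaminate planted truth. Background
#' H3K27me3 marks are uniform genome-wide.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created).
#' @return list with `paths`, `truth` (tables of planted elements),
#'   `chrom_sizes` and `cfg`.
#' @export
simulate_dataset <- function(cfg = default_desk_config(),
                             out_dir = tempfile("simdata")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  L <- cfg$chrom_length_bp
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  aw <- cfg$anchor_width; pw <- cfg$peak_width; gw <- cfg$gene_width

  n_diff <- round(cfg$frac_diff_loops * cfg$n_loops)
  nd_c <- ceiling(n_diff / cfg$n_chrom)
  prom_zone <- c(0, floor(0.4 * L))
  dist_off <- floor(0.4 * L)
  bg_zone <- c(floor(0.8 * L) + 25000, L)
  slot <- if (nd_c > 0) floor(prom_zone[2] / nd_c) else prom_zone[2]
  if (nd_c > 0 && slot < aw + gw + 600)
    stop("geometry overflow: more planted loops than fit without overlap")
  if (dist_off < 100000)
    stop("geometry overflow: chromosome too short for 100 kb separation")

  # --- planted differential loop geometry ---------------------------
  diff_geo <- NULL
  if (n_diff > 0) {
    idx <- seq_len(n_diff) - 1
    chrom_i <- idx %% cfg$n_chrom + 1
    k <- idx %/% cfg$n_chrom
    ps <- k * slot
    diff_geo <- data.frame(
      chrom = chroms[chrom_i],
      prom_start = ps, prom_end = ps + aw,
      dist_start = ps + dist_off, dist_end = ps + dist_off + aw,
      direction = rep(c(-1L, 1L), length.out = n_diff),
      stringsAsFactors = FALSE)
  }

  # --- loop strengths (planted loops first, then null loops) --------
  direction <- c(if (n_diff > 0) diff_geo$direction else integer(),
                 rep(0L, cfg$n_loops - n_diff))
  sim <- simulate_loop_strengths(cfg$n_loops, direction = direction,
                                 effect = cfg$loop_effect_log2,
                                 noise_sd = cfg$loop_noise_sd,
                                 seed = derive_seed(cfg$seed, 1))

  null_geo <- with_local_seed(derive_seed(cfg$seed, 2), {
    n_null <- cfg$n_loops - n_diff
    chrom <- sample(chroms, n_null, replace = TRUE)
    a <- floor(stats::runif(n_null, 0, L - 1.2e6 - 2 * aw))
    d <- floor(stats::runif(n_null, 1e5, 1e6))
    data.frame(chrom = chrom, prom_start = a, prom_end = a + aw,
               dist_start = a + d, dist_end = a + d + aw,
               direction = 0L, stringsAsFactors = FALSE)
  })
  geo <- rbind(diff_geo, null_geo)
  geo$loop_id <- rownames(sim$matrix)

  loop_paths <- character(0)
  for (j in seq_len(ncol(sim$matrix))) {
    df <- data.frame(chrom1 = geo$chrom, start1 = geo$prom_start,
                     end1 = geo$prom_end, chrom2 = geo$chrom,
                     start2 = geo$dist_start, end2 = geo$dist_end,
                     strength = sim$matrix[, j], loop_id = geo$loop_id,
                     stringsAsFactors = FALSE)
    p <- file.path(out_dir, paste0("loops_", colnames(sim$matrix)[j],
                                   ".bedpe"))
    write_bedpe_loops(df, p)
    loop_paths <- c(loop_paths, p)
  }

  # --- planted state-specific peaks inside planted anchors ----------
  peak_truth <- NULL
  planted_peaks <- list(d1 = NULL, d2 = NULL, r1 = NULL, r2 = NULL)
  if (n_diff > 0) {
    both_ends <- rbind(
      data.frame(chrom = diff_geo$chrom,
                 start = diff_geo$prom_start + (aw - pw) %/% 2,
                 direction = diff_geo$direction, loop_id = geo$loop_id[seq_len(n_diff)],
                 endtype = "promoter", stringsAsFactors = FALSE),
      data.frame(chrom = diff_geo$chrom,
                 start = diff_geo$dist_start + (aw - pw) %/% 2,
                 direction = diff_geo$direction, loop_id = geo$loop_id[seq_len(n_diff)],
                 endtype = "distal", stringsAsFactors = FALSE))
    both_ends$end <- both_ends$start + pw
    both_ends$state <- ifelse(both_ends$direction == -1L,
                              "diagnosis", "relapse")
    both_ends$name <- sprintf("pk_%s_%05d",
                              substr(both_ends$state, 1, 1),
                              seq_len(nrow(both_ends)))
    real <- with_local_seed(derive_seed(cfg$seed, 3), {
      both <- stats::runif(nrow(both_ends)) < cfg$peak_reproducibility
      pick <- sample(1:2, nrow(both_ends), replace = TRUE)
      list(both = both, pick = pick)
    })
    both_ends$in_rep1 <- real$both | real$pick == 1
    both_ends$in_rep2 <- real$both | real$pick == 2
    for (st in c("diagnosis", "relapse")) {
      pref <- substr(st, 1, 1)
      sel <- both_ends$state == st
      planted_peaks[[paste0(pref, 1)]] <-
        both_ends[sel & both_ends$in_rep1,
                  c("chrom", "start", "end", "name")]
      planted_peaks[[paste0(pref, 2)]] <-
        both_ends[sel & both_ends$in_rep2,
                  c("chrom", "start", "end", "name")]
    }
    peak_truth <- both_ends[, c("name", "chrom", "start", "end", "state",
                                "loop_id", "endtype", "in_rep1", "in_rep2")]
  }

  # --- background and replicate-noise peaks -------------------------
  bg_width <- bg_zone[2] - bg_zone[1] - pw
  bg <- with_local_seed(derive_seed(cfg$seed, 4), {
    n <- cfg$n_background_peaks
    chrom <- sample(chroms, n, replace = TRUE)
    s <- bg_zone[1] + floor(stats::runif(n, 0, bg_width))
    data.frame(chrom = chrom, start = s, end = s + pw,
               name = sprintf("bg_%05d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
  noise <- with_local_seed(derive_seed(cfg$seed, 5), {
    lapply(stats::setNames(nm = c("d1", "d2", "r1", "r2")), function(id) {
      n <- cfg$n_noise_peaks
      chrom <- sample(chroms, n, replace = TRUE)
      s <- bg_zone[1] + floor(stats::runif(n, 0, bg_width))
      data.frame(chrom = chrom, start = s, end = s + pw,
                 name = sprintf("noise_%s_%05d", id, seq_len(n)),
                 stringsAsFactors = FALSE)
    })
  })
  peak_paths <- character(0)
  for (id in c("d1", "d2", "r1", "r2")) {
    pk <- sort_intervals(rbind(planted_peaks[[id]], bg, noise[[id]]))
    p <- file.path(out_dir, paste0("peaks_", id, ".bed"))
    write_bed(pk, p)
    peak_paths <- c(peak_paths, p)
  }

  # --- genes: wired (silencer-loss + relapse tri-omic) and free -----
  n_up <- cfg$n_de_genes %/% 2
  n_down <- cfg$n_de_genes - n_up
  n_sil <- round(cfg$frac_silencer_loss_genes * n_up)
  d_loops <- which(geo$direction == -1L)
  r_loops <- which(geo$direction == +1L)
  if (n_sil > length(d_loops) || n_sil > length(r_loops))
    stop("geometry overflow: not enough planted loops to wire genes")
  sil_loops <- d_loops[seq_len(n_sil)]
  rel_loops <- r_loops[seq_len(n_sil)]
  wired <- c(sil_loops, rel_loops)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  symbols <- toupper(gene_ids)
  n_free <- cfg$n_genes - length(wired)
  free_geo <- with_local_seed(derive_seed(cfg$seed, 6), {
    chrom <- sample(chroms, n_free, replace = TRUE)
    s <- bg_zone[1] + floor(stats::runif(n_free, 0, bg_zone[2] - bg_zone[1] - gw))
    data.frame(chrom = chrom, start = s, end = s + gw,
               stringsAsFactors = FALSE)
  })
  ann <- data.frame(
    chrom = c(geo$chrom[wired], free_geo$chrom),
    start = c(geo$prom_end[wired] + 500, free_geo$start),
    end = c(geo$prom_end[wired] + 500 + gw, free_geo$end),
    gene_id = gene_ids, symbol = symbols,
    stringsAsFactors = FALSE)
  ann$strand <- with_local_seed(derive_seed(cfg$seed, 7),
                                sample(c("+", "-"), cfg$n_genes,
                                       replace = TRUE))
  ann_path <- file.path(out_dir, "genes.bed")
  utils::write.table(
    cbind(ann$chrom, ann$start, ann$end, ann$gene_id, ann$symbol,
          ann$strand),
    ann_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  # DE assignment: wired genes are upregulated; remaining planted DE
  # genes are free genes
  log2fc <- rep(0, cfg$n_genes)
  # wired genes count toward "up"; total up = wired (2*n_sil) + free up
  n_free_up <- max(0, n_up - 2 * n_sil)
  up_ids <- c(gene_ids[seq_along(wired)],
              gene_ids[length(wired) + seq_len(n_free_up)])
  down_ids <- gene_ids[length(wired) + n_free_up + seq_len(n_down)]
  log2fc[match(up_ids, gene_ids)] <- cfg$de_log2fc
  log2fc[match(down_ids, gene_ids)] <- -cfg$de_log2fc
  mu <- with_local_seed(derive_seed(cfg$seed, 8),
                        pmax(exp(stats::rnorm(cfg$n_genes, log(100), 1)), 2))
  names(mu) <- gene_ids
  gc <- simulate_gene_counts(mu, log2fc, dispersion = cfg$nb_dispersion,
                             seed = derive_seed(cfg$seed, 9))
  counts_path <- file.path(out_dir, "counts.tsv")
  write_counts_tsv(gc$matrix, counts_path, id_col = "gene_id")

  # --- H3K27me3: silencer distal anchors + uniform background -------
  sil_marks <- if (n_sil > 0)
    data.frame(chrom = geo$chrom[sil_loops],
               start = geo$dist_start[sil_loops],
               end = geo$dist_end[sil_loops],
               name = sprintf("mark_sil_%03d", seq_len(n_sil)),
               stringsAsFactors = FALSE) else NULL
  n_bg_marks <- round(cfg$mark_background_frac * cfg$n_chrom * L /
                      cfg$mark_width)
  bg_marks <- with_local_seed(derive_seed(cfg$seed, 10), {
    chrom <- sample(chroms, n_bg_marks, replace = TRUE)
    s <- floor(stats::runif(n_bg_marks, 0, L - cfg$mark_width))
    data.frame(chrom = chrom, start = s, end = s + cfg$mark_width,
               name = sprintf("mark_bg_%05d", seq_len(n_bg_marks)),
               stringsAsFactors = FALSE)
  })
  marks <- sort_intervals(rbind(sil_marks, bg_marks))
  marks_path <- file.path(out_dir, "h3k27me3.bed")
  write_bed(marks, marks_path)

  sizes_path <- file.path(out_dir, "chrom.sizes")
  utils::write.table(cbind(chroms, format(rep(L, cfg$n_chrom),
                                          scientific = FALSE)),
                     sizes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # --- truth tables -------------------------------------------------
  sil_genes <- gene_ids[seq_len(n_sil)]
  rel_genes <- gene_ids[n_sil + seq_len(n_sil)]
  wired_genes <- c(sil_genes, rel_genes)
  # tri-omic truth: wired genes whose promoter-anchor peak is realized
  # in both replicates of its state (the chain is then discoverable)
  tri <- character(0)
  if (n_diff > 0 && length(wired)) {
    prom_pk <- peak_truth[peak_truth$endtype == "promoter", ]
    realized <- prom_pk$loop_id[prom_pk$in_rep1 & prom_pk$in_rep2]
    tri <- wired_genes[geo$loop_id[wired] %in% realized]
  }
  truth <- list(
    diff_loops = data.frame(
      loop_id = geo$loop_id[geo$direction != 0L],
      state = ifelse(geo$direction[geo$direction != 0L] == -1L,
                     "diagnosis", "relapse"),
      stringsAsFactors = FALSE),
    peaks = peak_truth,
    de_genes = data.frame(
      gene_id = c(up_ids, down_ids),
      sign = rep(c("up", "down"), c(length(up_ids), length(down_ids))),
      stringsAsFactors = FALSE),
    silencer_loss_genes = sil_genes,
    relapse_wired_genes = rel_genes,
    tri_omic_genes = tri)
  for (nm in c("diff_loops", "peaks", "de_genes")) {
    if (!is.null(truth[[nm]]))
      utils::write.table(truth[[nm]],
                         file.path(out_dir, "truth",
                                   paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(sil_genes, file.path(out_dir, "truth",
                                  "silencer_loss_genes.txt"))
  writeLines(tri, file.path(out_dir, "truth", "tri_omic_genes.txt"))

  list(paths = list(loops = stats::setNames(loop_paths,
                                            colnames(sim$matrix)),
                    peaks = stats::setNames(peak_paths,
                                            c("d1", "d2", "r1", "r2")),
                    annotation = ann_path, counts = counts_path,
                    marks = marks_path, chrom_sizes = sizes_path,
                    dir = out_dir),
       group = sim$group,
       truth = truth,
       chrom_sizes = stats::setNames(rep(L, cfg$n_chrom), chroms),
       cfg = cfg)
}
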