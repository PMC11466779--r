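#' Pipeline orchestration
#'
#' Runs the full diagnosis-vs-relapse comparison in dependency
#' order — simulate (optional) -> differential loops -> peak states
#' -> differential expression -> integration — behind one
#' configuration list (or YAML file), with deterministic seeding and
#' a run log. The report is written as versioned JSON plus a TSV of
#' headline counts; reruns with the same inputs and seed are
#' byte-identical (timestamps are confined to the log).
#'
#' @name pipeline
NULL

#' Assemble the integration report
#'
#' All stages are required; a missing one raises an error naming it.
#'
#' @param dl differential loops ([call_differential_loops()]).
#' @param loops anchor table from [build_loop_matrix()].
#' @param sp peak states ([derive_states()]).
#' @param de differential expression ([differential_expression()]).
#' @param records_diagnosis,records_relapse integration records.
#' @param enrich_diagnosis,enrich_relapse enrichment results
#'   ([de_enrichment()]); may be NA when no genes were linked.
#' @param silencer silencer-loss permutation ([silencer_loss_test()]);
#'   may be NA when there were no candidates.
#' @param seed master seed used for the run.
#' @return report list (JSON-ready).
#' @export
build_report <- function(dl, loops, sp, de, records_diagnosis,
                         records_relapse, enrich_diagnosis,
                         enrich_relapse, silencer, seed) {
  stages <- list(dl = dl, loops = loops, sp = sp, de = de,
                 records_diagnosis = records_diagnosis,
                 records_relapse = records_relapse)
  for (nm in names(stages))
    if (is.null(stages[[nm]])) stop("missing stage output: ", nm)
  anc_d <- state_anchors(dl, loops, "diagnosis")
  anc_r <- state_anchors(dl, loops, "relapse")
  linked_d <- unique(records_diagnosis$gene_id)
  linked_r <- unique(records_relapse$gene_id)
  de_sig <- c(de$upregulated, de$downregulated)
  tri <- sort(intersect(union(linked_d, linked_r), de_sig))
  enr <- function(e) if (is.null(e) || all(is.na(e[1]))) NULL else
    list(observed_stat = e$observed_stat, null_stats = e$null_stats,
         n_random = e$n_random, p_empirical = e$p_empirical,
         seed = e$seed, stat = e$stat)
  sil <- if (is.null(silencer) || all(is.na(silencer[1]))) NULL else
    list(observed_prop = silencer$observed_prop,
         n_perm = silencer$n_perm, k_exceed = silencer$k_exceed,
         p_value = silencer$p_value,
         p_value_trunc = silencer$p_value_trunc,
         repressive_genes = sort(silencer$repressive_genes),
         seed = silencer$seed)
  list(
    schema_version = "1.0",
    seed = seed,
    loops = list(n_tested = dl$n_top,
                 n_significant = length(dl$relapse_specific) +
                                 length(dl$diagnosis_specific),
                 n_diagnosis_specific = length(dl$diagnosis_specific),
                 n_relapse_specific = length(dl$relapse_specific),
                 alpha = dl$alpha),
    anchors = list(n_diagnosis = nrow(anc_d), n_relapse = nrow(anc_r),
                   n_unique_accessible_diagnosis =
                     length(unique(paste(records_diagnosis$promoter_chrom,
                                         records_diagnosis$promoter_start))),
                   n_unique_accessible_relapse =
                     length(unique(paste(records_relapse$promoter_chrom,
                                         records_relapse$promoter_start)))),
    peaks = as.list(sp$counts),
    expression = list(n_universe = length(de$universe),
                      n_significant = length(de_sig),
                      n_upregulated = length(de$upregulated),
                      n_downregulated = length(de$downregulated),
                      alpha = de$alpha, lfc = de$lfc),
    integration = list(
      n_linked_genes_diagnosis = length(linked_d),
      n_linked_genes_relapse = length(linked_r),
      linked_genes_diagnosis = sort(linked_d),
      linked_genes_relapse = sort(linked_r),
      linked_upregulated_diagnosis =
        sort(intersect(linked_d, de$upregulated)),
      linked_upregulated_relapse =
        sort(intersect(linked_r, de$upregulated)),
      enrichment_diagnosis = enr(enrich_diagnosis),
      enrichment_relapse = enr(enrich_relapse),
      silencer_loss = sil,
      tri_omic_genes = tri,
      n_tri_omic_genes = length(tri)))
}

#' Write the report as JSON and TSV
#' @param report list from [build_report()].
#' @param out_dir output directory.
#' @return paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  flat <- c(unlist(report$loops), unlist(report$peaks),
            unlist(report$expression),
            n_tri_omic_genes = report$integration$n_tri_omic_genes)
  tp <- file.path(out_dir, "report.tsv")
  utils::write.table(data.frame(key = names(flat),
                                value = unname(flat)),
                     tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = jp, tsv = tp))
}

#' Default run parameters
#' @return named list of stage parameters.
#' @export
default_params <- function() {
  list(n_top = 100000, alpha = 0.1, lfc = 1, window = 20000,
       n_random = 10, n_perm = 10000, seed = 1337,
       enrichment_universe = "whole", weight_trend_rna = TRUE)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' @param config list (or path to a YAML file) with entries:
#'   `simulate` (logical; when TRUE the inputs are generated with
#'   [simulate_dataset()] using `sim` overrides), or `inputs` with
#'   named paths `loops` (d1, d2, r1, r2), `peaks` (d1, d2, r1, r2),
#'   `counts`, `annotation`, `marks`, `chrom_sizes` and a `groups`
#'   vector for the loop/count samples; `params` overriding
#'   [default_params()]; `out_dir`.
#' @return the report list, invisibly; outputs under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_params(),
                              config$params %||% list())
  out_dir <- config$out_dir %||% tempfile("triomics_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))

  if (isTRUE(config$simulate)) {
    cfg <- do.call(sim_config,
                   utils::modifyList(list(seed = params$seed),
                                     config[["sim"]] %||% list()))
    log_line(logf, "stage simulate: seed=", cfg$seed)
    sim <- simulate_dataset(cfg, file.path(out_dir, "simdata"))
    inputs <- sim$paths
    groups <- sim$group
    chrom_sizes <- sim$chrom_sizes
    truth <- sim$truth
  } else {
    inputs <- config$inputs
    for (p in c(unlist(inputs$loops), unlist(inputs$peaks),
                inputs$counts, inputs$annotation, inputs$marks,
                inputs$chrom_sizes))
      if (!file.exists(p)) stop("pre-flight: missing input file: ", p)
    groups <- config$groups
    if (is.null(groups)) stop("pre-flight: 'groups' is required")
    chrom_sizes <- read_chrom_sizes(inputs$chrom_sizes)
    truth <- NULL
  }

  log_line(logf, "stage diffloops: n_top=", params$n_top,
           " alpha=", params$alpha)
  grp <- if (!is.null(names(groups)) && !is.null(names(inputs$loops)))
    unname(groups[names(inputs$loops)]) else unname(groups)
  lm <- build_loop_matrix(unname(unlist(inputs$loops)), groups = grp,
                          sample_ids = names(inputs$loops))
  dl <- call_differential_loops(lm, n_top = params$n_top,
                                alpha = params$alpha)
  utils::write.table(dl$results, file.path(out_dir, "loop_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anc_d <- state_anchors(dl, lm$loops, "diagnosis")
  anc_r <- state_anchors(dl, lm$loops, "relapse")
  write_bed(anc_d, file.path(out_dir, "diagnosis_anchors.bed"))
  write_bed(anc_r, file.path(out_dir, "relapse_anchors.bed"))

  log_line(logf, "stage peakstates")
  pk <- lapply(inputs$peaks, read_bed)
  sp <- derive_states(pk$d1, pk$d2, pk$r1, pk$r2)
  for (nm in c("common_diagnosis", "common_relapse",
               "diagnosis_specific", "relapse_specific", "shared"))
    write_bed(sp[[nm]], file.path(out_dir, paste0("peaks_", nm, ".bed")))
  jsonlite::write_json(as.list(sp$counts),
                       file.path(out_dir, "peak_counts.json"),
                       auto_unbox = TRUE)

  log_line(logf, "stage diffexpr: alpha=", params$alpha,
           " lfc=", params$lfc)
  de <- differential_expression(inputs$counts, groups,
                                alpha = params$alpha, lfc = params$lfc,
                                weight_trend = params$weight_trend_rna)
  utils::write.table(de$results, file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(de$upregulated, file.path(out_dir, "up.txt"))
  writeLines(de$downregulated, file.path(out_dir, "down.txt"))

  log_line(logf, "stage integrate: window=", params$window,
           " n_random=", params$n_random, " n_perm=", params$n_perm)
  ann <- read_gene_annotation(inputs$annotation)
  marks <- read_bed(inputs$marks)
  rec_d <- integration_records(dl, lm$loops, "diagnosis",
                               sp$diagnosis_specific, ann, de, marks,
                               window = params$window)
  rec_r <- integration_records(dl, lm$loops, "relapse",
                               sp$relapse_specific, ann, de, marks,
                               window = params$window)
  universe <- if (identical(params$enrichment_universe, "upregulated"))
    de$upregulated else de$universe
  run_enrich <- function(rec, k) {
    genes <- intersect(unique(rec$gene_id), de$upregulated)
    genes <- intersect(genes, universe)
    if (length(genes) == 0 ||
        length(setdiff(universe, genes)) < length(genes)) return(NULL)
    de_enrichment(genes, de, universe = universe,
                  n_random = params$n_random,
                  seed = derive_seed(params$seed, k))
  }
  enr_d <- run_enrich(rec_d, 101)
  enr_r <- run_enrich(rec_r, 102)
  # candidates: genes upregulated in relapse (positive log2FC; the
  # silencer-loss hypothesis concerns the direction of change, not
  # the DE significance call)
  cand <- rec_d[!is.na(rec_d$log_fc) & rec_d$log_fc > 0, , drop = FALSE]
  sil <- if (nrow(cand) > 0 && nrow(marks) > 0)
    silencer_loss_test(cand, marks, chrom_sizes,
                       n_perm = params$n_perm,
                       seed = derive_seed(params$seed, 103)) else NULL
  report <- build_report(dl, lm$loops, sp, de, rec_d, rec_r,
                         enr_d, enr_r, sil, seed = params$seed)
  if (!is.null(truth)) {
    recovered <- intersect(report$integration$silencer_loss$repressive_genes,
                           truth$silencer_loss_genes)
    report$truth_eval <- list(
      n_planted_silencer_genes = length(truth$silencer_loss_genes),
      n_silencer_genes_recovered = length(recovered),
      n_planted_tri_omic = length(truth$tri_omic_genes),
      n_tri_omic_recovered =
        length(intersect(report$integration$tri_omic_genes,
                         truth$tri_omic_genes)))
  }
  write_report(report, out_dir)
  log_line(logf, "done")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
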