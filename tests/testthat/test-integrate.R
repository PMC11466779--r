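test_that("accessible anchors are exactly those overlapping a peak", {
  anchors <- intervals("chr1", c(0, 10000), c(5000, 15000))
  peaks <- intervals("chr1", 2000, 2500, name = "pk1")
  acc <- accessible_anchors(anchors, peaks)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$start, 0)
  expect_equal(acc$peak_ids[[1]], "pk1")
  # no overlaps anywhere
  far <- intervals("chr1", 90000, 90100)
  expect_equal(nrow(accessible_anchors(anchors, far)), 0)
  # brute-force equivalence
  set.seed(23)
  a <- random_intervals(120); p <- random_intervals(120)
  got <- accessible_anchors(a, p)
  want <- sort(unique(brute_overlap(a, p)$a))
  expect_equal(nrow(got), length(want))
  expect_equal(got$start, a$start[want])
})

test_that("gene assignment respects the 20 kb window", {
  ann_file <- write_tmp("chr1\t10000\t20000\tg1\tG1\t+")
  ann <- read_gene_annotation(ann_file)
  near <- intervals("chr1", 35000, 36000)
  expect_equal(assign_genes(near, ann)$gene_id, "g1")  # gap 15 kb
  far <- intervals("chr1", 45001, 46000)               # gap > 20 kb
  expect_equal(nrow(assign_genes(far, ann)), 0)
  # boundary: gap exactly 20,000 fails half-open, 19,999 links
  edge <- intervals("chr1", 40000, 41000)
  expect_equal(nrow(assign_genes(edge, ann)), 0)
  edge2 <- intervals("chr1", 39999, 41000)
  expect_equal(assign_genes(edge2, ann)$gene_id, "g1")
})

fake_de <- function(genes, lfc) {
  res <- data.frame(feature_id = genes, log_fc = lfc,
                    state_call = ifelse(lfc > 1, "up",
                                        ifelse(lfc < -1, "down", "ns")),
                    stringsAsFactors = FALSE)
  list(results = res, upregulated = res$feature_id[res$state_call == "up"],
       downregulated = res$feature_id[res$state_call == "down"],
       universe = genes, alpha = 0.1, lfc = 1)
}

test_that("enrichment p-values follow the add-one rule with ties as exceedances", {
  genes <- sprintf("g%02d", 1:40)
  de <- fake_de(genes, rep(1.5, 40))      # all log_fc equal: every null ties
  enr <- de_enrichment(genes[1:5], de, n_random = 10, seed = 1)
  expect_equal(enr$p_empirical, 1)
  # planted ordering forces the minimum attainable p = 1/11
  de2 <- fake_de(genes, c(rep(2, 5), rep(0, 35)))
  enr2 <- de_enrichment(genes[1:5], de2, n_random = 10, seed = 11)
  expect_equal(enr2$p_empirical, 1 / 11)
  expect_length(enr2$null_stats, 10)
  expect_gte(enr2$p_empirical, 1 / 11)
  expect_error(de_enrichment(genes[1:30], de, n_random = 10, seed = 1),
               "universe too small")
})

make_records <- function(n, chrom = "chr1", width = 1000, gap = 50000) {
  s <- (seq_len(n) - 1) * gap + 100000
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             state = "diagnosis-specific",
             loop_id = sprintf("L%02d", seq_len(n)),
             promoter_chrom = chrom, promoter_start = s - 90000,
             promoter_end = s - 89000,
             distal_chrom = chrom, distal_start = s, distal_end = s + width,
             log_fc = 2, de_call = "up",
             stringsAsFactors = FALSE)
}

test_that("silencer-loss permutation handles degenerate mark layouts", {
  rec <- make_records(5)
  sizes <- c(chr1 = 1e6)
  # marks far away from every distal anchor: observed 0, p = 1
  off <- intervals("chr1", 900000, 901000)
  t0 <- silencer_loss_test(rec, off, sizes, n_perm = 50, seed = 1)
  expect_equal(t0$observed_prop, 0)
  expect_equal(t0$p_value, 1)
  # marks covering the whole chromosome: saturation ties give p = 1
  all_mk <- intervals("chr1", 0, 1e6)
  t1 <- silencer_loss_test(rec, all_mk, sizes, n_perm = 50, seed = 1)
  expect_equal(t1$observed_prop, 1)
  expect_equal(t1$p_value, 1)
  # chromosome shorter than an anchor is an error
  expect_error(silencer_loss_test(rec, off, c(chr1 = 500), n_perm = 5,
                                  seed = 1),
               "shorter than an anchor")
})

test_that("marks placed exactly on the distal anchors force the minimum p", {
  rec <- make_records(8, gap = 120000)
  sizes <- c(chr1 = 1e6 + 8 * 120000)
  mk <- intervals(rec$distal_chrom, rec$distal_start, rec$distal_end)
  t <- silencer_loss_test(rec, mk, sizes, n_perm = 10000, seed = 3)
  expect_equal(t$observed_prop, 1)
  expect_equal(t$k_exceed, 0)
  expect_equal(t$p_value, 1 / 10001)
  expect_equal(t$p_value_trunc, 9.99e-5)
  # add-one bounds hold
  expect_gte(t$p_value, 1 / (t$n_perm + 1))
  expect_lte(t$p_value, 1)
})

test_that("truncation to three significant figures matches the printing convention", {
  expect_equal(trunc_signif(1 / 10001, 3), 9.99e-5)
  expect_equal(trunc_signif(0.123456, 3), 0.123)
  expect_equal(trunc_signif(0.9999, 3), 0.999)
  expect_equal(trunc_signif(0, 3), 0)
  expect_equal(trunc_signif(123456, 3), 123000)
})

test_that("integration records rebuild the anchor-peak-gene chain exactly", {
  # two diagnosis loops: L1 anchorA near g1 and carrying a peak;
  # L2 accessible but with no gene in range
  loops <- data.frame(
    chrom1 = "chr1", start1 = c(100000, 400000),
    end1 = c(105000, 405000),
    chrom2 = "chr1", start2 = c(300000, 700000),
    end2 = c(305000, 705000),
    loop_id = c("L1", "L2"), stringsAsFactors = FALSE)
  dl <- list(diagnosis_specific = c("L1", "L2"),
             relapse_specific = character(0))
  peaks <- intervals("chr1", c(101000, 401000), c(101500, 401500),
                     name = c("pk1", "pk2"))
  ann <- read_gene_annotation(
    write_tmp(c("chr1\t110000\t112000\tg1\tG1\t+",
                "chr1\t900000\t902000\tg2\tG2\t-")))
  de <- fake_de(c("g1", "g2"), c(2, 0))
  marks <- intervals("chr1", 302000, 303000)
  rec <- integration_records(dl, loops, "diagnosis", peaks, ann, de,
                             marks)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$gene_id, "g1")
  expect_equal(rec$promoter_start, 100000)
  expect_equal(rec$distal_start, 300000)   # the other end of L1
  expect_equal(rec$peak_ids[[1]], "pk1")
  expect_true(rec$repressive_overlap)
  expect_equal(rec$de_call, "up")
  # promoter and distal anchors always differ
  expect_false(any(rec$promoter_start == rec$distal_start &
                   rec$promoter_end == rec$distal_end))
})
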