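make_loop_file <- function(starts, strengths, chrom = "chr1",
                           ids = NULL) {
  df <- data.frame(chrom1 = chrom, start1 = starts,
                   end1 = starts + 1000, chrom2 = chrom,
                   start2 = starts + 100000,
                   end2 = starts + 101000,
                   strength = strengths,
                   loop_id = if (is.null(ids)) NA_character_ else ids,
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bedpe")
  df$loop_id[is.na(df$loop_id)] <-
    sprintf("%s:%d-%d|%s:%d-%d", df$chrom1, df$start1, df$end1,
            df$chrom2, df$start2, df$end2)[is.na(df$loop_id)]
  write_bedpe_loops(df, f)
  f
}

test_that("loop matrix is the union of loops with zero fill", {
  fA <- make_loop_file(c(0, 5000), c(1, 2), ids = c("L1", "L2"))
  fB <- make_loop_file(c(20000, 30000), c(3, 4), ids = c("L3", "L4"))
  lm <- build_loop_matrix(c(fA, fA, fB, fB),
                          c("diagnosis", "diagnosis",
                            "relapse", "relapse"))
  expect_equal(dim(lm$matrix), c(4, 4))
  expect_equal(unname(lm$matrix["L1", ]), c(1, 1, 0, 0))
  expect_equal(unname(lm$matrix["L4", ]), c(0, 0, 4, 4))
  # identical files give identical columns
  expect_identical(lm$matrix[, 1], lm$matrix[, 2])
})

test_that("loop matrix strengths equal their source file values", {
  set.seed(14)
  files <- lapply(1:4, function(i) {
    n <- 50
    make_loop_file(seq(0, by = 3000, length.out = n),
                   round(rlnorm(n), 6),
                   ids = sprintf("L%02d", 1:n))
  })
  grp <- rep(c("diagnosis", "relapse"), each = 2)
  lm <- build_loop_matrix(unlist(files), grp)
  for (j in 1:4) {
    src <- read_bedpe_loops(files[[j]])
    expect_equal(unname(lm$matrix[src$loop_id, j]), src$strength)
  }
})

test_that("an exact-null matrix yields zero significant loops", {
  set.seed(1)
  col <- rlnorm(200, log(10))
  m <- matrix(rep(col, 4), ncol = 4,
              dimnames = list(paste0("L", 1:200),
                              c("d1", "d2", "r1", "r2")))
  lm <- list(loops = NULL, matrix = m,
             group = setNames(rep(c("diagnosis", "relapse"), each = 2),
                              colnames(m)))
  dl <- call_differential_loops(lm, n_top = 1000)
  expect_length(dl$relapse_specific, 0)
  expect_length(dl$diagnosis_specific, 0)
})

test_that("swapping group labels negates log_fc and swaps the calls", {
  sim <- simulate_loop_strengths(2000, frac_diff = 0.1, seed = 5)
  lm1 <- list(matrix = sim$matrix, group = sim$group)
  lm2 <- list(matrix = sim$matrix,
              group = setNames(ifelse(sim$group == "diagnosis",
                                      "relapse", "diagnosis"),
                               names(sim$group)))
  dl1 <- call_differential_loops(lm1, n_top = 1e6)
  dl2 <- call_differential_loops(lm2, n_top = 1e6)
  expect_equal(dl1$results$log_fc, -dl2$results$log_fc)
  expect_setequal(dl1$relapse_specific, dl2$diagnosis_specific)
  expect_setequal(dl1$diagnosis_specific, dl2$relapse_specific)
  # sanity: specific sets partition the significant set
  expect_equal(length(dl1$relapse_specific) +
               length(dl1$diagnosis_specific),
               sum(dl1$results$p_adj < dl1$alpha))
})

test_that("planted differential loops are recovered with AUROC >= 0.9", {
  sim <- simulate_loop_strengths(20000, frac_diff = 0.05, effect = 2,
                                 noise_sd = 0.3, seed = 1337)
  lm <- list(matrix = sim$matrix, group = sim$group)
  dl <- call_differential_loops(lm, n_top = 1e5)
  planted <- names(sim$direction)[sim$direction != 0]
  lab <- dl$results$feature_id %in% planted
  expect_gte(auroc(-dl$results$p, lab), 0.9)
})

test_that("state anchors deduplicate exact coordinates", {
  loops <- data.frame(
    chrom1 = "chr1", start1 = c(0, 0), end1 = c(1000, 1000),
    chrom2 = "chr1", start2 = c(5000, 8000), end2 = c(6000, 9000),
    loop_id = c("L1", "L2"), stringsAsFactors = FALSE)
  dl <- list(diagnosis_specific = "L1", relapse_specific = c("L1", "L2"))
  expect_equal(nrow(state_anchors(dl, loops, "diagnosis")), 2)
  # two loops sharing an anchor give 3 unique anchors
  anc <- state_anchors(dl, loops, "relapse")
  expect_equal(nrow(anc), 3)
  expect_equal(nrow(unique(anc[, c("chrom", "start", "end")])), 3)
})
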