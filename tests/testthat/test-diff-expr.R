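null_counts <- function(n = 300, seed = 2) {
  set.seed(seed)
  col <- rpois(n, 60) + 1
  m <- matrix(rep(col, 4), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:n),
                              c("d1", "d2", "r1", "r2")))
  m
}

grp <- rep(c("diagnosis", "relapse"), each = 2)

test_that("identical columns produce zero DE genes", {
  de <- differential_expression(null_counts(), grp)
  expect_length(de$upregulated, 0)
  expect_length(de$downregulated, 0)
  expect_true(all(de$results$log_fc == 0))
})

test_that("swapping group labels maps up to down exactly", {
  mu <- setNames(pmax(exp(rnorm(2000, log(100), 1)), 2),
                 sprintf("g%04d", 1:2000))
  lfc <- c(rep(2, 30), rep(-2, 30), rep(0, 1940))
  gc <- simulate_gene_counts(mu, lfc, seed = 77)
  de1 <- differential_expression(gc$matrix, unname(gc$group))
  de2 <- differential_expression(gc$matrix,
                                 ifelse(gc$group == "diagnosis",
                                        "relapse", "diagnosis"))
  expect_setequal(de1$upregulated, de2$downregulated)
  expect_setequal(de1$downregulated, de2$upregulated)
})

test_that("result ordering is deterministic (p, then gene id)", {
  de <- differential_expression(null_counts(), grp)
  r <- de$results
  expect_false(is.unsorted(r$p))
  same_p <- split(r$feature_id, r$p)
  expect_true(all(vapply(same_p, function(x) !is.unsorted(x),
                         logical(1))))
})

test_that("planted DE genes are recovered with recall >= 0.5 and FDR <= 0.25", {
  n <- 10000; n_de <- 200
  mu <- with(list(), {
    set.seed(21)
    setNames(pmax(exp(rnorm(n, log(100), 1)), 2), sprintf("g%05d", 1:n))
  })
  lfc <- rep(0, n)
  lfc[seq_len(n_de)] <- rep(c(2, -2), length.out = n_de)
  gc <- simulate_gene_counts(mu, lfc, dispersion = 0.1, seed = 21)
  de <- differential_expression(gc$matrix, unname(gc$group))
  truth <- names(mu)[seq_len(n_de)]
  calls <- c(de$upregulated, de$downregulated)
  expect_gte(mean(truth %in% calls), 0.5)
  expect_lte(mean(!(calls %in% truth)), 0.25)
  # recovered genes carry the planted direction
  expect_true(all(intersect(de$upregulated, truth) %in%
                  names(mu)[lfc > 0]))
  expect_true(all(intersect(de$downregulated, truth) %in%
                  names(mu)[lfc < 0]))
})

test_that("moderated p-values track the reference voom pipeline", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  mu <- setNames(pmax(exp(rnorm(3000, log(100), 1)), 2),
                 sprintf("g%04d", 1:3000))
  lfc <- c(rep(2, 50), rep(-2, 50), rep(0, 2900))
  gc <- simulate_gene_counts(mu, lfc, seed = 55)
  de <- differential_expression(gc$matrix, unname(gc$group))
  d <- edgeR::DGEList(gc$matrix)
  d <- edgeR::calcNormFactors(d)
  design <- model.matrix(~factor(gc$group,
                                 levels = c("diagnosis", "relapse")))
  v <- limma::voom(d, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  common <- intersect(de$results$feature_id, rownames(tt))
  ord <- match(common, de$results$feature_id)
  expect_gt(cor(de$results$log_fc[ord], tt[common, "logFC"]), 0.99)
  expect_gt(cor(rank(de$results$p[ord]), rank(tt[common, "P.Value"])),
            0.95)
})
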