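test_that("TMM factors are 1 for identical or purely depth-scaled samples", {
  m <- matrix(rep(c(5, 10, 20, 40), 3), ncol = 3,
              dimnames = list(letters[1:4], c("a", "b", "c")))
  f <- tmm_factors(m)
  expect_equal(unname(f$tmm_factor), rep(1, 3))
  # doubling a whole column is a library-size effect, not composition
  m2 <- cbind(A = c(5, 10, 20, 40), B = 2 * c(5, 10, 20, 40))
  rownames(m2) <- letters[1:4]
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2$tmm_factor), c(1, 1))
  expect_equal(unname(f2$lib_size), c(75, 150))
})

test_that("TMM is insensitive to scaling any single sample", {
  # M-values, A-values and the trimming are exactly scale-invariant;
  # only the inverse-variance weights feel the depth, so factors can
  # move in the third decimal (the published estimator behaves the
  # same way)
  set.seed(3)
  m <- matrix(rpois(4000, 50), ncol = 4)
  rownames(m) <- paste0("f", 1:1000)
  base <- tmm_factors(m)$tmm_factor
  for (j in 1:4) {
    m2 <- m
    m2[, j] <- m2[, j] * 7.3
    expect_equal(unname(tmm_factors(m2)$tmm_factor), unname(base),
                 tolerance = 0.02)
  }
})

test_that("TMM factors match the reference implementation on a composition-biased matrix", {
  skip_if_not_installed("edgeR")
  set.seed(99)
  n <- 5000
  m <- matrix(rpois(n * 4, lambda = rep(rgamma(n, 2, scale = 30), 4)),
              ncol = 4)
  infl <- sample.int(n, n %/% 10)
  m[infl, 2] <- m[infl, 2] * 8          # 10% of features inflated 8x
  rownames(m) <- paste0("f", 1:n)
  got <- tmm_factors(m)$tmm_factor
  want <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("log_cpm implements log2 counts-per-million with a prior", {
  m <- matrix(c(2^20 * 0.25, 2^20 * 0.75), ncol = 1,
              dimnames = list(c("a", "b"), "s"))
  m <- m / sum(m) * 1e6                 # library size exactly 1e6
  norm <- list(lib_size = colSums(m), tmm_factor = c(s = 1))
  expect_equal(unname(log_cpm(m, norm, prior = 0)[, 1]),
               unname(log2(m[, 1])))
  # prior keeps zeros finite
  mz <- matrix(c(0, 10), ncol = 1, dimnames = list(c("a", "b"), "s"))
  expect_true(all(is.finite(log_cpm(mz))))
  # monotone in the count
  m1 <- matrix(c(5, 10), ncol = 1, dimnames = list(c("a", "b"), "s"))
  m2 <- m1; m2[1, 1] <- 6
  expect_gt(log_cpm(m2, norm)[1, 1], log_cpm(m1, norm)[1, 1])
})

test_that("top_variable picks the largest sample SDs, stably", {
  m <- rbind(a = c(0, 6), b = c(0, 4), c = c(0, 2))  # SDs ~ (4.2, 2.8, 1.4)
  expect_equal(top_variable(m, 2), c("a", "b"))
  expect_equal(top_variable(m, 10), c("a", "b", "c"))
  # ties broken by input order
  tie <- rbind(x = c(0, 2), y = c(5, 7), z = c(0, 4))
  expect_equal(top_variable(tie, 2), c("x", "z"))
  # random matrix vs full sort oracle
  set.seed(21)
  r <- matrix(rnorm(500 * 6), 500)
  rownames(r) <- paste0("f", 1:500)
  sds <- apply(r, 1, sd)
  want <- rownames(r)[sort(order(-sds)[1:50])]
  expect_equal(top_variable(r, 50), want)
})

test_that("two-group fit equals the OLS oracle", {
  logm <- rbind(f1 = c(1, 1, 3, 3))
  grp <- c("diagnosis", "diagnosis", "relapse", "relapse")
  fit <- fit_two_group(logm, grp)
  expect_equal(unname(fit$log_fc), 2)
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df_resid, 2)
  # equal group means give zero log_fc
  fit0 <- fit_two_group(rbind(f1 = c(2, 4, 1, 5)), grp)
  expect_equal(unname(fit0$log_fc), 0)
  # random rows against lm()
  set.seed(8)
  r <- matrix(rnorm(50 * 4), 50, dimnames = list(paste0("f", 1:50), NULL))
  fit <- fit_two_group(r, grp)
  for (i in c(1, 17, 50)) {
    ols <- lm(r[i, ] ~ factor(grp, levels = c("diagnosis", "relapse")))
    expect_equal(unname(fit$log_fc[i]), unname(coef(ols)[2]))
    expect_equal(unname(fit$s2[i]), summary(ols)$sigma^2)
  }
  expect_error(fit_two_group(r[, 1:3], grp[1:3]), "2 samples")
})

test_that("variance shrinkage degenerates correctly at the edges", {
  # identical variances: no spread in log s2, so d0 = Inf
  eb <- ebayes_shrink(rep(0.5, 30), df_resid = 2)
  expect_equal(eb$d0, Inf)
  expect_equal(eb$s2_post, rep(0.5, 30))
  # all-zero variances instruct the caller to floor them
  expect_error(ebayes_shrink(rep(0, 20), 2), "floor")
  # d0 = 0 recovers the unmoderated variances (ordinary t)
  set.seed(2)
  s2 <- rchisq(100, 2) / 2
  eb0 <- ebayes_shrink(s2, 2, d0 = 0)
  expect_equal(eb0$s2_post, s2)
  # posterior variance is a convex combination of s2 and s0_sq
  eb <- ebayes_shrink(s2, 2)
  lo <- pmin(s2, eb$s0_sq); hi <- pmax(s2, eb$s0_sq)
  ok <- s2 == eb$s0_sq | (eb$s2_post > lo & eb$s2_post < hi)
  expect_true(all(ok))
})

test_that("the scaled-F prior fit recovers planted hyperparameters", {
  set.seed(31)
  d0 <- 4; s0 <- 0.25; df <- 2; n <- 20000
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  fit <- fit_f_dist(s2, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.20)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.10)
})

test_that("shrinkage agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  s2 <- rchisq(500, 3) / 3 * exp(rnorm(500, 0, 0.8))
  got <- ebayes_shrink(s2, df_resid = 4)
  want <- limma::squeezeVar(s2, df = 4)
  expect_equal(got$d0, want$df.prior, tolerance = 1e-8)
  expect_equal(got$s0_sq, want$var.prior, tolerance = 1e-8)
  expect_equal(got$s2_post, want$var.post, tolerance = 1e-8)
})

test_that("BH adjustment matches hand examples, the oracle, and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(200)^2
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # rank preserved
  }
})

test_that("moderated test keeps exact nulls at p = 1", {
  m <- matrix(rep(c(1, 5, 9), 4), ncol = 4,
              dimnames = list(c("a", "b", "c"), NULL))
  res <- moderated_test(log_cpm(m), rep(c("diagnosis", "relapse"),
                                        each = 2))
  expect_equal(res$log_fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})
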