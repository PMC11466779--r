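# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own overlap/statistics code paths.

# O(n*m) double-loop interval overlap
brute_overlap <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    w <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (w >= min_bp) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer()))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2])
}

# textbook BH: p_adj(i) = min_{j >= i, sorted} m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), L = 1e5,
                             wmax = 500) {
  s <- floor(runif(n, 0, L - wmax - 1))
  w <- 1 + floor(runif(n, 0, wmax))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w, stringsAsFactors = FALSE)
}

# rank-based AUROC of a score against a logical label
auroc <- function(score, label) {
  r <- rank(score)
  np <- sum(label); nn <- sum(!label)
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

pair_key <- function(df) paste(df$a, df$b, sep = ":")

write_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small simulation config for fast end-to-end tests
small_sim_config <- function(seed = 1337, ...) {
  sim_config(n_loops = 4000, n_genes = 1200, n_de_genes = 60,
             frac_silencer_loss_genes = 0.2, seed = seed, ...)
}
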