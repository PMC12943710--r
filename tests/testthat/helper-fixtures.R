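# shared fixtures and independent oracles used across test files

tiny_table <- function() {
  otu_table(matrix(c(5L, 0L, 3L,
                     1L, 2L, 0L), nrow = 3,
                   dimnames = list(c("t1", "t2", "t3"), c("s1", "s2"))),
            "bacteria")
}

random_table <- function(n_taxa, n_samples, seed, depth = 200,
                         kingdom = "bacteria", prefix = "t") {
  set.seed(seed)
  cnt <- sapply(seq_len(n_samples), function(j)
    as.integer(rmultinom(1, depth, rexp(n_taxa))))
  dimnames(cnt) <- list(paste0(prefix, seq_len(n_taxa)),
                        paste0("s", seq_len(n_samples)))
  otu_table(cnt, kingdom)
}

# brute-force beta-MNTD: nested loops over taxa, no vectorization
bmntd_oracle <- function(table, tree) {
  cnt <- table$counts
  D <- ape::cophenetic.phylo(tree)[rownames(cnt), rownames(cnt)]
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  n <- ncol(cnt)
  out <- matrix(0, n, n, dimnames = list(colnames(cnt), colnames(cnt)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ta <- which(rel[, a] > 0); tb <- which(rel[, b] > 0)
    sab <- 0
    for (i in ta) {
      best <- Inf
      for (j in tb) best <- min(best, D[i, j])
      sab <- sab + rel[i, a] * best
    }
    sba <- 0
    for (j in tb) {
      best <- Inf
      for (i in ta) best <- min(best, D[j, i])
      sba <- sba + rel[j, b] * best
    }
    out[a, b] <- 0.5 * (sab + sba)
  }
  out
}

# natural connectivity via truncated series of tr(exp(A)) = sum tr(A^k)/k!
nat_conn_series <- function(adj, k_max = 60) {
  n <- nrow(adj)
  acc <- diag(n)
  tr <- n
  pw <- diag(n)
  for (k in seq_len(k_max)) {
    pw <- pw %*% adj
    tr <- tr + sum(diag(pw)) / factorial(k)
  }
  log(tr / n)
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
wilcox_enum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
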