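test_that("beta-MNTD matches hand values and the nested-loop oracle", {
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  tab <- otu_table(matrix(c(10L, 0L, 0L, 10L), 2,
                          dimnames = list(c("t1", "t2"), c("A", "B"))),
                   "bacteria")
  expect_equal(beta_mntd(tab, tree)["A", "B"], 2)

  dup <- otu_table(matrix(c(3L, 7L, 3L, 7L), 2,
                          dimnames = list(c("t1", "t2"), c("A", "B"))),
                   "bacteria")
  expect_equal(beta_mntd(dup, tree)["A", "B"], 0)

  for (sd in 1:4) {
    tree <- generate_phylogeny(6, seed = sd)
    tab <- random_table(6, 4, seed = sd, depth = 40)
    expect_equal(beta_mntd(tab, tree), bmntd_oracle(tab, tree),
                 tolerance = 1e-10)
  }
})

test_that("beta-MNTD agrees with picante::comdistnt", {
  tree <- generate_phylogeny(12, seed = 3)
  tab <- random_table(12, 5, seed = 3, depth = 100)
  mine <- beta_mntd(tab, tree)
  ref <- as.matrix(picante::comdistnt(t(tab$counts), ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI flags degenerate pairs and matches the exhaustive null", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:2):1);")
  same <- otu_table(matrix(c(5L, 5L, 0L, 1L, 5L, 5L, 0L, 1L), 4,
                           dimnames = list(paste0("t", 1:4), c("A", "B"))),
                    "bacteria")
  r <- beta_nti(same, tree, n_null = 99, seed = 1)
  expect_true(r$degenerate["A", "B"])
  expect_equal(r$bnti["A", "B"], 0)

  tab <- otu_table(matrix(c(6L, 1L, 0L, 0L, 0L, 0L, 4L, 3L), 4,
                          dimnames = list(paste0("t", 1:4), c("A", "B"))),
                   "bacteria")
  # exhaustive null over all 4! tip relabelings
  D <- ape::cophenetic.phylo(tree)[paste0("t", 1:4), paste0("t", 1:4)]
  rel <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  perms <- rbind(1:4)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  vals <- apply(perms, 1, function(p)
    rhizonet:::bmntd_all_pairs(D[p, p], rel)["A", "B"])
  z_exact <- (rhizonet:::bmntd_all_pairs(D, rel)["A", "B"] - mean(vals)) /
    sd(vals)
  z_mc <- beta_nti(tab, tree, n_null = 999, seed = 4)$bnti["A", "B"]
  expect_equal(z_mc, z_exact, tolerance = 0.25)  # Monte-Carlo error at 999
  expect_error(beta_nti(tab, tree, n_null = 50), "99")
})

test_that("betaNTI null is exchangeable under tip relabeling of the data", {
  tree <- generate_phylogeny(20, seed = 5)
  tab <- random_table(20, 4, seed = 5, depth = 150)
  base <- beta_nti(tab, tree, n_null = 199, seed = 7)$bnti
  perm <- sample(20)
  tab2 <- otu_table({
    m <- tab$counts
    rownames(m) <- rownames(m)[perm]
    m[order(rownames(m)), , drop = FALSE]
  }, "bacteria")
  relab <- beta_nti(tab2, tree, n_null = 199, seed = 7)$bnti
  # same null family: distributions of z-scores should be comparable in scale
  expect_lt(abs(mean(abs(base)) - mean(abs(relab))), 1.5)
})

test_that("Raup-Crick detects identical communities and stays bounded", {
  set.seed(10)
  cnt <- matrix(rpois(80, 8) + 1L, 20, 4,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:4)))
  cnt[, 2] <- cnt[, 1]  # identical rich pair
  tab <- otu_table(cnt, "bacteria")
  rc <- raup_crick_bray(tab, n_null = 199, seed = 2)
  expect_lt(abs(rc["s1", "s2"] - (-1)), 0.05)
  for (sd in 1:5) {
    tab <- random_table(10, 4, seed = sd, depth = 50)
    rc <- raup_crick_bray(tab, n_null = 99, seed = sd)
    expect_true(all(rc >= -1 & rc <= 1))
    expect_true(isSymmetric(rc))
  }
})

test_that("the five-process partition is total with the published cut-offs", {
  b <- matrix(c(0, 3, 3, 0), 2); r <- matrix(0, 2, 2)
  expect_equal(partition_processes(b, r)$labels[1, 2],
               "heterogeneous selection")
  b <- matrix(c(0, -3, -3, 0), 2)
  expect_equal(partition_processes(b, r)$labels[1, 2],
               "homogeneous selection")
  b <- matrix(0, 2, 2); r <- matrix(c(0, 0.99, 0.99, 0), 2)
  expect_equal(partition_processes(b, r)$labels[1, 2],
               "dispersal limitation")
  r <- matrix(c(0, -0.99, -0.99, 0), 2)
  expect_equal(partition_processes(b, r)$labels[1, 2],
               "homogenizing dispersal")
  r <- matrix(0, 2, 2)
  expect_equal(partition_processes(b, r)$labels[1, 2], "drift/undominated")

  set.seed(3)
  n <- 8
  b <- matrix(rnorm(n * n, sd = 3), n); b <- b + t(b); diag(b) <- 0
  r <- matrix(runif(n * n, -1, 1), n); r <- (r + t(r)) / 2; diag(r) <- 0
  pp <- partition_processes(b, r, groups = rep(c("P", "M"), each = 4))
  expect_true(all(!is.na(pp$labels[upper.tri(pp$labels)])))
  expect_equal(sum(pp$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(pp$group_fractions$P), 1, tolerance = 1e-9)
})

test_that("MST is the symmetric min/max ratio of observed and null distance", {
  tab <- random_table(15, 6, seed = 6, depth = 120)
  grp <- rep(c("A", "B"), each = 3)
  st <- rhizonet:::null_bray_stats(tab, 99, 11)
  m <- mst(tab, grp, n_null = 99, seed = 11)
  idx <- which(grp == "A")
  ratio <- pmin(st$obs, st$mean_null) / pmax(st$obs, st$mean_null)
  expect_equal(unname(m["A"]),
               mean(ratio[idx, idx][upper.tri(diag(3))]), tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))
  # arithmetic of the ratio: 0.9 vs 0.45 halves
  expect_equal(min(0.9, 0.45) / max(0.9, 0.45), 0.5)
})

test_that("Sloan NCM saturates for abundant taxa and prefers neutral data", {
  mc <- generate_metacommunity(100, seed = 2, sdlog = 1.5)
  tab <- simulate_neutral_communities(mc, 24, 2000, m = 0.5, seed = 3)
  fit <- fit_ncm(tab)
  expect_true(all(fit$taxa$freq_pred[fit$taxa$mean_rel_abund > 0.02] > 0.999))
  expect_true(fit$m > 0 && fit$m <= 1)
  expect_identical(fit_ncm(tab)$m, fit$m)  # deterministic

  tree <- generate_phylogeny(100, seed = 2)
  names(mc) <- tree$tip.label
  filt <- simulate_filtered_communities(mc, tree,
                                        env = rep(c(-2, 2), each = 12),
                                        s = 8, n_reads = 2000, seed = 3)
  expect_gt(fit$r_squared, fit_ncm(filt)$r_squared)
})
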