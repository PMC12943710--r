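test_that("random phylogenies are reproducible with the right shape", {
  t2 <- generate_phylogeny(2, seed = 5)
  expect_equal(length(t2$tip.label), 2)
  a <- generate_phylogeny(50, seed = 1)
  b <- generate_phylogeny(50, seed = 1)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_equal(length(a$tip.label), 50)
  expect_equal(a$Nnode, 49)  # bifurcating rooted: n - 1 internal splits
  expect_true(all(a$edge.length >= 0))
  expect_error(generate_phylogeny(1, seed = 1), "n_taxa")
})

test_that("metacommunity abundances are a normalized rank-abundance curve", {
  mc <- generate_metacommunity(200, seed = 3)
  expect_equal(sum(mc), 1, tolerance = 1e-12)
  expect_true(all(mc > 0))
  expect_true(all(diff(sort(mc, decreasing = TRUE)) <= 0))
})

test_that("neutral simulation at m = 1 reproduces the metacommunity", {
  mc <- generate_metacommunity(50, seed = 2, sdlog = 1)
  tab <- simulate_neutral_communities(mc, n_samples = 40, n_reads = 2000,
                                      m = 1, seed = 9)
  expect_true(all(colSums(tab$counts) == 2000))
  obs <- rowMeans(relative_abundance(tab))
  se <- sqrt(mc * (1 - mc) / (2000 * 40))
  expect_true(all(abs(obs - mc) < 6 * se + 1e-4))
  again <- simulate_neutral_communities(mc, 40, 2000, m = 1, seed = 9)
  expect_identical(tab$counts, again$counts)
})

test_that("drift under low migration raises between-sample divergence", {
  mc <- generate_metacommunity(80, seed = 4, sdlog = 1.5)
  lo <- simulate_neutral_communities(mc, 10, 1000, m = 0.05, seed = 3)
  hi <- simulate_neutral_communities(mc, 10, 1000, m = 1, seed = 3)
  mean_bc <- function(t) mean(bray_curtis(t)[upper.tri(diag(10))])
  expect_gt(mean_bc(lo), mean_bc(hi))
})

test_that("filtered simulation reduces to neutral at s = 0 and evolves
           phylogenetically conserved traits", {
  tree <- generate_phylogeny(40, seed = 6)
  mc <- generate_metacommunity(40, seed = 6, sdlog = 1)
  tab <- simulate_filtered_communities(mc, tree, env = rep(0, 20), s = 0,
                                       n_reads = 1500, seed = 11)
  obs <- rowMeans(relative_abundance(tab))
  mcv <- mc / sum(mc)
  se <- sqrt(mcv * (1 - mcv) / (1500 * 20))
  expect_true(all(abs(obs[tree$tip.label] - mcv) < 6 * se + 1e-3))

  # closer tips have more similar traits (Mantel-style rank correlation)
  sig <- sapply(1:3, function(sd) {
    tr <- generate_phylogeny(60, seed = sd)
    tt <- simulate_filtered_communities(generate_metacommunity(60, sd),
                                        tr, env = 0, s = 0, n_reads = 500,
                                        seed = sd)
    trait <- attr(tt, "traits")
    td <- as.matrix(dist(trait[tr$tip.label]))
    pd <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
    ut <- upper.tri(td)
    cor(td[ut], pd[ut], method = "spearman")
  })
  expect_true(mean(sig) > 0.2)
})

test_that("selection toward contrasting optima separates groups in betaNTI", {
  tree <- generate_phylogeny(60, seed = 8)
  mc <- generate_metacommunity(60, seed = 8, sdlog = 1)
  env <- rep(c(-1.5, 1.5), each = 5)
  tab <- simulate_filtered_communities(mc, tree, env = env, s = 5,
                                       n_reads = 2000, seed = 13)
  bn <- beta_nti(tab, tree, n_null = 99, seed = 5)$bnti
  same <- outer(env, env, "==")
  ut <- upper.tri(bn)
  expect_gt(mean(abs(bn[ut & !same])), mean(abs(bn[ut & same])))
})

test_that("soil generator recovers declared shifts and correlations", {
  design <- data.frame(sample_id = paste0("s", 1:24),
                       stand_type = rep(c("P", "M"), each = 12),
                       stand_age = rep(c(20, 31, 20, 31), each = 6),
                       plot = paste0("p", 1:24))
  flat <- generate_soil_properties(design, effects = numeric(0),
                                   noise_sd = 0, seed = 1)
  for (v in c("pH", "SOC", "TN"))
    expect_equal(var(flat[[v]]), 0)

  shift_err <- sapply(1:5, function(sd) {
    m <- generate_soil_properties(design, effects = c(SOC = 1), seed = sd)
    z <- (m$SOC - mean(m$SOC)) / sd(m$SOC)
    (mean(z[m$stand_type == "M"]) - mean(z[m$stand_type == "P"])) - 1
  })
  expect_true(all(abs(shift_err) < 0.45))
  expect_lt(abs(mean(shift_err)), 0.3)

  cors <- sapply(1:5, function(sd) {
    m <- generate_soil_properties(design, seed = sd, rho = 0.3)
    cor(m$SOC, m$TN)
  })
  expect_lt(abs(mean(cors) - 0.3), 0.15)
})

test_that("a full synthetic study is reproducible and joined", {
  spec <- simulation_spec(n_taxa = c(bacteria = 40, fungi = 30),
                          n_reads = 500, seed = 21)
  st <- generate_study(spec)
  expect_equal(ncol(st$bacteria$counts), 24)
  expect_equal(ncol(st$fungi$counts), 24)
  expect_identical(colnames(st$bacteria$counts), st$meta$sample_id)
  expect_setequal(rownames(st$bacteria$counts), st$tree_bacteria$tip.label)
  st2 <- generate_study(spec)
  expect_identical(st$bacteria$counts, st2$bacteria$counts)
  expect_identical(st$fungi$counts, st2$fungi$counts)
  expect_identical(st$meta, st2$meta)
  expect_identical(ape::write.tree(st$tree_fungi),
                   ape::write.tree(st2$tree_fungi))
})
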