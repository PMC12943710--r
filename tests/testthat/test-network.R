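test_that("correlation screen is rank-invariant and honours its thresholds", {
  set.seed(4)
  n <- 16
  x <- sample(10:500, n)  # distinct values: t2 is strictly monotone in t1
  t1 <- x; t2 <- as.integer(round(x^1.5)); t3 <- rpois(n, 60) + 1L
  t4 <- 20000L - t1 - t2 - t3  # filler keeps depths equal across samples
  cnt <- matrix(as.integer(rbind(t1, t2, t3, t4)), nrow = 4,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:n)))
  tab <- otu_table(cnt, "bacteria")
  ed <- correlation_screen(tab, prevalence_min = 0, r_min = 0.9,
                           q_max = 0.05)
  # t2 is a strictly increasing transform of t1: Spearman rho = 1
  pair <- ed[(ed$from == "t1" & ed$to == "t2") |
               (ed$from == "t2" & ed$to == "t1"), ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$rho, 1, tolerance = 1e-10)

  expect_error(correlation_screen(tab, r_min = 1.01),
               NA)  # r_min > 1 simply yields no edges
  expect_equal(nrow(correlation_screen(tab, prevalence_min = 0,
                                       r_min = 1.01, q_max = 0.05)), 0)
  expect_error(correlation_screen(subset_samples(tab, paste0("s", 1:4)),
                                  r_min = 0.6), ">= 5 samples")
})

test_that("topology matches hand-enumerated graphs", {
  tri2 <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                     to = c("b", "c", "a", "y", "z", "x"),
                     rho = rep(0.9, 6), p = rep(1e-6, 6), q = rep(1e-5, 6),
                     sign = rep("positive", 6))
  attr(tri2, "taxa") <- setNames(rep("bacteria", 6),
                                 c("a", "b", "c", "x", "y", "z"))
  net <- build_network(tri2)
  # two disconnected triangles, modules = the triangles: Q = 2(0.5 - 0.25)
  expect_equal(net$topology$modularity, 0.5, tolerance = 1e-10)
  expect_equal(net$topology$clustering_coefficient, 1)
  expect_equal(net$topology$positive_edge_fraction, 1)
  expect_equal(net$topology$average_degree, 2)

  path3 <- data.frame(from = c("a", "b"), to = c("b", "c"),
                      rho = c(0.8, -0.7), p = c(1e-5, 1e-5),
                      q = c(1e-4, 1e-4), sign = c("positive", "negative"))
  attr(path3, "taxa") <- setNames(rep("fungi", 3), c("a", "b", "c"))
  net3 <- build_network(path3)
  expect_equal(net3$topology$average_path_length, 4 / 3)
  expect_equal(net3$topology$positive_edge_fraction, 0.5)

  empty <- tri2[0, ]
  expect_true(build_network(empty)$topology$empty)
})

test_that("graph metrics are invariant to node relabeling", {
  set.seed(6)
  ids <- paste0("t", 1:12)
  pairs <- t(combn(ids, 2))
  keep <- sample(nrow(pairs), 20)
  ed <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                   rho = runif(20, 0.6, 0.95) * sample(c(-1, 1), 20, TRUE),
                   p = 1e-5, q = 1e-4)
  ed$sign <- ifelse(ed$rho > 0, "positive", "negative")
  attr(ed, "taxa") <- setNames(rep("bacteria", 12), ids)
  relabel <- setNames(sample(ids), ids)
  ed2 <- data.frame(from = unname(relabel[ed$from]),
                    to = unname(relabel[ed$to]),
                    rho = ed$rho, p = ed$p, q = ed$q, sign = ed$sign)
  attr(ed2, "taxa") <- setNames(rep("bacteria", 12), unname(relabel[ids]))
  t1 <- build_network(ed)$topology
  t2 <- build_network(ed2)$topology
  for (k in c("n_nodes", "n_edges", "average_degree", "average_path_length",
              "clustering_coefficient", "positive_edge_fraction"))
    expect_equal(t1[[k]], t2[[k]])
})

test_that("cohesion weights connectedness by relative abundance", {
  cnt <- matrix(c(50L, 30L, 20L, 10L, 60L, 30L), 3,
                dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tab <- otu_table(cnt, "bacteria")
  ed <- data.frame(from = c("t1", "t1"), to = c("t2", "t3"),
                   rho = c(0.3, 0.1), p = 1e-5, q = 1e-4,
                   sign = "positive")
  co <- cohesion(tab, ed)
  conn <- c(t1 = 0.2, t2 = 0.3, t3 = 0.1)
  rel <- relative_abundance(tab)
  expect_equal(co$cohesion_pos, as.numeric(crossprod(rel, conn)),
               tolerance = 1e-12)
  expect_equal(co$cohesion_neg, c(0, 0))
  ed$rho <- -ed$rho; ed$sign <- "negative"
  co2 <- cohesion(tab, ed)
  expect_true(all(co2$cohesion_neg <= 0) && all(co2$cohesion_pos >= 0))
})

test_that("natural connectivity matches spectra and the series oracle", {
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(rhizonet:::nat_conn_adj(matrix(0, 5, 5)), 0)
  k3 <- igraph::make_full_graph(3)
  adj3 <- as.matrix(igraph::as_adjacency_matrix(k3, sparse = FALSE))
  expect_equal(rhizonet:::nat_conn_adj(adj3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:3) {
    g <- igraph::sample_gnp(20, 0.25)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    expect_equal(rhizonet:::nat_conn_adj(adj), nat_conn_series(adj),
                 tolerance = 1e-8)
  }

  # removing an edge never increases natural connectivity
  g <- igraph::sample_gnp(15, 0.3)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  base <- rhizonet:::nat_conn_adj(adj)
  ij <- which(adj == 1, arr.ind = TRUE)[1, ]
  adj2 <- adj; adj2[ij[1], ij[2]] <- adj2[ij[2], ij[1]] <- 0
  expect_lte(rhizonet:::nat_conn_adj(adj2), base + 1e-12)

  gfix <- igraph::sample_gnp(15, 0.4)
  adjfix <- as.matrix(igraph::as_adjacency_matrix(gfix, sparse = FALSE))
  curve <- natural_connectivity(gfix, "degree", steps = 5)
  expect_equal(curve$fraction_removed[1], 0)
  # curve starts at the intact-network value and decreases overall
  expect_equal(curve$natural_connectivity[1],
               rhizonet:::nat_conn_adj(adjfix), tolerance = 1e-10)
  expect_lt(curve$natural_connectivity[nrow(curve)],
            curve$natural_connectivity[1])
})

test_that("Zi-Pi follows the Guimera-Amaral definitions", {
  ed <- data.frame(
    from = c("a", "a", "a", "a", "b", "c", "x", "y"),
    to   = c("b", "c", "x", "y", "c", "d", "y", "z"),
    rho = 0.8, p = 1e-5, q = 1e-4, sign = "positive")
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  modules <- c(a = 1, b = 1, c = 1, d = 1, x = 2, y = 2, z = 2)
  zp <- zi_pi(g, modules)
  zp <- zp[match(names(modules), zp$taxon_id), ]
  # node a: degree 4, edges split 2/2 across the two modules
  expect_equal(zp$pi[zp$taxon_id == "a"], 0.5)
  # node d: all edges inside its own module
  expect_equal(zp$pi[zp$taxon_id == "d"], 0)
  # module 1 within-degrees are (a=2, b=2, c=3, d=1), mean 2: Zi(a) = 0
  expect_equal(zp$zi[zp$taxon_id == "a"], 0)
  expect_true(all(zp$role %in% c("module hub", "connector", "network hub",
                                 "peripheral")))
  iso_g <- igraph::add_vertices(g, 1, name = "lonely")
  zp2 <- zi_pi(iso_g, c(modules, lonely = 3))
  expect_true(zp2$isolated[zp2$taxon_id == "lonely"])
  expect_equal(zp2$pi[zp2$taxon_id == "lonely"], 0)
})
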