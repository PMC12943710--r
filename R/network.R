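#' Screen taxon pairs for significant co-occurrence
#'
#' Taxa are filtered to a minimum prevalence, Spearman rank correlations
#' are computed on relative abundances for all retained pairs (within- and
#' cross-kingdom), p-values come from the t approximation, and pairs are
#' kept when `|rho| >= r_min` and the Benjamini-Hochberg adjusted
#' `q <= q_max`.
#'
#' @param table a merged cross-kingdom [otu_table] (see [merge_kingdoms])
#'   with >= 5 samples.
#' @param prevalence_min minimum fraction of samples a taxon must occupy.
#' @param r_min minimum absolute Spearman correlation.
#' @param q_max Benjamini-Hochberg FDR level.
#' @return data.frame of retained edges: `from`, `to`, `rho`, `p`, `q`,
#'   `sign`; attribute `"taxa"` holds the retained taxon ids (with their
#'   kingdoms) so isolated nodes can be accounted for.
#' @export
correlation_screen <- function(table, prevalence_min = 1/3, r_min = 0.6,
                               q_max = 0.05) {
  cnt <- table$counts
  n <- ncol(cnt)
  if (n < 5) stop("need >= 5 samples")
  keep <- rowMeans(cnt > 0) >= prevalence_min
  if (sum(keep) < 2) stop("fewer than 2 taxa pass the prevalence filter")
  rel <- sweep(cnt[keep, , drop = FALSE], 2, colSums(cnt), "/")
  rho <- suppressWarnings(cor(t(rel), method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  pmat <- 2 * pt(-abs(tstat), df = n - 2)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = rownames(rho)[ut[, 1]],
                      to = rownames(rho)[ut[, 2]],
                      rho = rho[ut], p = pmat[ut])
  edges <- edges[is.finite(edges$rho), , drop = FALSE]
  edges$q <- p.adjust(edges$p, method = "BH")
  edges <- edges[abs(edges$rho) >= r_min & edges$q <= q_max, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  rownames(edges) <- NULL
  attr(edges, "taxa") <- table$kingdom[keep]
  edges
}

#' Build a signed co-occurrence network and its topology summary
#'
#' Undirected signed weighted graph from a screened edge list. Average
#' path length and diameter are computed on the largest connected
#' component; modularity uses greedy agglomeration
#' ([igraph::cluster_fast_greedy]) on the unsigned weighted graph.
#'
#' @param edges edge data.frame from [correlation_screen].
#' @param kingdom optional named kingdom vector for the nodes (defaults to
#'   the `"taxa"` attribute of `edges`).
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph, edge attributes `rho`, `q`, `sign`, `weight = |rho|`),
#'   `nodes` (data.frame with kingdom, module, degree), `edges`, and
#'   `topology` (n_nodes, n_edges, average_degree, average_path_length,
#'   clustering_coefficient, modularity, positive_edge_fraction).
#' @export
build_network <- function(edges, kingdom = NULL) {
  kingdom <- kingdom %||% attr(edges, "taxa")
  if (nrow(edges) == 0) {
    return(structure(list(graph = igraph::make_empty_graph(0,
                                                           directed = FALSE),
                          nodes = data.frame(), edges = edges,
                          topology = list(n_nodes = 0, n_edges = 0,
                                          average_degree = 0,
                                          average_path_length = 0,
                                          clustering_coefficient = 0,
                                          modularity = 0,
                                          positive_edge_fraction = NA_real_,
                                          empty = TRUE)),
                     class = "cooccurrence_network"))
  }
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(edges$rho)
  comm <- igraph::cluster_fast_greedy(g)
  modules <- igraph::membership(comm)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  topology <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    average_degree = mean(deg),
    average_path_length = igraph::mean_distance(giant, weights = NA),
    clustering_coefficient = igraph::transitivity(g, type = "global",
                                                  weights = NA),
    modularity = igraph::modularity(g, modules,
                                    weights = igraph::E(g)$weight),
    positive_edge_fraction = mean(edges$sign == "positive"))
  nodes <- data.frame(taxon_id = igraph::V(g)$name,
                      kingdom = unname(kingdom[igraph::V(g)$name]),
                      module = as.integer(modules),
                      degree = unname(deg))
  structure(list(graph = g, nodes = nodes, edges = edges,
                 topology = topology),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  t <- x$topology
  cat(sprintf(paste0("co-occurrence network: %d nodes, %d edges ",
                     "(%.0f%% positive)\n"),
              t$n_nodes, t$n_edges, 100 * (t$positive_edge_fraction %||% NA)))
  cat(sprintf("  avg degree %.2f, path length %.2f, clustering %.2f, Q %.3f\n",
              t$average_degree, t$average_path_length,
              t$clustering_coefficient, t$modularity))
  invisible(x)
}

#' Per-sample network cohesion
#'
#' Each taxon's positive (negative) connectedness is the mean of its
#' retained positive (negative) correlations, 0 if it has none. Cohesion
#' in a sample is the relative-abundance-weighted sum of connectedness
#' over taxa: `cohesion_pos >= 0 >= cohesion_neg`.
#'
#' @param table the [otu_table] used to build the network (same taxon ids).
#' @param edges screened edge data.frame from [correlation_screen].
#' @return data.frame per sample: `sample_id`, `cohesion_pos`,
#'   `cohesion_neg`.
#' @export
cohesion <- function(table, edges) {
  rel <- relative_abundance(table)
  taxa <- rownames(rel)
  conn_pos <- conn_neg <- setNames(numeric(length(taxa)), taxa)
  if (nrow(edges)) {
    long <- data.frame(taxon = c(edges$from, edges$to),
                       rho = c(edges$rho, edges$rho))
    for (tx in unique(long$taxon)) {
      r <- long$rho[long$taxon == tx]
      if (any(r > 0)) conn_pos[tx] <- mean(r[r > 0])
      if (any(r < 0)) conn_neg[tx] <- mean(r[r < 0])
    }
  }
  data.frame(sample_id = colnames(rel),
             cohesion_pos = as.numeric(crossprod(rel, conn_pos)),
             cohesion_neg = as.numeric(crossprod(rel, conn_neg)))
}

## natural connectivity of an adjacency matrix: ln of the mean exponential
## of its eigenvalues, computed with a stabilising shift
nat_conn_adj <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Natural-connectivity robustness curve under node removal
#'
#' Natural connectivity is `ln[(1/N) sum_i exp(lambda_i)]` over the
#' adjacency eigenvalues of the unsigned, unweighted graph; the curve
#' tracks it as nodes are progressively removed, either in decreasing
#' degree order or uniformly at random (averaged over repeats).
#'
#' @param network a `cooccurrence_network` or igraph graph (>= 2 nodes).
#' @param scheme `"degree"` (descending) or `"random"`.
#' @param steps number of removal steps along the curve.
#' @param n_rep random-scheme repeats to average over.
#' @param seed integer seed (random scheme).
#' @return data.frame of class `stability_result`: `fraction_removed`,
#'   `natural_connectivity`; row 1 is the intact network.
#' @export
natural_connectivity <- function(network, scheme = c("degree", "random"),
                                 steps = 10, n_rep = 10, seed = 1) {
  scheme <- match.arg(scheme)
  g <- if (inherits(network, "cooccurrence_network")) network$graph
       else network
  n <- igraph::vcount(g)
  if (n < 2) stop("need >= 2 nodes")
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj != 0) * 1
  n_remove <- floor(seq(0, 0.8 * n, length.out = steps + 1))
  curve_for <- function(order_idx) {
    vapply(n_remove, function(k) {
      keep <- setdiff(seq_len(n), order_idx[seq_len(k)])
      nat_conn_adj(adj[keep, keep, drop = FALSE])
    }, numeric(1))
  }
  if (scheme == "degree") {
    vals <- curve_for(order(rowSums(adj), decreasing = TRUE))
  } else {
    vals <- with_seed(seed, {
      reps <- vapply(seq_len(n_rep), function(r) curve_for(sample.int(n)),
                     numeric(length(n_remove)))
      rowMeans(reps)
    })
  }
  structure(data.frame(fraction_removed = n_remove / n,
                       natural_connectivity = vals),
            class = c("stability_result", "data.frame"))
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' `Zi = (k_i - mean(k, module)) / sd(k, module)` (0 when the module SD is
#' 0) and `Pi = 1 - sum_s (k_is / k_i)^2`. Role classification follows the
#' Guimera-Amaral convention: module hub (`Zi > 2.5, Pi <= 0.62`),
#' connector (`Zi <= 2.5, Pi > 0.62`), network hub (both), peripheral
#' (neither). Isolated nodes get `Pi = 0` and are flagged.
#'
#' @param network a `cooccurrence_network`, or an igraph graph.
#' @param modules optional named module membership (defaults to the
#'   network's fast-greedy modules).
#' @param zi_cut,pi_cut role thresholds.
#' @return data.frame per node: `taxon_id`, `module`, `degree`, `zi`,
#'   `pi`, `role`, `isolated`.
#' @export
zi_pi <- function(network, modules = NULL, zi_cut = 2.5, pi_cut = 0.62) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph
       else network
  if (is.null(modules)) {
    if (!inherits(network, "cooccurrence_network"))
      stop("modules must be supplied for a bare graph")
    modules <- setNames(network$nodes$module, network$nodes$taxon_id)
  }
  vn <- igraph::V(g)$name
  if (!all(vn %in% names(modules))) stop("every node needs a module")
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj != 0) * 1
  mod <- modules[vn]
  k <- rowSums(adj)
  ## within-module degree of every node
  k_in <- vapply(seq_along(vn), function(i)
    sum(adj[i, mod == mod[i]]), numeric(1))
  zi <- numeric(length(vn))
  for (mm in unique(mod)) {
    idx <- which(mod == mm)
    s <- sd(k_in[idx])
    zi[idx] <- if (is.na(s) || s == 0) 0 else (k_in[idx] - mean(k_in[idx])) / s
  }
  pi_val <- vapply(seq_along(vn), function(i) {
    if (k[i] == 0) return(0)
    k_is <- tapply(adj[i, ], mod, sum)
    1 - sum((k_is / k[i])^2)
  }, numeric(1))
  role <- ifelse(zi > zi_cut & pi_val > pi_cut, "network hub",
          ifelse(zi > zi_cut, "module hub",
          ifelse(pi_val > pi_cut, "connector", "peripheral")))
  data.frame(taxon_id = vn, module = as.integer(mod), degree = k,
             zi = zi, pi = pi_val, role = role, isolated = k == 0,
             row.names = NULL)
}
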