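#' Run configuration
#'
#' Bundles every tunable threshold and replicate count of the pipeline.
#'
#' @param n_null null-model replicates for betaNTI / RCbray / MST (>= 99).
#' @param n_perm PERMANOVA permutations.
#' @param prevalence_min,r_min,q_max network edge screen settings
#'   (prevalence fraction, |Spearman rho| threshold in (0, 1], BH FDR
#'   level).
#' @param bnti_cut,rc_cut process-classification cut-offs.
#' @param rf_trees,rf_perm random-forest size and response permutations.
#' @param rarefy optional even depth to rarefy OTU tables to before
#'   diversity/assembly analyses (`NULL`, the default, uses the tables
#'   as given and relative abundances where needed).
#' @param seed master integer seed; each randomized stage derives a child
#'   seed deterministically.
#' @return list of class `rhizo_config`.
#' @export
rhizo_config <- function(n_null = 999, n_perm = 999, prevalence_min = 1/3,
                         r_min = 0.6, q_max = 0.05, bnti_cut = 2,
                         rc_cut = 0.95, rf_trees = 1000, rf_perm = 999,
                         rarefy = NULL, seed = 1) {
  stopifnot(n_null >= 1, n_perm >= 1, r_min > 0, r_min <= 1,
            q_max > 0, q_max <= 1, prevalence_min >= 0, prevalence_min <= 1)
  structure(as.list(environment()), class = "rhizo_config")
}

#' Subset an OTU table to a set of samples
#' @param table an [otu_table].
#' @param ids sample ids to keep.
#' @return an [otu_table].
#' @export
subset_samples <- function(table, ids) {
  otu_table(table$counts[, ids, drop = FALSE], table$kingdom)
}

#' Rarefy an OTU table to even depth
#' @param table an [otu_table].
#' @param depth reads per sample; samples below `depth` are dropped with a
#'   warning.
#' @param seed integer seed.
#' @return an [otu_table] with every sample total equal to `depth`.
#' @export
rarefy_table <- function(table, depth, seed = 1) {
  cnt <- table$counts
  keep <- colSums(cnt) >= depth
  if (any(!keep))
    warning("dropping sample(s) below rarefaction depth: ",
            paste(colnames(cnt)[!keep], collapse = ", "))
  cnt <- cnt[, keep, drop = FALSE]
  out <- with_seed(seed, {
    apply(cnt, 2, function(x) {
      ind <- sample(rep.int(seq_along(x), x), depth)
      tabulate(ind, nbins = length(x))
    })
  })
  dimnames(out) <- dimnames(cnt)
  otu_table(out, table$kingdom)
}

#' Run the full analysis pipeline on a study
#'
#' Executes, in order: the SMC index with its group tests and OLS
#' relationships; alpha/beta diversity with PCoA and one-factor PERMANOVA
#' per kingdom; null-model assembly inference (betaNTI, RCbray, process
#' partition, MST) and per-group Sloan NCM fits; per-stand-type
#' cross-kingdom co-occurrence networks with cohesion, topology and Zi-Pi;
#' and the driver models (permutation-importance random forest and the
#' recursive path model).
#'
#' @param study a `synthetic_study` from [generate_study], or any list with
#'   elements `bacteria`, `fungi` ([otu_table]s), `tree_bacteria`,
#'   `tree_fungi` ([ape::phylo]) and `meta` (metadata data.frame).
#' @param config a [rhizo_config].
#' @param stages character subset of
#'   `c("smc", "diversity", "assembly", "network", "drivers")`.
#' @return list of class `rhizo_results`.
#' @export
run_pipeline <- function(study, config = rhizo_config(),
                         stages = c("smc", "diversity", "assembly",
                                    "network", "drivers")) {
  meta <- validate_metadata(study$meta)
  tabs <- list(bacteria = study$bacteria, fungi = study$fungi)
  trees <- list(bacteria = study$tree_bacteria, fungi = study$tree_fungi)
  if (!is.null(config$rarefy))
    for (kd in names(tabs))
      tabs[[kd]] <- rarefy_table(tabs[[kd]], config$rarefy,
                                 derive_seed(config$seed, 99))
  ids <- meta$sample_id
  groups <- as.character(meta$stand_type)
  res <- list(meta = meta, config = config)

  if ("smc" %in% stages) res$smc <- smc_index(meta)

  if ("diversity" %in% stages) {
    res$alpha <- lapply(tabs, alpha_diversity)
    res$beta <- lapply(names(tabs), function(kd) {
      bc <- bray_curtis(subset_samples(tabs[[kd]], ids))
      list(bray_curtis = bc, pcoa = pcoa(bc),
           permanova = permanova(bc, groups, n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 11)))
    })
    names(res$beta) <- names(tabs)
  }

  if ("assembly" %in% stages) {
    res$assembly <- lapply(seq_along(tabs), function(k) {
      kd <- names(tabs)[k]
      tab <- subset_samples(tabs[[kd]], ids)
      bnti <- beta_nti(tab, trees[[kd]], n_null = config$n_null,
                       seed = derive_seed(config$seed, 20 + k))
      rc <- raup_crick_bray(tab, n_null = config$n_null,
                            seed = derive_seed(config$seed, 30 + k))
      part <- partition_processes(bnti$bnti, rc, groups = groups,
                                  bnti_cut = config$bnti_cut,
                                  rc_cut = config$rc_cut)
      m <- mst(tab, groups, n_null = config$n_null,
               seed = derive_seed(config$seed, 40 + k))
      ncm <- lapply(split(ids, groups), function(g)
        fit_ncm(subset_samples(tab, g)))
      ncm$all <- fit_ncm(tab)
      list(bnti = bnti, rc = rc, partition = part, mst = m, ncm = ncm)
    })
    names(res$assembly) <- names(tabs)
  }

  if ("network" %in% stages) {
    merged <- merge_kingdoms(subset_samples(tabs$bacteria, ids),
                             subset_samples(tabs$fungi, ids))
    res$networks <- lapply(split(ids, groups), function(g) {
      sub <- subset_samples(merged, g)
      edges <- correlation_screen(sub, prevalence_min = config$prevalence_min,
                                  r_min = config$r_min, q_max = config$q_max)
      net <- build_network(edges)
      zp <- if (net$topology$n_nodes > 0) zi_pi(net) else NULL
      stab <- if (net$topology$n_nodes >= 2)
        natural_connectivity(net, scheme = "degree") else NULL
      list(edges = edges, network = net, zi_pi = zp, stability = stab,
           cohesion = cohesion(sub, edges))
    })
    res$cohesion <- do.call(rbind, lapply(res$networks, `[[`, "cohesion"))
    rownames(res$cohesion) <- NULL
  }

  if ("drivers" %in% stages) {
    dt <- assemble_driver_table(res)
    preds <- dt[, grep("^(B_|F_|cohesion_)", names(dt)), drop = FALSE]
    imp <- rf_importance(preds, dt$SMC, n_trees = config$rf_trees,
                         n_perm = config$rf_perm,
                         seed = derive_seed(config$seed, 60))
    pm_data <- data.frame(
      forest_type = as.numeric(dt$stand_type == "M"),
      pH = dt$pH,
      B_diversity = dt$B_shannon, F_diversity = dt$F_shannon,
      B_assembly = dt$B_mean_bnti, complexity = dt$cohesion_pos,
      SMC = dt$SMC)
    path <- fit_path_model(pm_data, default_path_diagram(), outcome = "SMC")
    res$drivers <- list(table = dt, importance = imp, path = path)
  }
  structure(res, class = "rhizo_results")
}

#' Default path diagram for the driver model
#'
#' Stand type acts on soil (pH), both kingdoms' diversity, bacterial
#' assembly and network complexity; soil acts on diversity and assembly;
#' diversity acts on complexity; soil, diversity, assembly and complexity
#' act directly on SMC.
#'
#' @return data.frame of directed edges (`from`, `to`).
#' @export
default_path_diagram <- function() {
  data.frame(
    from = c("forest_type", "forest_type", "forest_type", "forest_type",
             "forest_type", "pH", "pH", "pH",
             "B_diversity", "F_diversity",
             "pH", "B_diversity", "F_diversity", "B_assembly", "complexity"),
    to = c("pH", "B_diversity", "F_diversity", "B_assembly",
           "complexity", "B_diversity", "F_diversity", "B_assembly",
           "complexity", "complexity",
           "SMC", "SMC", "SMC", "SMC", "SMC"),
    stringsAsFactors = FALSE)
}

#' @export
print.rhizo_results <- function(x, ...) {
  cat("rhizo_results with stages:",
      paste(intersect(c("smc", "alpha", "beta", "assembly", "networks",
                        "drivers"), names(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Export a co-occurrence network to GraphML
#'
#' Node attributes: kingdom, module, degree, Zi, Pi, role; edge
#' attributes: rho, q, sign.
#'
#' @param network a `cooccurrence_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- network$graph
  zp <- zi_pi(network)
  idx <- match(igraph::V(g)$name, zp$taxon_id)
  igraph::V(g)$kingdom <- network$nodes$kingdom
  igraph::V(g)$module <- network$nodes$module
  igraph::V(g)$zi <- zp$zi[idx]
  igraph::V(g)$pi <- zp$pi[idx]
  igraph::V(g)$role <- zp$role[idx]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
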