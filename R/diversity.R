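#' Alpha diversity indices
#'
#' Shannon (natural log), Simpson (1 - sum p^2), Pielou evenness
#' (H / ln S_obs, set to 1 for single-taxon samples) and Chao1 richness
#' (S_obs + F1^2 / (2 F2), with the bias-corrected form
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) when F2 = 0).
#'
#' @param table an [otu_table]; every sample must have a positive total.
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `simpson`, `pielou`, `chao1`.
#' @export
alpha_diversity <- function(table) {
  cnt <- table$counts
  if (any(colSums(cnt) == 0)) stop("empty sample(s)")
  shannon <- vegan::diversity(t(cnt), index = "shannon")
  simpson <- vegan::diversity(t(cnt), index = "simpson")
  s_obs <- colSums(cnt > 0)
  pielou <- ifelse(s_obs > 1, shannon / log(s_obs), 1)
  chao1 <- apply(cnt, 2, function(x) {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
  data.frame(sample_id = colnames(cnt), richness = s_obs, shannon = shannon,
             simpson = simpson, pielou = pielou, chao1 = chao1,
             row.names = colnames(cnt))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum min(x_i, y_i) / sum (x_i + y_i)` on counts.
#'
#' @param table an [otu_table] with >= 2 samples.
#' @return a symmetric sample x sample matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  cnt <- table$counts
  if (ncol(cnt) < 2) stop("need >= 2 samples")
  if (any(colSums(cnt) == 0)) stop("all-zero sample(s)")
  as.matrix(vegan::vegdist(t(cnt), method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered Gower matrix of squared
#' dissimilarities. Axes are ordered by eigenvalue; negative eigenvalues
#' (possible for semi-metric inputs such as Bray-Curtis) are reported, not
#' dropped.
#'
#' @param dist symmetric dissimilarity matrix.
#' @param k number of axes to return.
#' @return list with `coordinates` (n x k, axes with positive eigenvalues),
#'   `eigenvalues` (all n, sorted decreasing), and
#'   `relative_eig` (share of the positive eigenvalue total).
#' @export
pcoa <- function(dist, k = 2) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dist)
  g <- -0.5 * dist^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  g <- g + mean(-0.5 * dist^2)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  k_use <- min(k, length(pos))
  coords <- e$vectors[, pos[seq_len(k_use)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k_use)]]), k_use)
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("PCo", seq_len(k_use))
  list(coordinates = coords, eigenvalues = e$values,
       relative_eig = pmax(e$values, 0) / sum(pmax(e$values, 0)))
}

#' One-factor PERMANOVA
#'
#' Pseudo-F from among/within sums of squared dissimilarities
#' (Anderson's distance-based decomposition), `R^2 = SS_among / SS_total`,
#' and the permutation p-value
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)` under random relabeling
#' with a fixed seed.
#'
#' @param dist symmetric dissimilarity matrix.
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `f`, `r_squared`, `p`, `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  a <- length(tab)
  ss_within_for <- function(g) {
    sw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      sw <- sw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    sw
  }
  f_stat <- function(g) {
    sw <- ss_within_for(g)
    sa <- ss_total - sw
    (sa / (a - 1)) / (sw / (n - a))
  }
  f_obs <- f_stat(groups)
  ss_within <- ss_within_for(groups)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_stat(sample(groups)), numeric(1))
  })
  list(f = f_obs,
       r_squared = (ss_total - ss_within) / ss_total,
       p = (1 + sum(perm_f >= f_obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Aggregate composition to a taxonomy level
#'
#' Sums per-sample relative abundances within taxonomy groups; taxa not in
#' the map are assigned `"Unclassified"`.
#'
#' @param table an [otu_table].
#' @param taxonomy named character vector mapping taxon id to group, or
#'   `NULL` to keep taxa as-is.
#' @return group x sample matrix of relative abundances; columns sum to 1.
#' @export
aggregate_composition <- function(table, taxonomy = NULL) {
  rel <- relative_abundance(table)
  if (is.null(taxonomy)) return(rel)
  grp <- taxonomy[rownames(rel)]
  grp[is.na(grp)] <- "Unclassified"
  rowsum(rel, group = grp)
}
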