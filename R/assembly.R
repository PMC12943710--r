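## ---- phylogenetic turnover -------------------------------------------------

## beta-MNTD for all sample pairs given a patristic distance matrix D
## (taxa x taxa) and a relative-abundance matrix (taxa x samples).
bmntd_all_pairs <- function(D, rel) {
  n <- ncol(rel)
  present <- lapply(seq_len(n), function(j) which(rel[, j] > 0))
  ## min patristic distance from every taxon to the taxa present in sample j
  min_to <- vapply(seq_len(n), function(j)
    row_mins(D[, present[[j]], drop = FALSE]), numeric(nrow(D)))
  out <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    v <- 0.5 * (sum(rel[, a] * min_to[, b]) + sum(rel[, b] * min_to[, a]))
    out[a, b] <- out[b, a] <- v
  }
  out
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For each sample pair, the mean patristic distance from every taxon in
#' one sample to its nearest taxon in the other, weighted by relative
#' abundance and averaged over both directions. A taxon present in both
#' samples has nearest-taxon distance 0.
#'
#' @param table an [otu_table]; every taxon must be a tip of `tree`.
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param weighted if `FALSE`, presence/absence weights (1/richness) are
#'   used instead of relative abundances.
#' @return symmetric sample x sample matrix of beta-MNTD values.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  cnt <- table$counts
  miss <- setdiff(rownames(cnt), tree$tip.label)
  if (length(miss)) stop("taxa absent from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (any(colSums(cnt) == 0)) stop("empty sample(s)")
  D <- ape::cophenetic.phylo(tree)[rownames(cnt), rownames(cnt)]
  rel <- if (weighted) sweep(cnt, 2, colSums(cnt), "/")
         else sweep(cnt > 0, 2, colSums(cnt > 0), "/")
  bmntd_all_pairs(D, rel)
}

#' Beta nearest taxon index (phylogenetic null-model z-score)
#'
#' `betaNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null)`
#' where the null shuffles taxon labels across the tips of the tree
#' ("taxa.labels" null). Each null replicate uses one shared tip
#' relabeling for all sample pairs. Pairs whose null SD is zero (e.g.
#' identical samples) are flagged degenerate and assigned betaNTI = 0.
#' Values beyond +/-2 indicate deterministic assembly (heterogeneous /
#' homogeneous selection).
#'
#' @inheritParams beta_mntd
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed.
#' @return list with `bnti`, `bmntd` (observed), `degenerate` (logical
#'   matrix), `n_null`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = 1, weighted = TRUE) {
  if (n_null < 99) stop("n_null must be >= 99 for stable z-scores")
  cnt <- table$counts
  miss <- setdiff(rownames(cnt), tree$tip.label)
  if (length(miss)) stop("taxa absent from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  D <- ape::cophenetic.phylo(tree)[rownames(cnt), rownames(cnt)]
  rel <- if (weighted) sweep(cnt, 2, colSums(cnt), "/")
         else sweep(cnt > 0, 2, colSums(cnt > 0), "/")
  obs <- bmntd_all_pairs(D, rel)
  n <- ncol(rel)
  sum1 <- sum2 <- matrix(0, n, n)
  with_seed(seed, {
    nt <- nrow(D)
    for (r in seq_len(n_null)) {
      perm <- sample.int(nt)
      nul <- bmntd_all_pairs(D[perm, perm], rel)
      sum1 <- sum1 + nul
      sum2 <- sum2 + nul^2
    }
  })
  mu <- sum1 / n_null
  sdv <- sqrt(pmax((sum2 - n_null * mu^2) / (n_null - 1), 0))
  degenerate <- sdv < 1e-12
  bnti <- (obs - mu) / ifelse(degenerate, 1, sdv)
  bnti[degenerate] <- 0
  diag(degenerate) <- FALSE
  dimnames(bnti) <- dimnames(degenerate) <- dimnames(obs)
  list(bnti = bnti, bmntd = obs, degenerate = degenerate, n_null = n_null)
}

## ---- taxonomic null models -------------------------------------------------

## Shared null-community scheme (Raup-Crick / MST): each null sample keeps
## its observed richness (taxa drawn without replacement with probability
## proportional to occurrence frequency) and its observed total count
## (one individual per drawn taxon, the remainder multinomial with
## probability proportional to mean relative abundance). Returns the mean
## null Bray-Curtis matrix plus the fraction of null values below / tied
## with the observed ones.
null_bray_stats <- function(table, n_null, seed, tol = 1e-10) {
  cnt <- table$counts
  n <- ncol(cnt)
  occ <- rowSums(cnt > 0)
  pool <- which(occ > 0)
  p_mean <- rowMeans(sweep(cnt, 2, colSums(cnt), "/"))
  rich <- colSums(cnt > 0)
  tot <- colSums(cnt)
  obs <- bray_curtis(table)
  nsum <- matrix(0, n, n)
  less <- tie <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nul <- matrix(0L, nrow(cnt), n)
      for (j in seq_len(n)) {
        sel <- pool[sample.int(length(pool), rich[j], prob = occ[pool])]
        cj <- rep(1L, length(sel))
        extra <- tot[j] - length(sel)
        if (extra > 0)
          cj <- cj + as.integer(rmultinom(1, extra, p_mean[sel]))
        nul[sel, j] <- cj
      }
      bc <- as.matrix(vegan::vegdist(t(nul), method = "bray"))
      nsum <- nsum + bc
      less <- less + (bc < obs - tol)
      tie <- tie + (abs(bc - obs) <= tol)
    }
  })
  dimnames(nsum) <- dimnames(less) <- dimnames(tie) <- dimnames(obs)
  list(obs = obs, mean_null = nsum / n_null, frac_less = less / n_null,
       frac_tie = tie / n_null, n_null = n_null)
}

#' Bray-Curtis based Raup-Crick index
#'
#' Compares each pair's observed Bray-Curtis dissimilarity to a null
#' distribution of randomly assembled communities (observed richness,
#' species drawn by occurrence frequency, counts filled by mean relative
#' abundance). `RCbray = 2 [ (#null < obs) + 0.5 (#null = obs) ] / n_null - 1`,
#' bounded in [-1, 1]; values beyond +/-0.95 indicate dispersal-driven
#' deviation from the null.
#'
#' @param table an [otu_table].
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed.
#' @return symmetric sample x sample matrix of RCbray values.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1) {
  if (n_null < 99) stop("n_null must be >= 99")
  st <- null_bray_stats(table, n_null, seed)
  rc <- 2 * (st$frac_less + 0.5 * st$frac_tie) - 1
  diag(rc) <- 0
  rc
}

#' Partition community assembly into five ecological processes
#'
#' Per sample pair: `betaNTI > 2` heterogeneous selection; `betaNTI < -2`
#' homogeneous selection; otherwise `RCbray > 0.95` dispersal limitation,
#' `RCbray < -0.95` homogenizing dispersal, and `|RCbray| <= 0.95`
#' drift/undominated. Every pair receives exactly one label.
#'
#' @param bnti,rc aligned symmetric matrices from [beta_nti] and
#'   [raup_crick_bray].
#' @param groups optional per-sample labels; fractions are then also
#'   reported over within-group pairs.
#' @param bnti_cut,rc_cut classification thresholds (defaults 2 and 0.95).
#' @return list with `labels` (pair matrix), `fractions` (overall), and
#'   `group_fractions` / `stochastic_share` when `groups` is given.
#'   Stochastic share is the fraction of pairs with `|betaNTI| < 2`.
#' @export
partition_processes <- function(bnti, rc, groups = NULL,
                                bnti_cut = 2, rc_cut = 0.95) {
  if (!all(dim(bnti) == dim(rc)))
    stop("betaNTI and RCbray matrices must be aligned")
  procs <- c("heterogeneous selection", "homogeneous selection",
             "dispersal limitation", "homogenizing dispersal",
             "drift/undominated")
  lab <- matrix(NA_character_, nrow(bnti), ncol(bnti),
                dimnames = dimnames(bnti))
  lab[bnti > bnti_cut] <- procs[1]
  lab[bnti < -bnti_cut] <- procs[2]
  sto <- abs(bnti) <= bnti_cut
  lab[sto & rc > rc_cut] <- procs[3]
  lab[sto & rc < -rc_cut] <- procs[4]
  lab[sto & abs(rc) <= rc_cut] <- procs[5]
  diag(lab) <- NA
  frac_of <- function(idx_pairs) {
    v <- lab[idx_pairs]
    tab <- table(factor(v, levels = procs))
    setNames(as.numeric(tab) / length(v), procs)
  }
  ut <- upper.tri(lab)
  out <- list(labels = lab, fractions = frac_of(ut))
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gf <- list(); ss <- numeric(0)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      mask <- matrix(FALSE, nrow(lab), ncol(lab))
      mask[idx, idx] <- TRUE
      mask <- mask & ut
      gf[[g]] <- frac_of(mask)
      ss[g] <- mean(abs(bnti[mask]) < bnti_cut)
    }
    out$group_fractions <- gf
    out$stochastic_share <- ss
  }
  out
}

#' Modified stochasticity ratio (MST)
#'
#' For each within-group pair, with observed Bray-Curtis `D_obs` and mean
#' null dissimilarity `D_null` (same null-community scheme as
#' [raup_crick_bray]): `MST_pair = min(D_obs, D_null) / max(D_obs, D_null)`.
#' The group MST is the mean over its pairs; values in [0, 1], with 1
#' fully stochastic and MST > 0.5 conventionally read as
#' stochasticity-dominated.
#'
#' @param table an [otu_table].
#' @param groups per-sample group labels (>= 2 samples per group).
#' @param n_null number of null replicates.
#' @param seed integer seed.
#' @return named numeric vector of per-group MST values, with per-pair
#'   values in attribute `"pairs"`.
#' @export
mst <- function(table, groups, n_null = 999, seed = 1) {
  groups <- as.character(groups)
  if (any(base::table(groups) < 2)) stop("every group needs >= 2 samples")
  st <- null_bray_stats(table, n_null, seed)
  ratio <- pmin(st$obs, st$mean_null) / pmax(st$obs, st$mean_null)
  ratio[pmax(st$obs, st$mean_null) == 0] <- NA  # flagged degenerate pairs
  out <- numeric(0)
  pairs <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- ratio[idx, idx][upper.tri(ratio[idx, idx])]
    pairs[[g]] <- v
    out[g] <- mean(v, na.rm = TRUE)
  }
  attr(out, "pairs") <- pairs
  out
}

## ---- Sloan neutral community model ----------------------------------------

#' Fit the Sloan neutral community model
#'
#' Predicts each taxon's occurrence frequency from its mean relative
#' abundance `p` under neutral island dynamics with migration probability
#' `m`. Two prediction forms are available:
#' \describe{
#'   \item{`"betabinomial"` (default)}{the exact stationary occupancy of a
#'     finite island Moran community of size `N`: counts follow a
#'     beta-binomial with shape `A p, A (1 - p)` where
#'     `A = m (N - 1) / (1 - m)`, and the predicted frequency is the
#'     probability of at least one individual. This matches simulated
#'     death-birth communities without the continuous-sampling bias.}
#'   \item{`"beta"`}{the classical continuous approximation
#'     `1 - BetaCDF(d; N m p, N m (1 - p))` with detection limit
#'     `d = 1/N` by default.}
#' }
#' `m` is estimated by least squares of predicted against observed
#' frequency (1-D search on a transformed scale, `m` constrained to
#' (1e-6, 1]); `R^2 = 1 - SSE/SST`. A 95% band around the prediction uses
#' the Wilson binomial interval at the number of samples.
#'
#' @param table an [otu_table] with >= 5 samples.
#' @param method prediction form, see Details.
#' @param detection_limit optional fixed detection limit for the `"beta"`
#'   form; default `1/N`.
#' @return object of class `ncm_fit`: list with `m`, `Nm`, `r_squared`,
#'   `N`, `detection_limit`, `method`, and `taxa` (per-taxon
#'   observed/predicted frequencies with the 95% band).
#' @export
fit_ncm <- function(table, method = c("betabinomial", "beta"),
                    detection_limit = NULL) {
  method <- match.arg(method)
  cnt <- table$counts
  if (ncol(cnt) < 5) stop("need >= 5 samples to fit the NCM")
  N <- mean(colSums(cnt))
  d <- detection_limit %||% (1 / N)
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  p <- rowMeans(rel)
  freq <- rowMeans(cnt > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  pred_at <- function(m) {
    if (method == "beta") return(1 - pbeta(d, N * m * p, N * m * (1 - p)))
    A <- m * (N - 1) / (1 - m)
    1 - exp(lbeta(A * p, A * (1 - p) + N) - lbeta(A * p, A * (1 - p)))
  }
  ## least squares on the logit scale keeps the search stable near m = 1
  sse <- function(lg) sum((freq - pred_at(stats::plogis(lg)))^2)
  opt <- optimize(sse, interval = c(-14, 14))
  m_hat <- min(1 - 1e-9, max(1e-6, stats::plogis(opt$minimum)))
  pred <- pred_at(m_hat)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
  n <- ncol(cnt); z <- 1.959964
  centre <- (pred + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(pred * (1 - pred) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  taxa <- data.frame(taxon_id = names(p), mean_rel_abund = p,
                     freq_obs = freq, freq_pred = pred,
                     lower = pmax(0, centre - half),
                     upper = pmin(1, centre + half))
  structure(list(m = m_hat, Nm = N * m_hat, r_squared = r2, N = N,
                 detection_limit = d, method = method, taxa = taxa,
                 converged = TRUE),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: m = %.4f (Nm = %.1f), R2 = %.3f over %d taxa\n",
              x$m, x$Nm, x$r_squared, nrow(x$taxa)))
  invisible(x)
}

#' @export
plot.ncm_fit <- function(x, ...) {
  o <- order(x$taxa$mean_rel_abund)
  plot(log10(x$taxa$mean_rel_abund), x$taxa$freq_obs, pch = 16, cex = 0.5,
       xlab = "log10 mean relative abundance", ylab = "occurrence frequency",
       ...)
  lines(log10(x$taxa$mean_rel_abund[o]), x$taxa$freq_pred[o], col = 2)
  lines(log10(x$taxa$mean_rel_abund[o]), x$taxa$lower[o], col = 2, lty = 2)
  lines(log10(x$taxa$mean_rel_abund[o]), x$taxa$upper[o], col = 2, lty = 2)
  invisible(x)
}
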