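#' Specification of a synthetic rhizosphere study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: a 2 (stand ages) x
#' 2 (stand types P/M) x 6 (replicate plots) layout, two marker communities
#' (bacteria and fungi), and group-shifted, mutually correlated soil
#' chemistry. Mixed-stand (M) samples are assembled with a higher migration
#' rate and weaker environmental filtering than pure-stand (P) samples, so
#' the qualitative contrasts the pipeline should detect (more stochastic
#' assembly, higher diversity, more cooperative networks in M) are present
#' in the ground truth.
#'
#' @param n_taxa named vector: metacommunity richness per kingdom.
#' @param n_reads sequencing depth per sample (constant by default).
#' @param ages,stand_types,replicates the factorial design.
#' @param m named migration rate per stand type, in (0, 1].
#' @param s named selection strength per stand type (0 = neutral);
#'   Gaussian-kernel filtering on a standardized Brownian trait.
#' @param env_optimum named environmental optimum per stand type, in trait
#'   SD units.
#' @param env_jitter within-group SD of the per-sample environment.
#' @param env_age_shift named per-stand-type difference in environmental
#'   optimum between the two age classes (trait SD units); heterogeneous
#'   selection across ages within a stand type.
#' @param bm_sigma Brownian-motion SD per unit branch length for trait
#'   evolution (trait conservation: larger trees/sigma give stronger
#'   phylogenetic signal).
#' @param sdlog log-normal shape of the metacommunity rank-abundance curve.
#' @param soil_effects named M-vs-P mean shifts (in SD units) per soil
#'   variable.
#' @param soil_age_effect mean shift (SD units) of the seven nutrients for
#'   the older stands.
#' @param soil_noise_sd residual SD of soil variables (SD units).
#' @param soil_cor common pairwise correlation among the seven nutrients.
#' @param soil_cor_phswc correlation of pH and SWC with each nutrient (and
#'   with each other).
#' @param responsive_frac fraction of taxa per kingdom loading on a shared
#'   per-sample fertility factor (the source of cooperative positive
#'   co-occurrence).
#' @param fertility_sd named SD of the per-sample fertility factor per
#'   stand type.
#' @param n_blocks number of interaction guilds (taxon blocks sharing a
#'   per-sample latent factor) per kingdom; guilds generate the strong
#'   within-block positive correlations co-occurrence screens detect.
#' @param block_frac fraction of a kingdom's taxa in each guild.
#' @param block_sd named SD of the per-sample guild factors per stand
#'   type; larger values mean stronger cooperative co-fluctuation.
#' @param block_load range (min, max) of per-taxon guild loadings.
#' @param burnin_factor death-birth events per individual in the local
#'   community process.
#' @param depth_jitter relative SD of per-sample read depth (0 = constant
#'   depth).
#' @param seed master integer seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_taxa = c(bacteria = 300, fungi = 150),
                            n_reads = 5000,
                            ages = c(20, 31),
                            stand_types = c("P", "M"),
                            replicates = 6,
                            m = c(P = 0.15, M = 0.9),
                            s = c(P = 6, M = 0.1),
                            env_optimum = c(P = -0.8, M = 0.8),
                            env_age_shift = c(P = 1.6, M = 0.2),
                            env_jitter = 0.3,
                            bm_sigma = 1,
                            sdlog = 2,
                            soil_effects = c(SOC = 1, TN = 1, TP = 0.8,
                                             AP = 1, AK = 0.8, NH4 = 1,
                                             NO3 = -0.8, pH = 0.8, SWC = 0.8),
                            soil_age_effect = 0.2,
                            soil_noise_sd = 1,
                            soil_cor = 0.3,
                            soil_cor_phswc = 0.3,
                            responsive_frac = 0.6,
                            fertility_sd = c(P = 0.2, M = 0.7),
                            n_blocks = 4,
                            block_frac = 0.1,
                            block_sd = c(P = 0.3, M = 0.5),
                            block_load = c(0.5, 1),
                            burnin_factor = 10,
                            depth_jitter = 0,
                            seed = 1) {
  stopifnot(all(n_taxa >= 10), n_reads >= 100, replicates >= 2,
            all(m > 0), all(m <= 1), all(s >= 0))
  structure(as.list(environment()), class = "simulation_spec")
}

#' Generate a random rooted phylogeny
#'
#' Coalescent-style random topology ([ape::rcoal]) with i.i.d. exponential
#' branch lengths (mean 1). Deterministic given the seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param prefix tip-label prefix.
#' @return an [ape::phylo] rooted bifurcating tree with `n_taxa` tips.
#' @export
generate_phylogeny <- function(n_taxa, seed, prefix = "t") {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  with_seed(seed, {
    tree <- ape::rcoal(n_taxa, tip.label = paste0(prefix, seq_len(n_taxa)))
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
    tree
  })
}

#' Generate log-normal metacommunity relative abundances
#'
#' @param n_taxa number of taxa.
#' @param seed integer seed.
#' @param sdlog log-normal shape parameter.
#' @return a vector of relative abundances summing to 1.
#' @export
generate_metacommunity <- function(n_taxa, seed, sdlog = 2) {
  with_seed(seed, {
    a <- rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)
    a / sum(a)
  })
}

## one local community via the death-birth (Moran) process; randomness
## must be pre-seeded by the caller
local_community <- function(pool, n_reads, m, burnin_factor) {
  n_taxa <- length(pool)
  comm <- sample.int(n_taxa, n_reads, replace = TRUE, prob = pool)
  n_events <- as.integer(round(burnin_factor * n_reads))
  if (n_events > 0 && m < 1) {
    comm <- moran_update(comm,
                         sample.int(n_reads, n_events, replace = TRUE),
                         sample.int(n_taxa, n_events, replace = TRUE,
                                    prob = pool),
                         sample.int(n_reads, n_events, replace = TRUE),
                         as.integer(runif(n_events) < m))
  } else if (n_events > 0) {
    ## m = 1: every replacement is a metacommunity draw, so the stationary
    ## community is an i.i.d. multinomial sample from the pool
    comm <- sample.int(n_taxa, n_reads, replace = TRUE, prob = pool)
  }
  tabulate(comm, nbins = n_taxa)
}

#' Simulate neutral local communities (Hubbell/Sloan regime)
#'
#' Each sample is initialized as a multinomial draw from the metacommunity
#' and then evolved by death-birth events in which the replacement is a
#' metacommunity migrant with probability `m` and a copy of a random local
#' individual otherwise. At `m = 1` samples are exactly i.i.d. multinomial
#' draws from the metacommunity.
#'
#' @param meta metacommunity relative abundances (will be normalized).
#' @param n_samples number of samples.
#' @param n_reads individuals (reads) per sample.
#' @param m migration rate in (0, 1].
#' @param seed integer seed.
#' @param burnin_factor death-birth events per individual (default 10).
#' @param sample_ids optional sample names.
#' @return an [otu_table] (kingdom `"bacteria"`) with columns summing to
#'   `n_reads`.
#' @export
simulate_neutral_communities <- function(meta, n_samples, n_reads, m, seed,
                                         burnin_factor = 10,
                                         sample_ids = NULL) {
  stopifnot(m > 0, m <= 1)
  meta <- meta / sum(meta)
  ids <- sample_ids %||% paste0("S", seq_len(n_samples))
  cnt <- with_seed(seed, {
    vapply(seq_len(n_samples), function(j)
      local_community(meta, n_reads, m, burnin_factor),
      integer(length(meta)))
  })
  dimnames(cnt) <- list(names(meta) %||% paste0("t", seq_along(meta)), ids)
  otu_table(cnt, "bacteria")
}

#' Simulate environmentally filtered communities
#'
#' A trait is evolved on the tree by Brownian motion (variance
#' `bm_sigma^2` per unit branch length), giving phylogenetically conserved
#' environmental optima. Each sample is a multinomial draw with taxon
#' weights `meta_i * exp(-s * (trait_i - env_j)^2)`. With `s = 0` this
#' reduces exactly to the neutral `m = 1` case.
#'
#' @param meta metacommunity relative abundances, named by tree tips or in
#'   tip order.
#' @param tree an [ape::phylo] tree whose tips are the taxa.
#' @param env per-sample environment values (same scale as the trait).
#' @param s selection strength (>= 0).
#' @param n_reads reads per sample.
#' @param seed integer seed.
#' @param bm_sigma Brownian SD per unit branch length.
#' @param traits optional pre-computed trait vector (named by tips);
#'   bypasses the Brownian simulation.
#' @param standardize_traits center/scale the trait to SD 1 so `s` and
#'   `env` are in trait-SD units.
#' @return an [otu_table] with attribute `"traits"`.
#' @export
simulate_filtered_communities <- function(meta, tree, env, s, n_reads, seed,
                                          bm_sigma = 1, traits = NULL,
                                          standardize_traits = TRUE) {
  stopifnot(s >= 0)
  n_taxa <- length(tree$tip.label)
  meta <- meta / sum(meta)
  if (is.null(traits))
    traits <- with_seed(derive_seed(seed, 0),
                        ape::rTraitCont(tree, model = "BM",
                                        sigma = bm_sigma))
  traits <- traits[tree$tip.label]
  if (standardize_traits && sd(traits) > 0)
    traits <- (traits - mean(traits)) / sd(traits)
  cnt <- with_seed(derive_seed(seed, 1), {
    vapply(seq_along(env), function(j) {
      w <- meta * exp(-s * (traits - env[j])^2)
      as.integer(rmultinom(1, n_reads, w))
    }, integer(n_taxa))
  })
  dimnames(cnt) <- list(tree$tip.label, paste0("S", seq_along(env)))
  out <- otu_table(cnt, "bacteria")
  attr(out, "traits") <- traits
  out
}

#' Generate group-structured soil chemistry
#'
#' Per-variable Gaussian draws in SD units with stand-type mean shifts, a
#' common pairwise correlation among the seven nutrients, and an optional
#' age shift; the standardized draws are then mapped to realistic raw
#' units. With zero effects and zero noise every sample gets identical
#' (baseline) values.
#'
#' @param design data.frame with columns `sample_id`, `stand_type`,
#'   `stand_age`, `plot`.
#' @param effects named M-vs-P shifts (SD units) for any of the nine soil
#'   variables.
#' @param noise_sd residual SD (SD units).
#' @param seed integer seed.
#' @param rho common nutrient-nutrient correlation.
#' @param rho_phswc correlation of pH and SWC with the nutrients and with
#'   each other.
#' @param age_effect shift (SD units) of the seven nutrients in the older
#'   age class.
#' @return a metadata `data.frame` (design columns + nine soil variables).
#' @export
generate_soil_properties <- function(design, effects = numeric(0),
                                     noise_sd = 1, seed = 1, rho = 0.3,
                                     rho_phswc = 0, age_effect = 0) {
  vars <- soil_variables()
  nutrients <- c("SOC", "TN", "TP", "AP", "AK", "NH4", "NO3")
  base <- c(pH = 5.2, SWC = 0.25, SOC = 35, TN = 2.5, TP = 0.6, AP = 8,
            AK = 150, NH4 = 12, NO3 = 6)
  scale <- c(pH = 0.4, SWC = 0.05, SOC = 6, TN = 0.5, TP = 0.12, AP = 2,
             AK = 30, NH4 = 3, NO3 = 1.5)
  n <- nrow(design)
  shift <- matrix(0, n, length(vars), dimnames = list(design$sample_id, vars))
  for (v in intersect(names(effects), vars))
    shift[, v] <- effects[[v]] * (design$stand_type == "M")
  old <- design$stand_age == max(design$stand_age)
  for (v in nutrients) shift[old, v] <- shift[old, v] + age_effect
  z <- with_seed(seed, {
    sigma <- diag(length(vars))
    dimnames(sigma) <- list(vars, vars)
    sigma[nutrients, nutrients] <- rho
    sigma[c("pH", "SWC"), ] <- rho_phswc
    sigma[, c("pH", "SWC")] <- rho_phswc
    diag(sigma) <- 1
    if (noise_sd > 0)
      MASS::mvrnorm(n, mu = rep(0, length(vars)),
                    Sigma = sigma * noise_sd^2)
    else matrix(0, n, length(vars))
  })
  out <- design
  for (i in seq_along(vars)) {
    v <- vars[i]
    out[[v]] <- base[[v]] + scale[[v]] * (shift[, v] + z[, i])
  }
  out
}

#' Generate a complete synthetic study
#'
#' Composes the phylogeny, metacommunity, trait, soil and community
#' generators into a fully joined study: one bacterial and one fungal
#' OTU table, the two phylogenies, and per-sample metadata. Stand-type
#' groups differ in migration rate, selection strength and environmental
#' optimum (M: higher m, lower s), and a shared per-sample fertility factor
#' induces cooperative positive covariance among a subset of taxa.
#'
#' @param spec a [simulation_spec].
#' @return a list of class `synthetic_study` with elements `bacteria`,
#'   `fungi` ([otu_table]s), `tree_bacteria`, `tree_fungi`, `meta`
#'   (metadata data.frame) and `spec`.
#' @export
generate_study <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  design <- expand.grid(rep = seq_len(spec$replicates),
                        stand_type = spec$stand_types,
                        stand_age = spec$ages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = paste0(design$stand_type, design$stand_age, "_", design$rep),
    stand_type = design$stand_type, stand_age = design$stand_age,
    plot = paste0(design$stand_type, design$stand_age, "_", design$rep),
    stringsAsFactors = FALSE)
  n <- nrow(design)

  meta <- generate_soil_properties(design, effects = spec$soil_effects,
                                   noise_sd = spec$soil_noise_sd,
                                   seed = derive_seed(spec$seed, 1),
                                   rho = spec$soil_cor,
                                   rho_phswc = spec$soil_cor_phswc,
                                   age_effect = spec$soil_age_effect)

  kingdoms <- c("bacteria", "fungi")
  tables <- trees <- list()
  for (k in seq_along(kingdoms)) {
    kd <- kingdoms[k]
    nt <- spec$n_taxa[[kd]]
    base_seed <- derive_seed(spec$seed, 10 * k)
    tree <- generate_phylogeny(nt, derive_seed(base_seed, 1),
                               prefix = paste0(substr(kd, 1, 1), "otu"))
    mc <- generate_metacommunity(nt, derive_seed(base_seed, 2), spec$sdlog)
    names(mc) <- tree$tip.label
    traits <- with_seed(derive_seed(base_seed, 3),
                        ape::rTraitCont(tree, model = "BM",
                                        sigma = spec$bm_sigma))
    traits <- (traits - mean(traits)) / sd(traits)
    loadings <- with_seed(derive_seed(base_seed, 4), {
      l <- numeric(nt)
      on <- runif(nt) < spec$responsive_frac
      l[on] <- runif(sum(on))
      l
    })
    ## interaction guilds: disjoint taxon blocks with a shared latent
    ## factor; membership is abundance-biased so the co-fluctuations are
    ## detectable at survey depth
    guild <- with_seed(derive_seed(base_seed, 6), {
      size <- max(2L, round(spec$block_frac * nt))
      members <- sample.int(nt, min(nt, size * spec$n_blocks),
                            prob = sqrt(mc))
      L <- matrix(0, nt, spec$n_blocks)
      for (b in seq_len(spec$n_blocks)) {
        idx <- members[((b - 1) * size + 1):min(b * size, length(members))]
        L[idx, b] <- runif(length(idx), spec$block_load[1], spec$block_load[2])
      }
      L
    })
    cnt <- with_seed(derive_seed(base_seed, 5), {
      env <- spec$env_optimum[design$stand_type] +
        spec$env_age_shift[design$stand_type] *
          ((design$stand_age == max(spec$ages)) - 0.5) +
        rnorm(n, 0, spec$env_jitter)
      fert <- rnorm(n) * spec$fertility_sd[design$stand_type]
      bsd <- spec$block_sd[design$stand_type]
      gfac <- matrix(rnorm(n * spec$n_blocks), spec$n_blocks, n) *
        rep(bsd, each = spec$n_blocks)
      depth <- if (spec$depth_jitter > 0)
        pmax(100L, as.integer(round(spec$n_reads *
          exp(rnorm(n, 0, spec$depth_jitter))))) else rep(spec$n_reads, n)
      sapply(seq_len(n), function(j) {
        sj <- spec$s[[design$stand_type[j]]]
        w <- mc * exp(-sj * (traits - env[j])^2 + loadings * fert[j] +
                        as.numeric(guild %*% gfac[, j]))
        local_community(w / sum(w), depth[j], spec$m[[design$stand_type[j]]],
                        spec$burnin_factor)
      })
    })
    dimnames(cnt) <- list(tree$tip.label, design$sample_id)
    tables[[kd]] <- otu_table(cnt, kd)
    attr(tables[[kd]], "traits") <- traits
    trees[[kd]] <- tree
  }
  structure(list(bacteria = tables$bacteria, fungi = tables$fungi,
                 tree_bacteria = trees$bacteria, tree_fungi = trees$fungi,
                 meta = meta, spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", ncol(x$bacteria$counts), "samples;",
      nrow(x$bacteria$counts), "bacterial and", nrow(x$fungi$counts),
      "fungal taxa\n")
  invisible(x)
}
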