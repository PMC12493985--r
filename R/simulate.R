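# Synthetic metacommunities and regional chemistry.
#
# The generators target exactly what the inference stages assume: the
# neutral simulator samples the stationary Sloan distribution, the
# selection simulator plants a phylogenetically conserved niche trait with
# Gaussian environmental filtering, and the chemistry simulator draws
# uniformly within the published per-region ranges.

#' Log-series metacommunity relative abundances
#'
#' Fisher log-series shape `p_i proportional to x^i / i` over abundance
#' ranks, normalised to sum to 1; a realistic long-tailed metacommunity.
#'
#' @param n_taxa number of taxa.
#' @param x log-series parameter in (0, 1); closer to 1 = flatter.
#' @return probability vector of length `n_taxa`.
#' @export
metacommunity_logseries <- function(n_taxa, x = 0.999) {
  n_taxa <- assert_count(n_taxa, "n_taxa", lower = 1)
  assert_number(x, "x", lower = 1e-12, upper = 1 - 1e-12)
  i <- seq_len(n_taxa)
  p <- x^i / i
  p / sum(p)
}

#' Simulate a neutral (Sloan) metacommunity
#'
#' Samples the stationary distribution of the neutral model directly: each
#' local community's relative abundances are one draw from
#' `Dirichlet(N m p)` - whose marginals are exactly the
#' `Beta(N m p_i, N m (1 - p_i))` of the occurrence-frequency formula -
#' followed by a multinomial draw of `N` individuals. Occurrence
#' frequencies in the output therefore converge to the model prediction as
#' the number of sites grows.
#'
#' @param n_sites number of local communities.
#' @param n_taxa number of taxa.
#' @param N individuals per local community (>= 1).
#' @param m migration probability in (0, 1].
#' @param metacommunity metacommunity relative abundances (defaults to
#'   [metacommunity_logseries()]).
#' @param seed RNG seed.
#' @return sites x taxa [otu_table()]; the simulation settings are attached as attribute
#'   `"sim_spec"`.
#' @export
simulate_neutral_metacommunity <- function(n_sites, n_taxa, N, m,
                                           metacommunity = NULL, seed = NULL) {
  n_sites <- assert_count(n_sites, "n_sites", lower = 2)
  n_taxa <- assert_count(n_taxa, "n_taxa", lower = 2)
  assert_number(N, "N", lower = 1)
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1) {
    abort("`m` must be a migration probability in (0, 1].")
  }
  p <- metacommunity %||% metacommunity_logseries(n_taxa)
  if (length(p) != n_taxa) abort("Metacommunity vector length != n_taxa.")
  if (abs(sum(p) - 1) > 1e-8) abort("Metacommunity abundances must sum to 1.")
  local_seed(seed)
  nm <- N * m
  counts <- matrix(0L, n_sites, n_taxa,
                   dimnames = list(sprintf("S%03d", seq_len(n_sites)),
                                   sprintf("OTU%05d", seq_len(n_taxa))))
  for (s in seq_len(n_sites)) {
    g <- rgamma(n_taxa, shape = nm * p, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    counts[s, ] <- as.integer(rmultinom(1, size = round(N), prob = g / sum(g)))
  }
  out <- otu_table(counts)
  attr(out, "sim_spec") <- list(model = "neutral", n_sites = n_sites,
                                n_taxa = n_taxa, N = N, m = m, Nm = nm,
                                seed = seed)
  out
}

#' Simulate a selection-structured metacommunity
#'
#' A niche optimum evolves by Brownian motion along a pure-birth tree
#' (rescaled to unit depth), so the trait is phylogenetically conserved.
#' Each site filters taxa with Gaussian weights
#' `w_ij proportional to p_j exp(-(env_i - trait_j)^2 / (2 filter_width^2))`
#' and draws `N` individuals multinomially. Homogeneous mode (one shared
#' environment) produces communities drawn repeatedly from the same
#' filtered clade (homogeneous selection); variable mode places sites in
#' two environment clusters (variable selection between clusters). As
#' `filter_width` grows the filter flattens and selection vanishes.
#'
#' @param n_sites number of sites.
#' @param n_taxa number of taxa (tree tips).
#' @param mode `"homogeneous"` or `"variable"`.
#' @param filter_width Gaussian filter width on the trait scale (smaller =
#'   stronger selection).
#' @param N individuals per site.
#' @param drift_sd standard deviation of per-site lognormal noise on taxon
#'   weights. This is the stochastic (drift/dispersal) component: with no
#'   noise every site would converge on the same filtered assemblage and
#'   there would be no turnover for a null model to judge; with noise,
#'   sites draw different members of the selected clade, the signature of
#'   selection acting on a drifting community.
#' @param bm_sigma Brownian-motion rate for the niche trait.
#' @param trait_delta Pagel-delta-style exponent (< 1) applied to node
#'   heights of the tree copy on which the trait evolves; smaller values
#'   concentrate trait divergence on deep splits and strengthen
#'   phylogenetic niche conservatism. Distances always use the original
#'   tree.
#' @param env optional per-site environment vector (overrides `mode`
#'   defaults; homogeneous mode requires all values equal).
#' @param tree optional `phylo` with `n_taxa` tips (default: pure-birth
#'   tree, unit depth).
#' @param metacommunity base relative abundances before filtering
#'   (default log-series).
#' @param seed RNG seed.
#' @return list: `table` ([otu_table()]), `tree`, `trait`, `env`.
#' @export
simulate_selection_metacommunity <- function(n_sites, n_taxa,
                                             mode = c("homogeneous", "variable"),
                                             filter_width = 0.2, N = 2000,
                                             drift_sd = 1.5, bm_sigma = 1,
                                             trait_delta = 0.1, env = NULL,
                                             tree = NULL, metacommunity = NULL,
                                             seed = NULL) {
  mode <- match.arg(mode)
  n_sites <- assert_count(n_sites, "n_sites", lower = 2)
  n_taxa <- assert_count(n_taxa, "n_taxa", lower = 3)
  assert_number(filter_width, "filter_width", lower = 1e-9)
  local_seed(seed)
  if (is.null(tree)) {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("OTU%05d", seq_len(n_taxa))
  }
  if (length(tree$tip.label) != n_taxa) abort("Tree tips != n_taxa.")
  # Evolve the niche optimum on a depth-compressed copy of the tree
  # (node heights h -> h^trait_delta, delta < 1): trait variance then sits
  # on deep splits, so trait-similar taxa are close relatives - the
  # phylogenetic niche conservatism the betaNTI framework assumes. The
  # returned tree (used for distances) is untransformed.
  trait <- ape::rTraitCont(delta_transform(tree, trait_delta),
                           model = "BM", sigma = bm_sigma)
  trait <- (trait - mean(trait)) / sd(trait)  # unit scale: filter_width is in trait sd
  if (is.null(env)) {
    # a trait extreme isolates a single conserved clade; the centre of the
    # trait range is reachable by many clades and filters weakly
    env <- if (mode == "homogeneous") {
      rep(quantile(trait, 0.9), n_sites)
    } else {
      lo <- quantile(trait, 0.1)
      hi <- quantile(trait, 0.9)
      c(rep(lo, ceiling(n_sites / 2)), rep(hi, floor(n_sites / 2)))
    }
  }
  if (length(env) != n_sites) abort("`env` must have one value per site.")
  if (mode == "homogeneous" && length(unique(env)) != 1) {
    abort("Homogeneous mode requires identical environments.")
  }
  p <- metacommunity %||% metacommunity_logseries(n_taxa, x = 0.999)
  p <- p[sample.int(n_taxa)]  # decouple abundance rank from tree order
  counts <- matrix(0L, n_sites, n_taxa,
                   dimnames = list(sprintf("S%03d", seq_len(n_sites)),
                                   tree$tip.label))
  for (s in seq_len(n_sites)) {
    w <- p * exp(-(env[s] - trait)^2 / (2 * filter_width^2)) *
      exp(stats::rnorm(n_taxa, 0, drift_sd))
    if (sum(w) == 0) w[which.min(abs(env[s] - trait))] <- 1
    counts[s, ] <- as.integer(rmultinom(1, size = N, prob = w / sum(w)))
  }
  list(table = otu_table(counts), tree = tree,
       trait = trait, env = env)
}

# node heights h -> (h/H)^delta * H on an ultrametric tree; delta < 1
# stretches deep branches relative to shallow ones
delta_transform <- function(tree, delta) {
  if (delta == 1) return(tree)
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)  # root-to-node distances
  total <- max(depths)
  heights <- (depths / total)^delta * total
  new_len <- heights[tree$edge[, 2]] - heights[tree$edge[, 1]]
  tree$edge.length <- pmax(new_len, 0)
  tree
}

# published per-region ranges for overlying water (umol/L except chl_a
# ug/L, DO mg/L) and sediments (% dry weight); salinity/temperature are
# package choices needed only for the O2-saturation term
chemistry_ranges <- function(region) {
  switch(region,
    YRE = list(
      water = list(ammonia = c(7.43, 15.21), nitrite = c(0.29, 2.21),
                   nitrate = c(1.29, 129.21), phosphate = c(0.05, 3.19),
                   silicate = c(14.27, 118.29), chl_a = c(0.12, 0.95),
                   do = c(0.59, 4.34), salinity = c(25, 32),
                   temperature = c(18, 26)),
      sediment = list(toc = c(0.63, 2.87), tn = c(0.15, 0.49))),
    ECS = list(
      water = list(ammonia = c(0.07, 2.36), nitrite = c(0.20, 0.48),
                   nitrate = c(1.02, 4.97), phosphate = c(0.02, 0.33),
                   silicate = c(0.25, 12.06), chl_a = c(0.2, 0.65),
                   do = c(3.0, 10.4), salinity = c(32, 34.5),
                   temperature = c(18, 26)),
      sediment = list(toc = c(0.06, 1.10), tn = c(0.05, 0.20))),
    abort(sprintf("Unknown region '%s' (use YRE or ECS).", region))
  )
}

#' Simulate regional water and sediment chemistry
#'
#' Independent uniform draws within the published per-region ranges for the
#' Yangtze River Estuary (YRE, eutrophic) and East China Sea (ECS,
#' oligotrophic): nutrients and silicate in umol/L, chlorophyll-a in ug/L,
#' DO in mg/L, sediment TOC/TN in percent dry weight. Ranges are the only
#' published constraint, so no cross-variable correlation is imposed.
#'
#' @param region `"YRE"` or `"ECS"`.
#' @param n_sites number of sites (0 gives empty tables).
#' @param seed RNG seed.
#' @return list of tibbles `water` and `sediment` sharing `site_id`.
#' @export
simulate_chemistry <- function(region, n_sites, seed = NULL) {
  if (length(region) != 1 || !region %in% c("YRE", "ECS")) {
    abort(sprintf("Unknown region '%s' (use YRE or ECS).", paste(region)))
  }
  n_sites <- assert_count(n_sites, "n_sites", lower = 0)
  rng <- chemistry_ranges(region)
  local_seed(seed)
  ids <- if (n_sites > 0) sprintf("%s%03d", region, seq_len(n_sites)) else character(0)
  draw <- function(r) if (n_sites > 0) runif(n_sites, r[1], r[2]) else numeric(0)
  water <- tibble(site_id = ids, region = rep(region, n_sites))
  for (nm in names(rng$water)) water[[nm]] <- draw(rng$water[[nm]])
  sediment <- tibble(site_id = ids, region = rep(region, n_sites))
  for (nm in names(rng$sediment)) sediment[[nm]] <- draw(rng$sediment[[nm]])
  list(water = water, sediment = sediment)
}
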