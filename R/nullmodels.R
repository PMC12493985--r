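# betaMNTD / betaNTI / Raup-Crick (Bray-Curtis) null models

# nearest-taxon turnover for one site pair given a patristic matrix `d`
# indexed in table column order; weights are relative abundances
bmntd_pair <- function(idx1, idx2, w1, w2, d) {
  d12 <- d[idx1, idx2, drop = FALSE]
  min1 <- apply(d12, 1, min)  # each taxon in site 1 -> nearest in site 2
  min2 <- apply(d12, 2, min)
  if (is.null(w1)) {
    # presence: pooled mean over both communities' nearest-taxon distances
    mean(c(min1, min2))
  } else {
    # abundance: relative abundances weight each direction equally
    0.5 * (sum(w1 * min1) + sum(w2 * min2))
  }
}

table_tree_dist <- function(table, tree) {
  mism <- match_tree_otus(tree, table)
  if (length(mism$missing_in_tree)) {
    abort(sprintf("Tree lacks tips for OTUs: %s%s",
                  paste(head(mism$missing_in_tree, 5), collapse = ", "),
                  if (length(mism$missing_in_tree) > 5) ", ..." else ""))
  }
  ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each site pair, each taxon's patristic distance to its nearest taxon
#' in the other community is averaged (abundance-weighted by default) in
#' both directions and the two directions are averaged.
#'
#' @param table OTU table (sites x OTUs).
#' @param tree `phylo` with branch lengths covering all table OTUs.
#' @param weighting `"abundance"` (default) or `"presence"`.
#' @return symmetric site x site matrix, diagonal `NA`.
#' @export
beta_mntd <- function(table, tree, weighting = c("abundance", "presence")) {
  weighting <- match.arg(weighting)
  m <- unclass(table)
  d <- table_tree_dist(table, tree)
  site_idx <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] > 0))
  if (any(lengths(site_idx) == 0)) abort("Site with zero taxa.")
  site_w <- lapply(seq_len(nrow(m)), function(i) {
    if (weighting == "presence") NULL else {
      x <- m[i, site_idx[[i]]]
      x / sum(x)
    }
  })
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <-
        bmntd_pair(site_idx[[i]], site_idx[[j]], site_w[[i]], site_w[[j]], d)
    }
  }
  out
}

#' beta nearest taxon index (betaNTI)
#'
#' Z-score of the observed betaMNTD of each site pair against a null built
#' by shuffling taxon identities across the tips of the phylogeny. With
#' `null_pool = "tree"` (default) one permutation of the full regional taxa
#' pool is drawn per replicate and applied to every pair, the behaviour of
#' the framework's reference implementation; `null_pool = "pair"` restricts
#' the shuffle to each pair's union of taxa (a much weaker null, retained
#' for comparison). `|betaNTI| > 2` indicates deterministic selection:
#' above +2 variable selection, below -2 homogeneous selection.
#'
#' @inheritParams beta_mntd
#' @param reps number of randomizations (default 999).
#' @param seed RNG seed for reproducible nulls.
#' @return symmetric site x site matrix of z-scores, diagonal `NA`; pairs
#'   with a degenerate null (sd = 0) are `NA` and counted in attribute
#'   `"n_degenerate"`.
#' @export
bnti <- function(table, tree, reps = 999, seed = NULL,
                 weighting = c("abundance", "presence"),
                 null_pool = c("tree", "pair")) {
  weighting <- match.arg(weighting)
  null_pool <- match.arg(null_pool)
  reps <- assert_count(reps, "reps", lower = 1)
  local_seed(seed)
  m <- unclass(table)
  d <- table_tree_dist(table, tree)
  n <- nrow(m)
  ntaxa <- ncol(m)
  site_idx <- lapply(seq_len(n), function(i) which(m[i, ] > 0))
  if (any(lengths(site_idx) == 0)) abort("Site with zero taxa.")
  site_w <- lapply(seq_len(n), function(i) {
    if (weighting == "presence") NULL else {
      x <- m[i, site_idx[[i]]]
      x / sum(x)
    }
  })
  pairs <- upper_pairs(n)
  obs <- apply(pairs, 1, function(pr) {
    bmntd_pair(site_idx[[pr[1]]], site_idx[[pr[2]]],
               site_w[[pr[1]]], site_w[[pr[2]]], d)
  })
  null_mat <- matrix(NA_real_, nrow(pairs), reps)
  if (null_pool == "tree") {
    for (r in seq_len(reps)) {
      perm <- sample.int(ntaxa)
      null_mat[, r] <- apply(pairs, 1, function(pr) {
        bmntd_pair(perm[site_idx[[pr[1]]]], perm[site_idx[[pr[2]]]],
                   site_w[[pr[1]]], site_w[[pr[2]]], d)
      })
    }
  } else {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      u <- union(site_idx[[i]], site_idx[[j]])
      pos1 <- match(site_idx[[i]], u)
      pos2 <- match(site_idx[[j]], u)
      for (r in seq_len(reps)) {
        pu <- u[sample.int(length(u))]
        null_mat[k, r] <- bmntd_pair(pu[pos1], pu[pos2],
                                     site_w[[i]], site_w[[j]], d)
      }
    }
  }
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  out[pairs] <- z
  out[pairs[, 2:1, drop = FALSE]] <- z
  attr(out, "n_degenerate") <- sum(sdv == 0)
  attr(out, "reps") <- reps
  attr(out, "null_pool") <- null_pool
  out
}

# one null assemblage per site: richness fixed by occurrence-frequency
# draws, abundances filled by individual draws from metacommunity relative
# abundance (the Bray-Curtis-extended Raup-Crick construction)
rc_null_matrix <- function(richness, totals, occ_freq, meta_rel) {
  ntaxa <- length(occ_freq)
  null <- matrix(0L, length(richness), ntaxa)
  for (i in seq_along(richness)) {
    chosen <- sample.int(ntaxa, richness[i], prob = occ_freq)
    counts <- rep(1L, richness[i])
    extra <- totals[i] - richness[i]
    if (extra > 0) {
      counts <- counts + as.integer(rmultinom(1, extra, prob = meta_rel[chosen]))
    }
    null[i, chosen] <- counts
  }
  null
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' For each site pair the observed Bray-Curtis dissimilarity is ranked
#' against `reps` null pairs. Null assemblages preserve each site's
#' observed richness and total abundance; taxa are drawn with probability
#' proportional to their metacommunity occurrence frequency and abundances
#' filled proportional to metacommunity relative abundance.
#' `RC = ((#null < obs) + 0.5 (#null = obs)) / reps`, rescaled to -1..1 by
#' `2 (RC - 0.5)`. `RC > 0.95` indicates dispersal limitation, `RC < -0.95`
#' homogenizing dispersal.
#'
#' @param table OTU table (sites x OTUs).
#' @param reps number of null replicates (default 999).
#' @param seed RNG seed.
#' @return symmetric site x site matrix in -1..1, diagonal `NA`.
#' @export
rc_bray <- function(table, reps = 999, seed = NULL) {
  reps <- assert_count(reps, "reps", lower = 1)
  local_seed(seed)
  m <- unclass(table)
  if (any(rowSums(m) <= 0)) abort("Positive row totals required.")
  n <- nrow(m)
  richness <- rowSums(m > 0)
  totals <- rowSums(m)
  occ_freq <- colMeans(m > 0)
  meta_rel <- colSums(m) / sum(m)
  present <- occ_freq > 0
  obs <- as.matrix(vegan::vegdist(m, method = "bray"))
  pairs <- upper_pairs(n)
  obs_v <- obs[pairs]
  less <- numeric(nrow(pairs))
  equal <- numeric(nrow(pairs))
  for (r in seq_len(reps)) {
    null <- rc_null_matrix(richness, totals, occ_freq[present],
                           meta_rel[present])
    bc <- as.matrix(vegan::vegdist(null, method = "bray"))[pairs]
    less <- less + (bc < obs_v - 1e-12)
    equal <- equal + (abs(bc - obs_v) <= 1e-12)
  }
  rc <- 2 * ((less + 0.5 * equal) / reps - 0.5)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  out[pairs] <- rc
  out[pairs[, 2:1, drop = FALSE]] <- rc
  attr(out, "reps") <- reps
  out
}

#' Partition site pairs into five assembly processes
#'
#' `betaNTI > 2`: variable selection; `betaNTI < -2`: homogeneous
#' selection; otherwise `RC > 0.95`: dispersal limitation; `RC < -0.95`:
#' homogenizing dispersal; else undominated. Pairs with undefined betaNTI
#' are excluded and reported.
#'
#' @param bnti_matrix site x site betaNTI matrix ([bnti()]).
#' @param rc_matrix site x site RC matrix ([rc_bray()]), same site order.
#' @param bnti_threshold selection threshold (default 2).
#' @param rc_threshold dispersal threshold (default 0.95).
#' @return tibble (process, n_pairs, fraction) covering all five processes;
#'   fractions sum to 1 over classified pairs. Attribute `"n_excluded"`
#'   counts pairs dropped for undefined betaNTI.
#' @export
classify_processes <- function(bnti_matrix, rc_matrix,
                               bnti_threshold = 2, rc_threshold = 0.95) {
  if (!all(dim(bnti_matrix) == dim(rc_matrix))) {
    abort("betaNTI and RC matrices must have matching site sets.")
  }
  pairs <- upper_pairs(nrow(bnti_matrix))
  b <- bnti_matrix[pairs]
  r <- rc_matrix[pairs]
  ok <- !is.na(b)
  n_excluded <- sum(!ok)
  b <- b[ok]
  r <- r[ok]
  proc <- dplyr::case_when(
    b > bnti_threshold ~ "variable_selection",
    b < -bnti_threshold ~ "homogeneous_selection",
    r > rc_threshold ~ "dispersal_limitation",
    r < -rc_threshold ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
  lv <- c("variable_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "undominated")
  tab <- table(factor(proc, levels = lv))
  out <- tibble(process = lv, n_pairs = as.integer(tab),
                fraction = as.numeric(tab) / max(sum(tab), 1L))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Full assembly-process analysis of an OTU table
#'
#' Convenience wrapper running [bnti()], [rc_bray()] and
#' [classify_processes()] with shared settings.
#'
#' @inheritParams bnti
#' @return list with `bnti`, `rc_bray`, `fractions` and the settings used.
#' @export
assembly_processes <- function(table, tree, reps = 999, seed = NULL,
                               weighting = c("abundance", "presence"),
                               null_pool = c("tree", "pair")) {
  weighting <- match.arg(weighting)
  null_pool <- match.arg(null_pool)
  b <- bnti(table, tree, reps = reps, seed = seed, weighting = weighting,
            null_pool = null_pool)
  r <- rc_bray(table, reps = reps,
               seed = if (is.null(seed)) NULL else seed + 1L)
  list(bnti = b, rc_bray = r, fractions = classify_processes(b, r),
       settings = list(reps = reps, seed = seed, weighting = weighting,
                       null_pool = null_pool))
}
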