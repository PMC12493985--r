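#' Per-site alpha diversity
#'
#' Observed richness, Chao1, Shannon (natural log by default) and the
#' Gini-Simpson index (1 - sum p^2). Shannon and Simpson are delegated to
#' [vegan::diversity()]; Chao1 is computed here so both the bias-corrected
#' form `S_obs + F1(F1-1)/(2(F2+1))` (default; finite at F2 = 0) and the
#' classical `S_obs + F1^2/(2 F2)` are available.
#'
#' @param table OTU table (sites x OTUs), see [otu_table()].
#' @param shannon_base log base for Shannon (default `exp(1)`, nats).
#' @param chao1 `"bias_corrected"` (default) or `"classical"`.
#' @return tibble: site_id, observed_richness, chao1, shannon, simpson.
#' @export
alpha_diversity <- function(table, shannon_base = exp(1),
                            chao1 = c("bias_corrected", "classical")) {
  chao1 <- match.arg(chao1)
  m <- unclass(table)
  if (any(rowSums(m) <= 0)) abort("Empty site row: alpha diversity undefined.")
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  sobs <- rowSums(m > 0)
  chao <- if (chao1 == "bias_corrected") {
    sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    ifelse(f2 > 0, sobs + f1^2 / (2 * f2), sobs + f1 * (f1 - 1) / 2)
  }
  tibble(
    site_id = rownames(m),
    observed_richness = as.integer(unname(sobs)),
    chao1 = unname(chao),
    shannon = unname(vegan::diversity(m, index = "shannon", base = shannon_base)),
    simpson = unname(vegan::diversity(m, index = "simpson"))
  )
}

#' Levins niche breadth per OTU and community-level mean
#'
#' `B_j = 1 / sum_i P_ij^2` with `P_ij` the share of OTU j's total found at
#' site i (Levins' convention, giving the documented range 1..n_sites:
#' 1 for a single-site specialist, n_sites for a perfectly even generalist).
#' `Bcom` is the unweighted mean over included OTUs; zero-total OTUs are
#' excluded with a warning.
#'
#' @param table OTU table (sites x OTUs).
#' @return tibble of per-OTU `b` with attributes `bcom` (mean) and
#'   `n_sites`; also accessible via [glance()]-free helpers `attr(x, "bcom")`.
#' @export
niche_breadth <- function(table) {
  m <- unclass(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    rlang::inform(sprintf("%d zero-total OTUs excluded from niche breadth.",
                          sum(tot == 0)))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(m, 2, tot, "/")
  b <- 1 / colSums(p^2)
  out <- tibble(otu = colnames(m), b = unname(b))
  attr(out, "bcom") <- mean(b)
  attr(out, "n_sites") <- nrow(m)
  out
}

#' Community-level habitat niche breadth
#'
#' @param table OTU table.
#' @return scalar `Bcom`, the mean Levins breadth across OTUs.
#' @export
bcom <- function(table) attr(niche_breadth(table), "bcom")

#' Bray-Curtis dissimilarity between sites
#'
#' @param table OTU table (sites x OTUs).
#' @param transform `"counts"` (raw) or `"relative"` (rows normalised to 1
#'   before the distance).
#' @return symmetric site x site matrix with zero diagonal, entries in 0..1.
#' @export
bray_curtis <- function(table, transform = c("counts", "relative")) {
  transform <- match.arg(transform)
  m <- unclass(table)
  if (any(rowSums(m) <= 0)) abort("Positive row totals required.")
  if (transform == "relative") m <- m / rowSums(m)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Great-circle distance between sites
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param sites data frame with `site_id`, `latitude`, `longitude`
#'   (decimal degrees).
#' @return symmetric site x site matrix of distances in km.
#' @export
geographic_distance <- function(sites) {
  sites <- as_tibble(sites)
  assert_number(sites$latitude, "latitude", lower = -90, upper = 90)
  assert_number(sites$longitude, "longitude", lower = -180, upper = 180)
  if (anyDuplicated(sites$site_id)) abort("site_id must be unique.")
  xy <- cbind(sites$longitude, sites$latitude)
  n <- nrow(xy)
  d <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(xy[i, , drop = FALSE], xy,
                                       r = 6371000) / 1000
  }
  (d + t(d)) / 2  # enforce exact symmetry against fp noise
}

#' Distance-decay regression of community similarity
#'
#' Ordinary least-squares fit of Bray-Curtis similarity (1 - dissimilarity)
#' on geographic distance over all unordered site pairs.
#'
#' @param similarity site x site similarity matrix (or dissimilarity with
#'   `is_dissimilarity = TRUE`).
#' @param distance_km site x site distance matrix, same site order.
#' @param is_dissimilarity set `TRUE` to pass a dissimilarity matrix.
#' @return one-row tibble: slope (similarity per km), intercept, r_squared,
#'   n_pairs; the pairwise data are attached as attribute `"pairs"`.
#' @export
distance_decay <- function(similarity, distance_km, is_dissimilarity = FALSE) {
  if (!all(dim(similarity) == dim(distance_km))) {
    abort("Similarity and distance matrices must match.")
  }
  if (is_dissimilarity) similarity <- 1 - similarity
  iu <- upper.tri(similarity)
  df <- tibble(distance_km = distance_km[iu], similarity = similarity[iu])
  if (nrow(df) < 3) abort("Need at least 3 site pairs for a regression.")
  fit <- lm(similarity ~ distance_km, data = df)
  r2 <- if (stats::var(df$similarity) == 0) 0 else summary(fit)$r.squared
  out <- tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                r_squared = r2, n_pairs = nrow(df))
  attr(out, "pairs") <- df
  out
}

#' Mean pairwise phylogenetic distance per site
#'
#' Unweighted: mean patristic distance over unordered pairs of taxa present
#' at the site. Abundance-weighted: the Rao-style double sum
#' `sum_{i,j} w_i w_j d_ij` over all ordered pairs (diagonal zero), with
#' `w` the site's relative abundances. Sites with fewer than two taxa are
#' reported as `NA`.
#'
#' @param table OTU table (sites x OTUs).
#' @param tree `phylo` covering all table OTUs.
#' @param weighting `"abundance"` (default) or `"presence"`.
#' @return tibble: site_id, mpd.
#' @export
phylo_distance <- function(table, tree, weighting = c("abundance", "presence")) {
  weighting <- match.arg(weighting)
  m <- unclass(table)
  mism <- match_tree_otus(tree, table)
  if (length(mism$missing_in_tree)) {
    abort(sprintf("OTUs missing from tree: %s",
                  paste(head(mism$missing_in_tree, 5), collapse = ", ")))
  }
  d <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  mpd_one <- function(x) {
    idx <- which(x > 0)
    if (length(idx) < 2) return(NA_real_)
    dd <- d[idx, idx]
    if (weighting == "presence") {
      mean(dd[upper.tri(dd)])
    } else {
      w <- x[idx] / sum(x[idx])
      as.numeric(t(w) %*% dd %*% w)
    }
  }
  tibble(site_id = rownames(m), mpd = unname(apply(m, 1, mpd_one)))
}
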