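test_that("alpha diversity matches hand-computed limits", {
  m <- matrix(c(10L, 0L, 0L), 1, 3,
              dimnames = list("s1", c("a", "b", "c")))
  one <- alpha_diversity(otu_table(m))
  expect_equal(one$observed_richness, 1L)
  expect_equal(one$shannon, 0)
  expect_equal(one$simpson, 0)

  u <- matrix(rep(5L, 10), 1, 10,
              dimnames = list("s1", paste0("o", 1:10)))
  uni <- alpha_diversity(otu_table(u))
  expect_equal(uni$shannon, log(10), tolerance = 1e-12)
  expect_equal(uni$shannon, 2.302585, tolerance = 1e-6)
  expect_equal(uni$simpson, 1 - 10 * 0.1^2)
  # configurable base
  expect_equal(alpha_diversity(otu_table(u), shannon_base = 2)$shannon,
               log2(10))
})

test_that("Chao1 reproduces the bias-corrected formula and bounds", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/(2*3) = 12
  counts <- c(1L, 1L, 1L, 1L, 2L, 2L, 5L, 6L, 7L, 8L)
  m <- matrix(counts, 1, 10, dimnames = list("s1", paste0("o", 1:10)))
  res <- alpha_diversity(otu_table(m))
  expect_equal(res$chao1, 12)
  classical <- alpha_diversity(otu_table(m), chao1 = "classical")
  expect_equal(classical$chao1, 10 + 16 / 4)

  for (seed in 1:5) {
    tab <- make_otu_table(8, 40, seed = seed)
    a <- alpha_diversity(tab)
    expect_true(all(a$chao1 >= a$observed_richness))
    # bias-corrected form adds F1(F1-1)/(2(F2+1)): zero iff F1 <= 1
    f1 <- rowSums(unclass(tab) == 1)
    expect_equal(a$chao1 == a$observed_richness, unname(f1 <= 1))
  }
})

test_that("Chao1 agrees with the vegan implementation", {
  tab <- make_otu_table(6, 60, seed = 3)
  ours <- alpha_diversity(tab)$chao1
  veg <- t(vegan::estimateR(unclass(tab)))[, "S.chao1"]
  expect_equal(ours, unname(veg), tolerance = 1e-8)
})

test_that("Levins niche breadth hits its limits and stays in bounds", {
  m <- matrix(0L, 5, 3, dimnames = list(paste0("s", 1:5), c("sp", "ev", "mid")))
  m[1, "sp"] <- 10L          # single-site specialist
  m[, "ev"] <- 4L            # perfectly even generalist
  m[, "mid"] <- c(2L, 1L, 1L, 0L, 0L)
  nb <- niche_breadth(otu_table(m))
  expect_equal(nb$b[nb$otu == "sp"], 1)
  expect_equal(nb$b[nb$otu == "ev"], 5)
  # P = (0.5, 0.25, 0.25) -> 1/0.375
  expect_equal(nb$b[nb$otu == "mid"], 1 / 0.375)
  expect_equal(nb$b[nb$otu == "mid"], 2.6667, tolerance = 1e-4)
  expect_equal(attr(nb, "bcom"), mean(nb$b))

  for (seed in 1:10) {
    tab <- make_otu_table(7, 30, seed = seed)
    b <- niche_breadth(tab)$b
    expect_true(all(b >= 1 - 1e-12 & b <= 7 + 1e-12))
  }
})

test_that("niche breadth is invariant to per-OTU rescaling", {
  tab <- make_otu_table(6, 20, seed = 4)
  m <- unclass(tab)
  m[, 3] <- m[, 3] * 7L
  expect_equal(bcom(otu_table(m)), bcom(tab))
})

test_that("Bray-Curtis behaves as a bounded dissimilarity", {
  m <- matrix(c(6L, 2L, 2L, 6L, 3L, 3L), 3, 2, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("a", "b")))
  d <- bray_curtis(otu_table(m), transform = "relative")
  expect_equal(d["x", "y"], 0.5)
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  expect_equal(d, t(d))

  disj <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
                 dimnames = list(c("x", "y"), c("a", "b")))
  expect_equal(bray_curtis(otu_table(disj))["x", "y"], 1)
  same <- matrix(c(3L, 3L, 2L, 2L), 2, 2,
                 dimnames = list(c("x", "y"), c("a", "b")))
  expect_equal(bray_curtis(otu_table(same))["x", "y"], 0)
  tab <- make_otu_table(6, 25, seed = 5)
  d <- bray_curtis(tab)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("great-circle distances use a 6371 km sphere", {
  sites <- tibble::tibble(site_id = c("o", "e", "n"),
                          latitude = c(0, 0, 1), longitude = c(0, 1, 0))
  d <- geographic_distance(sites)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "e"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(d["o", "e"], 111.19, tolerance = 1e-3)
  expect_equal(d, t(d))
})

test_that("distance-decay regression recovers known relationships", {
  n <- 10
  dm <- matrix(runif(n * n, 0, 800), n, n)
  dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  const <- matrix(0.7, n, n)
  flat <- distance_decay(const, dm)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  col <- 0.9 - 0.0005 * dm
  exact <- suppressWarnings(distance_decay(col, dm))  # perfect-fit warning
  expect_equal(exact$slope, -0.0005, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1)

  withr::with_seed(77, {
    sim <- 0.8 - 0.001 * dm + matrix(rnorm(n * n, 0, 0.01), n, n)
    sim <- (sim + t(sim)) / 2
  })
  noisy <- distance_decay(sim, dm)
  expect_equal(noisy$slope, -0.001, tolerance = 0.05)
  expect_error(distance_decay(matrix(1, 2, 2), matrix(0, 2, 2)), "3 site pairs")
})

test_that("mean pairwise phylogenetic distance handles both weightings", {
  # two tips at patristic distance 2
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(5L, 5L, 10L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("both", "solo"), c("A", "B")))
  w <- phylo_distance(otu_table(m), tr, weighting = "abundance")
  expect_equal(w$mpd[w$site_id == "both"], 1.0)  # 2 * 2 * (0.5 * 0.5)
  expect_true(is.na(w$mpd[w$site_id == "solo"]))
  u <- phylo_distance(otu_table(m), tr, weighting = "presence")
  expect_equal(u$mpd[u$site_id == "both"], 2)

  # star tree: unweighted MPD = 2b for any >= 2-taxon site
  star <- ape::read.tree(text = "(A:0.4,B:0.4,C:0.4,D:0.4);")
  sm <- matrix(c(1L, 1L, 1L, 0L, 3L, 1L, 0L, 0L), 2, 4, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  su <- phylo_distance(otu_table(sm), star, weighting = "presence")
  expect_equal(su$mpd, c(0.8, 0.8))
})

test_that("unweighted MPD agrees with picante", {
  skip_if_not_installed("picante")
  tab <- make_otu_table(5, 16, seed = 6)
  tr <- make_tree(16, seed = 6)
  ours <- phylo_distance(tab, tr, weighting = "presence")
  pic <- picante::mpd(unclass(tab), ape::cophenetic.phylo(tr)[colnames(tab), colnames(tab)])
  expect_equal(ours$mpd, pic, tolerance = 1e-10)
})
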