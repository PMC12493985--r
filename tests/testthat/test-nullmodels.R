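test_that("betaMNTD matches hand-computable cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # identical communities: every nearest-taxon distance is zero
  m <- matrix(c(3L, 2L, 1L, 3L, 2L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  bm <- beta_mntd(otu_table(m), tr)
  expect_equal(bm["s1", "s2"], 0)
  expect_true(is.na(bm["s1", "s1"]))

  # monodominant communities on tips at patristic distance 2
  m2 <- matrix(c(10L, 0L, 0L, 0L, 10L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_equal(beta_mntd(otu_table(m2), tr)["s1", "s2"], 2)
  m3 <- matrix(c(10L, 0L, 0L, 0L, 0L, 10L), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_equal(beta_mntd(otu_table(m3), tr)["s1", "s2"], 4)
})

test_that("betaMNTD agrees with picante::comdistnt in both weightings", {
  skip_if_not_installed("picante")
  for (seed in 1:3) {
    tab <- make_otu_table(5, 12, seed = seed)
    tr <- make_tree(12, seed = seed)
    d <- ape::cophenetic.phylo(tr)[colnames(tab), colnames(tab)]
    for (weighted in c(TRUE, FALSE)) {
      ours <- beta_mntd(tab, tr,
                        weighting = if (weighted) "abundance" else "presence")
      ref <- as.matrix(picante::comdistnt(unclass(tab), d,
                                          abundance.weighted = weighted))
      expect_equal(ours[upper.tri(ours)], ref[upper.tri(ref)],
                   tolerance = 1e-10)
    }
  }
})

test_that("adding a shared taxon never raises presence betaMNTD", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      tr <- make_tree(8, seed = seed)
      m <- matrix(0L, 2, 8, dimnames = list(c("s1", "s2"), tr$tip.label))
      m[1, sample(8, 3)] <- 1L
      m[2, sample(8, 3)] <- 1L
      if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1L
      before <- beta_mntd(otu_table(m), tr, weighting = "presence")["s1", "s2"]
      free <- which(m[1, ] == 0 & m[2, ] == 0)
      if (length(free) == 0) succeed()
      else {
        m[, free[1]] <- 1L
        after <- beta_mntd(otu_table(m), tr, weighting = "presence")["s1", "s2"]
        expect_lte(after, before + 1e-12)
      }
    })
  }
})

test_that("betaNTI is reproducible and flags degenerate nulls", {
  tab <- make_otu_table(5, 15, seed = 4)
  tr <- make_tree(15, seed = 4)
  b1 <- bnti(tab, tr, reps = 99, seed = 10)
  b2 <- bnti(tab, tr, reps = 99, seed = 10)
  expect_identical(b1, b2)
  b3 <- bnti(tab, tr, reps = 99, seed = 11)
  expect_false(identical(b1[1, 2], b3[1, 2]))

  # all sites identical: observed and all nulls coincide, sd = 0
  same <- matrix(rep(c(5L, 3L, 2L, 0L, 0L), each = 3), 3, 5,
                 dimnames = list(paste0("s", 1:3), tr$tip.label[1:5]))
  tr5 <- ape::keep.tip(tr, tr$tip.label[1:5])
  bd <- bnti(otu_table(same), tr5, reps = 49, seed = 1)
  expect_true(all(is.na(bd[upper.tri(bd)])))
  expect_equal(attr(bd, "n_degenerate"), 3)
})

test_that("pair-pool nulls are available and differ from tree-pool", {
  tab <- make_otu_table(4, 20, seed = 6)
  tr <- make_tree(20, seed = 6)
  bt <- bnti(tab, tr, reps = 99, seed = 2, null_pool = "tree")
  bp <- bnti(tab, tr, reps = 99, seed = 2, null_pool = "pair")
  expect_equal(attr(bp, "null_pool"), "pair")
  expect_false(isTRUE(all.equal(bt[upper.tri(bt)], bp[upper.tri(bp)])))
})

test_that("Raup-Crick ranks observed dissimilarity against its null", {
  # two identical sites: observed BC = 0, below every plausible null
  m <- matrix(c(8L, 4L, 2L, 1L, 8L, 4L, 2L, 1L, 1L, 2L, 4L, 8L), 3, 4,
              byrow = TRUE, dimnames = list(paste0("s", 1:3), paste0("o", 1:4)))
  rc <- rc_bray(otu_table(m), reps = 199, seed = 5)
  # nearly every null pair is more dissimilar than two identical sites
  # (ties at BC = 0 keep the score a shade above the -1 floor)
  expect_lt(rc["s1", "s2"], -0.9)
  expect_true(all(rc[upper.tri(rc)] >= -1 & rc[upper.tri(rc)] <= 1))
  expect_true(is.na(rc["s1", "s1"]))
  expect_equal(rc, t(rc))
  expect_error(rc_bray(otu_table(m), reps = 0), "reps")

  r1 <- rc_bray(otu_table(m), reps = 99, seed = 9)
  r2 <- rc_bray(otu_table(m), reps = 99, seed = 9)
  expect_identical(r1, r2)
})

test_that("neutral metacommunities sit inside the Raup-Crick band", {
  tab <- simulate_neutral_metacommunity(12, 300, N = 10000, m = 0.5, seed = 15)
  rc <- rc_bray(tab, reps = 199, seed = 16)
  expect_gt(mean(abs(rc[upper.tri(rc)]) <= 0.95), 0.5)
})

test_that("process classification follows the decision thresholds", {
  b <- matrix(NA_real_, 4, 4)
  r <- matrix(NA_real_, 4, 4)
  # pairs (1,2): bnti -3; (1,3): bnti 3; (1,4): bnti 1, rc 0.99;
  # (2,3): bnti 0, rc 0; (2,4): bnti 0, rc -0.99; (3,4): NA bnti
  b[1, 2] <- -3; b[1, 3] <- 3; b[1, 4] <- 1; b[2, 3] <- 0; b[2, 4] <- 0
  r[1, 4] <- 0.99; r[2, 3] <- 0; r[2, 4] <- -0.99
  res <- classify_processes(b, r)
  get <- function(p) res$n_pairs[res$process == p]
  expect_equal(get("homogeneous_selection"), 1L)
  expect_equal(get("variable_selection"), 1L)
  expect_equal(get("dispersal_limitation"), 1L)
  expect_equal(get("homogenizing_dispersal"), 1L)
  expect_equal(get("undominated"), 1L)
  expect_equal(sum(res$fraction), 1)
  expect_equal(attr(res, "n_excluded"), 1L)
})

test_that("raising the selection threshold never raises selection fractions", {
  tab <- make_otu_table(6, 30, seed = 21)
  tr <- make_tree(30, seed = 21)
  b <- bnti(tab, tr, reps = 99, seed = 22)
  rc <- rc_bray(tab, reps = 99, seed = 23)
  sel_frac <- function(thr) {
    res <- classify_processes(b, rc, bnti_threshold = thr)
    sum(res$fraction[res$process %in% c("variable_selection",
                                        "homogeneous_selection")])
  }
  expect_lte(sel_frac(2.5), sel_frac(2))
  expect_lte(sel_frac(2), sel_frac(1))
})

test_that("the assembly wrapper returns coherent pieces", {
  tab <- make_otu_table(5, 25, seed = 30)
  tr <- make_tree(25, seed = 30)
  res <- assembly_processes(tab, tr, reps = 49, seed = 31)
  expect_named(res, c("bnti", "rc_bray", "fractions", "settings"))
  expect_equal(sum(res$fractions$fraction), 1)
  expect_s3_class(plot_process_fractions(res$fractions), "ggplot")
})
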