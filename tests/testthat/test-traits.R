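mk_markers <- function(cov, sample_id = "S1") {
  tibble::tibble(sample_id = sample_id,
                 marker_id = sprintf("USCG%02d", seq_along(cov)),
                 mean_coverage = cov)
}

test_that("genome equivalents aggregate marker coverage", {
  expect_equal(genome_equivalents(mk_markers(rep(7, 35)))$genome_equivalents, 7)
  mixed <- mk_markers(c(rep(10, 34), 45))
  expect_equal(genome_equivalents(mixed)$genome_equivalents, 11)
  expect_equal(genome_equivalents(mixed, aggregation = "trimmed_mean")$genome_equivalents,
               10)
  expect_warning(genome_equivalents(mk_markers(rep(5, 20))), "fewer than 35")
  expect_error(suppressWarnings(genome_equivalents(mk_markers(rep(0, 35)))),
               "zero")
})

test_that("16S copy number divides summed 16S coverage by genome count", {
  ge <- tibble::tibble(sample_id = "S1", genome_equivalents = 10)
  cat0 <- tibble::tibble(sample_id = "S1", gene_id = "g1", label = "other",
                         length = 900, mean_coverage = 5)
  expect_equal(avg_16s_copy_number(cat0, ge)$avg_16s_copies, 0)
  cat1 <- tibble::tibble(sample_id = "S1", gene_id = c("a", "b"),
                         label = c("rrna16S", "rrna16S"), length = 1500,
                         mean_coverage = c(20, 7.5))
  expect_equal(avg_16s_copy_number(cat1, ge)$avg_16s_copies, 2.75)
  expect_error(avg_16s_copy_number(cat1,
    tibble::tibble(sample_id = "S1", genome_equivalents = 0)), "positive")
})

test_that("average genome size divides total bp by genome count", {
  ge <- tibble::tibble(sample_id = "S1", genome_equivalents = 10)
  bp <- tibble::tibble(sample_id = "S1", total_bp = 5.59e7)
  expect_equal(avg_genome_size(bp, ge)$avg_genome_size, 5.59e6)
  expect_error(avg_genome_size(bp,
    tibble::tibble(sample_id = "S1", genome_equivalents = 0)), "positive")
})

test_that("GC content excludes ambiguous bases explicitly", {
  expect_equal(as.numeric(gc_content("GGCC")), 1)
  expect_equal(as.numeric(gc_content("ATAT")), 0)
  g <- gc_content("ATGCNN")
  expect_equal(as.numeric(g), 0.5)
  expect_equal(attr(g, "n_ambiguous"), 2L)
  expect_error(gc_content("NNN"), "undefined")
})

test_that("community codon bias is the reciprocal mean ribosomal ENC'", {
  fams <- sedmicro:::codon_families()
  uniform <- paste(rep(unlist(fams), 10), collapse = "")
  cat1 <- tibble::tibble(sample_id = "S1", gene_id = "r1",
                         label = "ribosomal_protein",
                         length = nchar(uniform), mean_coverage = 1,
                         cds = uniform)
  cc <- community_cub(cat1, background = "uniform")
  expect_equal(cc$mean_enc_prime, 61)
  expect_equal(cc$cub, 0.016393, tolerance = 1e-4)
  # 1 / 55.25 on the community scale
  expect_equal(1 / 55.25, 0.0181, tolerance = 1e-4)
  # mean of identical genes equals the single-gene value
  cat2 <- dplyr::bind_rows(cat1, dplyr::mutate(cat1, gene_id = "r2"))
  expect_equal(community_cub(cat2, background = "uniform")$cub, cc$cub)
  expect_error(community_cub(dplyr::mutate(cat1, label = "other")),
               "ribosomal")
})

test_that("growth predictions respect the reciprocal contract", {
  cal <- growth_calibration(intercept = 1, slope = 0)
  res <- predict_growth(0.002, cal)
  expect_equal(res$min_generation_time, 10)
  expect_equal(res$max_growth_rate, 0.1)
  withr::with_seed(3, d <- runif(20, 0, 0.01))
  res2 <- predict_growth(d)
  expect_equal(res2$max_growth_rate * res2$min_generation_time, rep(1, 20))
  expect_true(all(res2$min_generation_time > 0))
  expect_error(predict_growth(1e6, growth_calibration(slope = 1e6)),
               "non-positive|generation")
})

test_that("calibration fitting inverts prediction", {
  truth <- growth_calibration(intercept = 1.1, slope = -180)
  withr::with_seed(8, d <- runif(30, 0, 0.008))
  pairs <- tibble::tibble(delta_cub = d,
                          generation_time = predict_growth(d, truth)$min_generation_time)
  refit <- fit_growth_calibration(pairs)
  expect_equal(refit$intercept, 1.1, tolerance = 1e-8)
  expect_equal(refit$slope, -180, tolerance = 1e-6)
})

test_that("transposase fraction is an RPM-style coverage-length share", {
  cat1 <- tibble::tibble(
    sample_id = "S1", gene_id = c("t", "o"),
    label = c("transposase", "other"),
    length = c(346, 9654), mean_coverage = c(1, 1))
  expect_equal(transposase_fraction(cat1)$transposase_pct, 3.46)
  none <- dplyr::filter(cat1, .data$label != "transposase")
  expect_equal(transposase_fraction(none)$transposase_pct, 0)
  # depth invariance
  dbl <- dplyr::mutate(cat1, mean_coverage = mean_coverage * 2)
  expect_equal(transposase_fraction(dbl)$transposase_pct, 3.46)
  # denominator choice
  cat2 <- dplyr::mutate(cat1, annotated = c(TRUE, FALSE))
  expect_equal(transposase_fraction(cat2, "annotated_genes")$transposase_pct, 100)
  expect_equal(transposase_fraction(cat2, "all_genes")$transposase_pct, 3.46)
})

test_that("estimators are depth-invariant except genome equivalents", {
  tr <- random_genome_traits(8, seed = 20)
  sim <- simulate_genome_community(tr, total_depth = 50, seed = 20)
  sim2 <- sim
  sim2$markers$mean_coverage <- sim$markers$mean_coverage * 3
  sim2$catalog$mean_coverage <- sim$catalog$mean_coverage * 3
  ge1 <- genome_equivalents(sim$markers)
  ge2 <- genome_equivalents(sim2$markers)
  expect_equal(ge2$genome_equivalents, 3 * ge1$genome_equivalents)
  expect_equal(avg_16s_copy_number(sim2$catalog, ge2)$avg_16s_copies,
               avg_16s_copy_number(sim$catalog, ge1)$avg_16s_copies)
  expect_equal(transposase_fraction(sim2$catalog)$transposase_pct,
               transposase_fraction(sim$catalog)$transposase_pct)
})

test_that("noiseless closed loop recovers planted traits exactly", {
  tr <- tibble::tibble(
    taxon = c("T001", "T002"),
    genome_size = c(2e6, 8e6), rrna16S_copies = c(4L, 2L),
    gc = c(0.42, 0.58), transposase_genes = c(6L, 12L),
    enc_target = c(40, 50), rel_abundance = c(0.5, 0.5))
  sim <- simulate_genome_community(tr, dispersion = 0, seed = 2)
  ge <- genome_equivalents(sim$markers)
  expect_equal(ge$genome_equivalents, 100)
  expect_equal(avg_16s_copy_number(sim$catalog, ge)$avg_16s_copies, 3)
  expect_equal(avg_genome_size(sim$reads, ge, basis = "reads")$avg_genome_size,
               5e6)
  expect_equal(sim$reads$gc, sim$planted$gc)
  expect_equal(transposase_fraction(sim$catalog)$transposase_pct,
               sim$planted$transposase_pct)

  solo <- tibble::tibble(taxon = "T001", genome_size = 4e6,
                         rrna16S_copies = 4L, gc = 0.5,
                         transposase_genes = 10L, enc_target = 45,
                         rel_abundance = 1)
  sims <- simulate_genome_community(solo, dispersion = 0, seed = 3)
  ges <- genome_equivalents(sims$markers)
  expect_equal(avg_16s_copy_number(sims$catalog, ges)$avg_16s_copies, 4)
})

test_that("the full trait profile assembles per sample", {
  tr <- random_genome_traits(6, seed = 33)
  sim <- simulate_genome_community(tr, dispersion = 0.05, seed = 33)
  prof <- life_history_traits(sim$catalog, sim$markers, sim$reads[, c("sample_id", "total_bp")],
                              gc = sim$reads[, c("sample_id", "gc")],
                              genome_size_basis = "reads")
  expect_equal(nrow(prof), 1)
  expect_true(all(c("genome_equivalents", "avg_16s_copies", "avg_genome_size",
                    "cub", "min_generation_time", "max_growth_rate",
                    "transposase_pct", "gc") %in% names(prof)))
  expect_equal(prof$max_growth_rate * prof$min_generation_time, 1)
  expect_s3_class(autoplot(prof), "ggplot")
})
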