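# Community-averaged life-history traits from metagenome summaries.
#
# A gene catalog is a tibble with columns: sample_id, gene_id, label
# (one of "rrna16S", "ribosomal_protein", "transposase", "other"),
# length (bp), mean_coverage (reads-per-base depth), and optionally cds
# (coding sequence) and annotated (logical, default TRUE).

catalog_labels <- c("rrna16S", "ribosomal_protein", "transposase", "other")

validate_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  need <- c("sample_id", "gene_id", "label", "length", "mean_coverage")
  missing_cols <- setdiff(need, names(catalog))
  if (length(missing_cols)) {
    abort(sprintf("Gene catalog lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(catalog$label %in% catalog_labels)) {
    abort(sprintf("Unknown gene labels: %s",
                  paste(setdiff(unique(catalog$label), catalog_labels),
                        collapse = ", ")))
  }
  if (any(catalog$length <= 0)) abort("Gene lengths must be positive.")
  if (any(catalog$mean_coverage < 0)) abort("Coverages must be non-negative.")
  if (!"annotated" %in% names(catalog)) catalog$annotated <- TRUE
  catalog
}

#' Genome equivalents from single-copy marker coverage
#'
#' The number of genomes sampled per unit of sequencing is estimated as the
#' aggregate mean coverage of a panel of universal single-copy marker genes
#' (35 by convention). A trimmed mean is available to blunt outlier markers.
#'
#' @param markers tibble with `sample_id`, `marker_id`, `mean_coverage`.
#' @param aggregation `"mean"` (default) or `"trimmed_mean"`.
#' @param trim fraction trimmed from each tail for `"trimmed_mean"`
#'   (default 0.1).
#' @param expected_markers expected panel size; a sample with fewer markers
#'   is flagged with a warning, not an error (default 35).
#' @return tibble: sample_id, genome_equivalents, n_markers.
#' @export
genome_equivalents <- function(markers, aggregation = c("mean", "trimmed_mean"),
                               trim = 0.1, expected_markers = 35) {
  aggregation <- match.arg(aggregation)
  markers <- as_tibble(markers)
  need <- c("sample_id", "marker_id", "mean_coverage")
  if (!all(need %in% names(markers))) {
    abort("Marker table needs sample_id, marker_id, mean_coverage.")
  }
  if (any(markers$mean_coverage < 0)) abort("Marker coverages must be >= 0.")
  out <- markers |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      genome_equivalents = if (aggregation == "mean") {
        mean(.data$mean_coverage)
      } else {
        mean(.data$mean_coverage, trim = trim)
      },
      n_markers = dplyr::n(), .groups = "drop")
  short <- out$n_markers < expected_markers
  if (any(short)) {
    warn(sprintf("Samples with fewer than %d markers: %s", expected_markers,
                 paste(out$sample_id[short], collapse = ", ")))
  }
  if (any(out$genome_equivalents <= 0)) {
    abort("All marker coverages are zero for at least one sample.")
  }
  out
}

#' Community-average 16S rRNA gene copy number
#'
#' Total coverage of 16S-labelled genes divided by the genome-equivalents
#' estimate; a coverage-weighted community mean, higher for communities of
#' fast-responding, multi-operon taxa.
#'
#' @param catalog gene catalog (see package docs) for one or more samples.
#' @param genome_eq tibble from [genome_equivalents()].
#' @return tibble: sample_id, avg_16s_copies.
#' @export
avg_16s_copy_number <- function(catalog, genome_eq) {
  catalog <- validate_catalog(catalog)
  if (any(genome_eq$genome_equivalents <= 0)) {
    abort("genome_equivalents must be positive.")
  }
  cov16 <- catalog |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      cov_16s = sum(.data$mean_coverage[.data$label == "rrna16S"]),
      .groups = "drop")
  dplyr::left_join(as_tibble(genome_eq), cov16, by = "sample_id") |>
    dplyr::mutate(avg_16s_copies = dplyr::coalesce(.data$cov_16s, 0) /
                    .data$genome_equivalents) |>
    dplyr::select("sample_id", "avg_16s_copies")
}

#' Community-average genome size
#'
#' Total base pairs (assembled contigs by convention, or total read bp with
#' `basis = "reads"`) divided by the genome-equivalents estimate.
#'
#' @param total_bp tibble with `sample_id`, `total_bp` (on the chosen basis).
#' @param genome_eq tibble from [genome_equivalents()].
#' @param basis bookkeeping flag recorded in the output (`"assembled"`
#'   default or `"reads"`).
#' @return tibble: sample_id, avg_genome_size (bp), basis.
#' @export
avg_genome_size <- function(total_bp, genome_eq,
                            basis = c("assembled", "reads")) {
  basis <- match.arg(basis)
  if (any(genome_eq$genome_equivalents <= 0)) {
    abort("genome_equivalents must be positive.")
  }
  dplyr::left_join(as_tibble(total_bp), as_tibble(genome_eq),
                   by = "sample_id") |>
    dplyr::mutate(avg_genome_size = .data$total_bp / .data$genome_equivalents,
                  basis = basis) |>
    dplyr::select("sample_id", "avg_genome_size", "basis")
}

#' GC content of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`; ambiguity codes are excluded from the
#' denominator and counted in the `"n_ambiguous"` attribute.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @return fraction in 0..1 with attributes `n_bases` (unambiguous) and
#'   `n_ambiguous`.
#' @export
gc_content <- function(sequences) {
  s <- toupper(paste(as.character(sequences), collapse = ""))
  chars <- strsplit(s, "")[[1]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  n_amb <- length(chars) - length(acgt)
  if (!length(acgt)) abort("No unambiguous bases: GC content undefined.")
  gc <- sum(acgt %in% c("G", "C")) / length(acgt)
  structure(gc, n_bases = length(acgt), n_ambiguous = n_amb)
}

#' Community codon usage bias from ribosomal genes
#'
#' The community CUB is the reciprocal of the unweighted mean ENC' across
#' all admissible ribosomal-protein coding sequences (lower ENC' = stronger
#' bias = larger CUB). Genes shorter than `min_codons` are excluded.
#'
#' @param catalog gene catalog with a `cds` column.
#' @param background forwarded to [enc_prime()].
#' @param min_codons forwarded to [enc_prime()] (default 100).
#' @return tibble: sample_id, mean_enc_prime, cub, n_genes.
#' @export
community_cub <- function(catalog, background = c("gene", "uniform"),
                          min_codons = 100) {
  background <- match.arg(background)
  catalog <- validate_catalog(catalog)
  if (!"cds" %in% names(catalog)) abort("Catalog has no `cds` column.")
  ribo <- dplyr::filter(catalog, .data$label == "ribosomal_protein",
                        !is.na(.data$cds))
  if (nrow(ribo) == 0) abort("No ribosomal-protein coding sequences.")
  ribo$enc <- vapply(ribo$cds, enc_prime, numeric(1),
                     background = background, min_codons = min_codons)
  out <- ribo |>
    dplyr::filter(!is.na(.data$enc)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_enc_prime = mean(.data$enc),
                     n_genes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cub = 1 / .data$mean_enc_prime) |>
    dplyr::select("sample_id", "mean_enc_prime", "cub", "n_genes")
  if (nrow(out) == 0) abort("No admissible ribosomal genes after filtering.")
  out
}

#' Ribosomal-vs-background codon bias contrast
#'
#' `delta_cub = 1/mean(ENC' ribosomal) - 1/mean(ENC' all CDS)`: how much
#' more biased the translation machinery is than the genomic background.
#' This is the statistic growth calibrations map to generation time.
#'
#' @inheritParams community_cub
#' @return tibble: sample_id, cub_ribosomal, cub_background, delta_cub.
#' @export
catalog_delta_cub <- function(catalog, background = c("gene", "uniform"),
                              min_codons = 100) {
  background <- match.arg(background)
  catalog <- validate_catalog(catalog)
  if (!"cds" %in% names(catalog)) abort("Catalog has no `cds` column.")
  withcds <- dplyr::filter(catalog, !is.na(.data$cds))
  withcds$enc <- vapply(withcds$cds, enc_prime, numeric(1),
                        background = background, min_codons = min_codons)
  withcds <- dplyr::filter(withcds, !is.na(.data$enc))
  bg <- withcds |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(cub_background = 1 / mean(.data$enc), .groups = "drop")
  ribo <- withcds |>
    dplyr::filter(.data$label == "ribosomal_protein") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(cub_ribosomal = 1 / mean(.data$enc), .groups = "drop")
  if (nrow(ribo) == 0) abort("No admissible ribosomal genes.")
  dplyr::left_join(ribo, bg, by = "sample_id") |>
    dplyr::mutate(delta_cub = .data$cub_ribosomal - .data$cub_background)
}

#' Growth calibration mapping codon bias to generation time
#'
#' `log10(minimum generation time in hours) = intercept + slope * delta_cub`.
#' The default coefficients are a package default on the scale of published
#' codon-bias growth predictors (stronger ribosomal bias, shorter
#' generation time); they are deliberately configurable, and
#' [fit_growth_calibration()] refits them on user-provided
#' (delta_cub, generation time) pairs.
#'
#' @param intercept log10 hours at `delta_cub = 0`.
#' @param slope change in log10 hours per unit delta_cub (negative).
#' @param note provenance note carried in results.
#' @return object of class `growth_calibration`.
#' @export
growth_calibration <- function(intercept = 1.25, slope = -250,
                               note = "package default (codon-bias growth predictor scale)") {
  assert_number(intercept, "intercept")
  assert_number(slope, "slope")
  structure(list(intercept = intercept, slope = slope, note = note),
            class = "growth_calibration")
}

#' Fit a growth calibration from reference pairs
#'
#' Least-squares fit of `log10(generation_time)` on `delta_cub`.
#'
#' @param data data frame with columns `delta_cub` and `generation_time`
#'   (hours, positive).
#' @return a [growth_calibration()].
#' @export
fit_growth_calibration <- function(data) {
  data <- as_tibble(data)
  if (!all(c("delta_cub", "generation_time") %in% names(data))) {
    abort("Need columns delta_cub and generation_time.")
  }
  if (any(data$generation_time <= 0)) abort("Generation times must be positive.")
  fit <- lm(log10(generation_time) ~ delta_cub, data = data)
  growth_calibration(intercept = unname(coef(fit)[1]),
                     slope = unname(coef(fit)[2]),
                     note = sprintf("fitted on %d reference pairs", nrow(data)))
}

#' Predict minimum generation time and maximal growth rate
#'
#' @param delta_cub ribosomal-vs-background bias contrast
#'   (see [catalog_delta_cub()]).
#' @param calibration a [growth_calibration()].
#' @return tibble: delta_cub, min_generation_time (h), max_growth_rate
#'   (1/h, the reciprocal).
#' @export
predict_growth <- function(delta_cub, calibration = growth_calibration()) {
  if (!inherits(calibration, "growth_calibration")) {
    abort("`calibration` must be a growth_calibration object.")
  }
  gt <- 10^(calibration$intercept + calibration$slope * delta_cub)
  if (any(!is.finite(gt) | gt <= 0)) {
    abort(sprintf(
      "Calibration (intercept=%.4g, slope=%.4g) produced a non-positive generation time.",
      calibration$intercept, calibration$slope))
  }
  tibble(delta_cub = delta_cub, min_generation_time = gt,
         max_growth_rate = 1 / gt)
}

#' Transposase fraction of a gene catalog
#'
#' Coverage-times-length (RPM-equivalent) weight of transposase-labelled
#' genes as a percentage of the denominator set: `"annotated_genes"`
#' (default; records with `annotated = TRUE`) or `"all_genes"`.
#'
#' @param catalog gene catalog.
#' @param denominator `"annotated_genes"` or `"all_genes"`.
#' @return tibble: sample_id, transposase_pct.
#' @export
transposase_fraction <- function(catalog,
                                 denominator = c("annotated_genes", "all_genes")) {
  denominator <- match.arg(denominator)
  catalog <- validate_catalog(catalog)
  catalog$w <- catalog$mean_coverage * catalog$length
  catalog$in_denom <- if (denominator == "all_genes") TRUE else catalog$annotated
  out <- catalog |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      num = sum(.data$w[.data$label == "transposase"]),
      den = sum(.data$w[.data$in_denom]),
      .groups = "drop")
  if (any(out$den <= 0)) abort("Empty denominator gene set.")
  dplyr::transmute(out, sample_id = .data$sample_id,
                   transposase_pct = 100 * .data$num / .data$den)
}

#' Full community life-history trait profile
#'
#' Runs every trait estimator on a sample's metagenome summaries and
#' returns one row per sample: genome equivalents, average 16S copy number,
#' average genome size, GC content, codon usage bias (1/mean ENC'),
#' predicted minimum generation time and maximal growth rate, and
#' transposase percentage.
#'
#' @param catalog gene catalog (with `cds` for ribosomal genes).
#' @param markers single-copy marker coverage table.
#' @param total_bp tibble `sample_id`, `total_bp`; basis per
#'   `genome_size_basis`.
#' @param gc tibble `sample_id`, `gc` (fraction), e.g. from read summaries;
#'   optional.
#' @param calibration a [growth_calibration()].
#' @param genome_size_basis `"assembled"` or `"reads"`.
#' @param transposase_denominator see [transposase_fraction()].
#' @param min_codons see [enc_prime()].
#' @return tibble of class `trait_profile`, one row per sample.
#' @export
life_history_traits <- function(catalog, markers, total_bp, gc = NULL,
                                calibration = growth_calibration(),
                                genome_size_basis = c("assembled", "reads"),
                                transposase_denominator = c("annotated_genes", "all_genes"),
                                min_codons = 100) {
  genome_size_basis <- match.arg(genome_size_basis)
  transposase_denominator <- match.arg(transposase_denominator)
  ge <- genome_equivalents(markers)
  copies <- avg_16s_copy_number(catalog, ge)
  size <- avg_genome_size(total_bp, ge, basis = genome_size_basis)
  cub <- community_cub(catalog, min_codons = min_codons)
  dcub <- catalog_delta_cub(catalog, min_codons = min_codons)
  growth <- dplyr::bind_cols(
    dplyr::select(dcub, "sample_id"),
    predict_growth(dcub$delta_cub, calibration))
  tp <- transposase_fraction(catalog, denominator = transposase_denominator)
  out <- dplyr::select(ge, "sample_id", "genome_equivalents") |>
    dplyr::left_join(copies, by = "sample_id") |>
    dplyr::left_join(dplyr::select(size, "sample_id", "avg_genome_size"),
                     by = "sample_id") |>
    dplyr::left_join(dplyr::select(cub, "sample_id", "cub", "mean_enc_prime"),
                     by = "sample_id") |>
    dplyr::left_join(growth, by = "sample_id") |>
    dplyr::left_join(tp, by = "sample_id")
  if (!is.null(gc)) out <- dplyr::left_join(out, as_tibble(gc), by = "sample_id")
  class(out) <- c("trait_profile", class(out))
  out
}
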