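# Synthetic genome communities with planted life-history traits.

#' Synthesize a coding sequence with a target ENC'
#'
#' Two-regime codon sampler: per codon, with probability `w` the family's
#' preferred codon is used, otherwise a uniform synonymous codon. `w` is
#' tuned by bisection until the realized [enc_prime()] of the sequence hits
#' the target within `tol` (the sampler's random choices are frozen first,
#' so the realized ENC' is a monotone step function of `w` and bisection
#' converges). Uses the caller's RNG stream.
#'
#' @param n_codons number of codons (default 300).
#' @param enc_target target ENC' in 20..61.
#' @param tol acceptance window on realized ENC' (default 0.5).
#' @return list: `cds` (character), `enc` (realized), `w` (preferred-codon
#'   weight used).
#' @export
synth_cds <- function(n_codons = 300, enc_target = 45, tol = 0.5) {
  n_codons <- assert_count(n_codons, "n_codons", lower = 50)
  assert_number(enc_target, "enc_target", lower = 20, upper = 61)
  fams <- codon_families()
  fam_idx <- sample.int(length(fams), n_codons, replace = TRUE)
  u_pref <- runif(n_codons)
  u_alt <- runif(n_codons)
  build <- function(w) {
    codons <- vapply(seq_len(n_codons), function(i) {
      fam <- fams[[fam_idx[i]]]
      if (u_pref[i] < w) fam[1] else fam[1 + ceiling(u_alt[i] * (length(fam) - 1))]
    }, character(1))
    paste(codons, collapse = "")
  }
  eval_w <- function(w) enc_prime(build(w), min_codons = 50)
  lo <- 0; hi <- 1
  best_w <- 0.5
  best <- eval_w(best_w)
  for (iter in seq_len(40)) {
    if (abs(best - enc_target) <= tol) break
    if (best > enc_target) lo <- best_w else hi <- best_w
    best_w <- (lo + hi) / 2
    best <- eval_w(best_w)
  }
  list(cds = build(best_w), enc = best, w = best_w)
}

#' Draw a random table of per-taxon genome traits
#'
#' Realistic marine-prokaryote ranges: genome sizes 2-8 Mb, 1-7 rRNA
#' operons, GC 0.35-0.65, 5-40 transposase genes, ribosomal ENC' targets
#' 35-55, long-tailed relative abundances.
#'
#' @param n_taxa number of taxa.
#' @param seed RNG seed.
#' @return tibble: taxon, genome_size, rrna16S_copies, gc, transposase_genes,
#'   enc_target, rel_abundance.
#' @export
random_genome_traits <- function(n_taxa, seed = NULL) {
  n_taxa <- assert_count(n_taxa, "n_taxa", lower = 1)
  local_seed(seed)
  ab <- rgamma(n_taxa, shape = 0.8)
  tibble(
    taxon = sprintf("T%03d", seq_len(n_taxa)),
    genome_size = round(runif(n_taxa, 2e6, 8e6)),
    rrna16S_copies = sample.int(7, n_taxa, replace = TRUE),
    gc = runif(n_taxa, 0.35, 0.65),
    transposase_genes = sample(5:40, n_taxa, replace = TRUE),
    enc_target = runif(n_taxa, 35, 55),
    rel_abundance = ab / sum(ab)
  )
}

#' Simulate a metagenome summary for a genome community
#'
#' Builds the per-sample inputs of the life-history stage from a table of
#' per-taxon true traits: a 35-marker single-copy coverage table (each
#' taxon contributes exactly one copy of each marker), a gene catalog with
#' 16S records (`rrna16S_copies` copies' worth of coverage), transposase
#' records, ribosomal-protein coding sequences synthesized at each taxon's
#' target ENC', background coding sequences at weak bias, and an aggregate
#' remainder record so each taxon's annotated length matches its coding
#' genome, plus a read summary (total bp and GC). Coverage noise is
#' multiplicative gamma with mean 1 whose CV is `dispersion` for a 1 kb
#' feature and shrinks with the square root of feature length (0 = exact).
#' The abundance-weighted community traits the estimators should recover
#' are returned alongside under `planted`.
#'
#' @param traits tibble as from [random_genome_traits()].
#' @param sample_id sample label.
#' @param total_depth community genome equivalents (total marker depth).
#' @param dispersion coverage noise: CV of the multiplicative gamma noise
#'   on a 1 kb feature (>= 0; longer features get proportionally smaller
#'   CV as mean coverage averages over more positions).
#' @param n_ribo_genes ribosomal-protein CDS per taxon.
#' @param n_background_genes weak-bias background CDS per taxon.
#' @param codons_per_gene codons per synthesized CDS.
#' @param coding_fraction fraction of the genome annotated as genes.
#' @param seed RNG seed.
#' @return list: `catalog`, `markers`, `reads` (sample_id, total_bp, gc),
#'   `planted` (one-row tibble of true community traits).
#' @export
simulate_genome_community <- function(traits, sample_id = "S1",
                                      total_depth = 100, dispersion = 0,
                                      n_ribo_genes = 5, n_background_genes = 3,
                                      codons_per_gene = 300,
                                      coding_fraction = 0.9, seed = NULL) {
  traits <- as_tibble(traits)
  need <- c("genome_size", "rrna16S_copies", "gc", "transposase_genes",
            "enc_target", "rel_abundance")
  if (!all(need %in% names(traits))) {
    abort(sprintf("Trait table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (abs(sum(traits$rel_abundance) - 1) > 1e-8) {
    abort("Relative abundances must sum to 1.")
  }
  if (any(traits$gc <= 0 | traits$gc >= 1)) abort("gc must be in (0, 1).")
  if (any(traits$enc_target < 20 | traits$enc_target > 61)) {
    abort("enc_target must lie in [20, 61].")
  }
  if (!is.numeric(dispersion) || dispersion < 0) abort("dispersion must be >= 0.")
  if (any(traits$rrna16S_copies < 1)) abort("rrna16S_copies must be >= 1.")
  local_seed(seed)
  n_taxa <- nrow(traits)
  taxa <- traits$taxon %||% sprintf("T%03d", seq_len(n_taxa))
  depth <- total_depth * traits$rel_abundance
  # `dispersion` is the coverage CV for a 1 kb feature; the mean coverage
  # of a longer feature averages over proportionally more positions, so
  # its CV shrinks as 1/sqrt(length)
  noisy <- function(x, len = 1000) {
    if (dispersion == 0) return(x)
    cv <- dispersion * sqrt(1000 / len)
    k <- 1 / cv^2
    x * rgamma(length(x), shape = k, rate = k)
  }
  markers <- tidyr::expand_grid(marker_id = sprintf("USCG%02d", 1:35),
                                taxon = seq_len(n_taxa)) |>
    dplyr::mutate(cov = noisy(depth[.data$taxon])) |>  # markers ~1 kb
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(mean_coverage = sum(.data$cov), .groups = "drop") |>
    dplyr::mutate(sample_id = sample_id) |>
    dplyr::select("sample_id", "marker_id", "mean_coverage")

  len_16s <- 1500L
  len_trans <- 1000L
  len_cds <- 3L * codons_per_gene
  rows <- vector("list", n_taxa)
  realized_enc <- numeric(0)
  for (t in seq_len(n_taxa)) {
    ribo <- lapply(seq_len(n_ribo_genes), function(i) {
      synth_cds(codons_per_gene, traits$enc_target[t])
    })
    bgg <- lapply(seq_len(n_background_genes), function(i) {
      synth_cds(codons_per_gene, 57)
    })
    realized_enc <- c(realized_enc, vapply(ribo, `[[`, numeric(1), "enc"))
    n_tr <- traits$transposase_genes[t]
    used_bp <- len_16s + n_tr * len_trans +
      (n_ribo_genes + n_background_genes) * len_cds
    rest_bp <- max(round(coding_fraction * traits$genome_size[t]) - used_bp, 1L)
    df <- tibble(
      gene_id = c(sprintf("%s_16S", taxa[t]),
                  sprintf("%s_tnp%02d", taxa[t], seq_len(n_tr)),
                  sprintf("%s_rpl%02d", taxa[t], seq_len(n_ribo_genes)),
                  sprintf("%s_bg%02d", taxa[t], seq_len(n_background_genes)),
                  sprintf("%s_rest", taxa[t])),
      label = c("rrna16S", rep("transposase", n_tr),
                rep("ribosomal_protein", n_ribo_genes),
                rep("other", n_background_genes), "other"),
      length = c(len_16s, rep(len_trans, n_tr),
                 rep(len_cds, n_ribo_genes + n_background_genes), rest_bp),
      cds = c(NA_character_, rep(NA_character_, n_tr),
              vapply(ribo, `[[`, character(1), "cds"),
              vapply(bgg, `[[`, character(1), "cds"), NA_character_)
    )
    cov <- noisy(rep(depth[t], nrow(df)), len = df$length)
    cov[1] <- cov[1] * traits$rrna16S_copies[t]  # 16S: copies x genome depth
    df$mean_coverage <- cov
    df$taxon <- taxa[t]
    rows[[t]] <- df
  }
  catalog <- dplyr::bind_rows(rows) |>
    dplyr::mutate(sample_id = sample_id, annotated = TRUE) |>
    dplyr::select("sample_id", "gene_id", "taxon", "label", "length",
                  "mean_coverage", "cds", "annotated")

  read_depth <- noisy(depth, len = traits$genome_size)
  total_bp <- sum(read_depth * traits$genome_size)
  gc_reads <- sum(read_depth * traits$genome_size * traits$gc) / total_bp
  a <- traits$rel_abundance
  # true annotated bp per genome: catalog stores one 16S record whose
  # coverage carries the copy number, so add the extra copies' bp here
  ann_len <- vapply(split(catalog$length, catalog$taxon)[taxa], sum, numeric(1)) +
    (traits$rrna16S_copies - 1) * len_16s
  planted <- tibble(
    sample_id = sample_id,
    avg_16s_copies = sum(a * traits$rrna16S_copies),
    avg_genome_size = sum(a * traits$genome_size),
    gc = sum(a * traits$genome_size * traits$gc) / sum(a * traits$genome_size),
    transposase_pct = 100 * sum(a * traits$transposase_genes * len_trans) /
      sum(a * ann_len),
    mean_enc_target = mean(traits$enc_target),
    mean_enc_realized = mean(realized_enc),
    genome_equivalents = total_depth
  )
  list(catalog = catalog,
       markers = markers,
       reads = tibble(sample_id = sample_id, total_bp = total_bp, gc = gc_reads),
       planted = planted)
}
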