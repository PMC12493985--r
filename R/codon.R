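# Effective number of codons, background-corrected (ENC') and classical.
#
# Synonymous families come from the standard genetic code: 2 single-codon
# amino acids (Met, Trp), 9 two-fold, 1 three-fold (Ile), 5 four-fold and
# 3 six-fold families, giving the 20..61 range.

codon_families <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_map <- Biostrings::GENETIC_CODE
    aa <- unique(gc_map[gc_map != "*"])
    fams <- lapply(aa, function(a) names(gc_map)[gc_map == a])
    names(fams) <- aa
    cache <<- fams[lengths(fams) >= 2]  # degenerate families only
    cache
  }
})

split_codons <- function(cds) {
  cds <- toupper(gsub("U", "T", as.character(cds)))
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3.")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc_map <- Biostrings::GENETIC_CODE
  known <- codons %in% names(gc_map)
  codons <- codons[known]  # codons with ambiguity codes are skipped
  aa <- gc_map[codons]
  if (length(codons) && any(aa[-length(aa)] == "*")) {
    abort("Internal stop codon in CDS.")
  }
  if (length(codons) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]  # trailing stop is fine
  }
  codons
}

nt_composition <- function(x) {
  counts <- table(factor(strsplit(paste(x, collapse = ""), "")[[1]],
                         levels = c("A", "C", "G", "T")))
  p <- as.numeric(counts) / sum(counts)
  setNames(p, c("A", "C", "G", "T"))
}

# expected within-family codon probabilities under a background nucleotide
# composition (product over the three positions, renormalised per family)
expected_codon_probs <- function(family, bg) {
  e <- vapply(family, function(cd) {
    prod(bg[strsplit(cd, "")[[1]]])
  }, numeric(1))
  e / sum(e)
}

# class means of family homozygosity; `f_fun(counts, e)` returns one F
enc_from_f <- function(codons, f_fun, bg) {
  fams <- codon_families()
  kls <- lengths(fams)
  f_by_class <- split(rep(NA_real_, length(fams)), kls)
  fvals <- numeric(0)
  fsize <- integer(0)
  for (i in seq_along(fams)) {
    cnt <- table(factor(codons, levels = fams[[i]]))
    n <- sum(cnt)
    if (n < 2) next  # family unusable with fewer than 2 codons
    e <- expected_codon_probs(fams[[i]], bg)
    f <- f_fun(as.numeric(cnt), e)
    if (!is.finite(f) || f <= 0) next
    fvals <- c(fvals, f)
    fsize <- c(fsize, kls[i])
  }
  if (!length(fvals)) return(NA_real_)
  classes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)  # families per class
  fbar <- vapply(names(classes), function(k) {
    mean(fvals[fsize == as.integer(k)])
  }, numeric(1))
  # Wright's imputation for a missing three-fold class; any other missing
  # class mean falls back to the mean of the observed class means
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (anyNA(fbar)) fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)
  nc <- 2 + sum(classes / fbar)
  min(max(nc, 20), 61)
}

#' Effective number of codons, background-corrected (ENC')
#'
#' Codon-usage-bias statistic on the 20 (maximal bias, one codon per amino
#' acid) to 61 (no bias) scale. For each synonymous family the deviation of
#' observed codon usage from the usage expected under a background
#' nucleotide composition is measured by a chi-square statistic and turned
#' into a corrected homozygosity `F = (X^2 + n - k) / (k (n - 1))`; class
#' means of `F` enter the classical weighting
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to 20..61. The correction
#' removes apparent bias that is explained by composition alone (e.g. GC
#' skew).
#'
#' @param cds coding nucleotide sequence (character or `DNAString`);
#'   length divisible by 3, no internal stop codons (a trailing stop is
#'   removed).
#' @param background `"gene"` (default; composition of the CDS itself),
#'   `"uniform"`, or a named numeric vector over A/C/G/T via `bg_freq`.
#' @param bg_freq optional explicit background composition (overrides
#'   `background`).
#' @param min_codons genes shorter than this return `NA` (flagged,
#'   excluded from community means). Default 100.
#' @return ENC' in 20..61, or `NA` for a too-short CDS.
#' @export
enc_prime <- function(cds, background = c("gene", "uniform"), bg_freq = NULL,
                      min_codons = 100) {
  background <- match.arg(background)
  codons <- split_codons(cds)
  if (length(codons) < min_codons) return(NA_real_)
  bg <- if (!is.null(bg_freq)) {
    bg_freq[c("A", "C", "G", "T")] / sum(bg_freq)
  } else if (background == "uniform") {
    c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else {
    nt_composition(codons)
  }
  f_cf <- function(cnt, e) {
    n <- sum(cnt)
    k <- length(cnt)
    p <- cnt / n
    x2 <- n * sum((p - e)^2 / e)
    (x2 + n - k) / (k * (n - 1))
  }
  enc_from_f(codons, f_cf, bg)
}

#' Effective number of codons, uncorrected (Wright's Nc)
#'
#' Classical statistic using the homozygosity estimator
#' `F = (n sum p^2 - 1) / (n - 1)`; no composition correction. Provided for
#' comparison with [enc_prime()].
#'
#' @inheritParams enc_prime
#' @return Nc in 20..61, or `NA` for a too-short CDS.
#' @export
enc_wright <- function(cds, min_codons = 100) {
  codons <- split_codons(cds)
  if (length(codons) < min_codons) return(NA_real_)
  f_w <- function(cnt, e) {
    n <- sum(cnt)
    p <- cnt / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  enc_from_f(codons, f_w, bg = c(A = .25, C = .25, G = .25, T = .25))
}
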