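# fixtures are built in code; no data files

make_otu_table <- function(n_sites = 6, n_taxa = 20, seed = 1, max_count = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_sites * n_taxa, lambda = 3), n_sites, n_taxa)
    m[sample(length(m), length(m) %/% 4)] <- 0
    empty <- rowSums(m) == 0
    m[empty, 1] <- 1L
    dimnames(m) <- list(sprintf("S%03d", seq_len(n_sites)),
                        sprintf("OTU%05d", seq_len(n_taxa)))
    otu_table(m)
  })
}

make_tree <- function(n_tips, seed = 1, labels = sprintf("OTU%05d", seq_len(n_tips))) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- labels
    tr
  })
}

# ---- independent brute-force ENC' oracle -------------------------------
# Straightforward transcription of the composition-corrected effective
# number of codons: plain loops, no shared code with the package internals
# beyond the genetic code itself.

enc_prime_oracle <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  cds <- toupper(cds)
  codons <- character(0)
  for (i in seq(1, nchar(cds), by = 3)) {
    codons <- c(codons, substr(cds, i, i + 2))
  }
  codons <- codons[codons %in% names(code)]
  aas <- code[codons]
  if (length(aas) && aas[length(aas)] == "*") {
    codons <- codons[-length(codons)]
    aas <- aas[-length(aas)]
  }
  stopifnot(!any(aas == "*"))
  # background mononucleotide frequencies from the codons themselves
  nts <- unlist(strsplit(codons, ""))
  bg <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in names(bg)) bg[b] <- sum(nts == b)
  bg <- bg / sum(bg)
  fam_of <- split(names(code)[code != "*"], code[code != "*"])
  f_list <- list()
  for (aa in names(fam_of)) {
    fam <- fam_of[[aa]]
    k <- length(fam)
    if (k < 2) next
    n_codon <- sum(codons %in% fam)
    if (n_codon < 2) next
    e <- numeric(k)
    for (j in seq_len(k)) {
      e[j] <- bg[substr(fam[j], 1, 1)] * bg[substr(fam[j], 2, 2)] *
        bg[substr(fam[j], 3, 3)]
    }
    e <- e / sum(e)
    p <- numeric(k)
    for (j in seq_len(k)) p[j] <- sum(codons == fam[j]) / n_codon
    chi2 <- 0
    for (j in seq_len(k)) chi2 <- chi2 + n_codon * (p[j] - e[j])^2 / e[j]
    f <- (chi2 + n_codon - k) / (k * (n_codon - 1))
    if (is.finite(f) && f > 0) {
      f_list[[length(f_list) + 1]] <- c(k = k, f = f)
    }
  }
  fm <- do.call(rbind, f_list)
  fbar <- c()
  for (k in c(2, 3, 4, 6)) {
    fbar[as.character(k)] <- mean(fm[fm[, "k"] == k, "f"])
  }
  if (is.nan(fbar["3"]) && !is.nan(fbar["2"]) && !is.nan(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (any(is.nan(fbar))) fbar[is.nan(fbar)] <- mean(fbar, na.rm = TRUE)
  nc <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(max(nc, 20), 61))
}

random_cds <- function(n_codons = 300, seed = 1) {
  withr::with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}
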