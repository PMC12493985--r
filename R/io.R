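#' Construct and validate an OTU count table
#'
#' An OTU table is stored in the field's canonical form: an integer matrix
#' with sites as rows and OTUs as columns, both dimensions named. The
#' constructor enforces the invariants every downstream function relies on:
#' no negative entries, every site with a positive total, unique ids.
#'
#' @param counts numeric matrix (or data frame) of non-negative integers,
#'   sites in rows, OTUs in columns, with dimnames.
#' @return the validated integer matrix, invisibly classed `"otu_table"`.
#' @export
otu_table <- function(counts) {
  x <- as.matrix(counts)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("OTU table needs site rownames and OTU colnames.")
  }
  if (anyDuplicated(rownames(x))) abort("Duplicate site ids in OTU table.")
  if (anyDuplicated(colnames(x))) abort("Duplicate OTU ids in OTU table.")
  if (!is.numeric(x) || anyNA(x)) abort("OTU counts must be numeric and complete.")
  if (any(x < 0)) abort("OTU counts must be non-negative.")
  if (any(abs(x - round(x)) > 1e-8)) abort("OTU counts must be integers.")
  if (any(rowSums(x) <= 0)) {
    abort(sprintf("Every site needs a positive total; empty: %s",
                  paste(rownames(x)[rowSums(x) <= 0], collapse = ", ")))
  }
  storage.mode(x) <- "integer"
  class(x) <- c("otu_table", class(x))
  x
}

#' Read an OTU count table from TSV
#'
#' Accepts both common orientations via an explicit flag; internally the
#' canonical orientation is always sites x OTUs. Lines starting with `#`
#' (the provenance comment written by [write_otu_table()]) are skipped.
#'
#' @param path TSV file: one header row of ids, one leading id column.
#' @param orientation `"otus_as_rows"` (default; rows are OTUs, columns are
#'   sites) or `"sites_as_rows"`.
#' @return sites x OTUs integer matrix of class `"otu_table"`.
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "sites_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) abort("OTU table needs an id column plus at least one sample column.")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate ids in first column of %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, names(raw)[-1]))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-numeric cell at row '%s', column '%s' in %s.",
                  rownames(num)[bad[1, 1]], colnames(num)[bad[1, 2]], path))
  }
  if (orientation == "otus_as_rows") num <- t(num)
  otu_table(num)
}

#' Write an OTU count table to TSV
#'
#' A `#`-prefixed header comment records the package version (and seed, when
#' supplied) so stochastic outputs stay attributable to a run.
#'
#' @param x OTU table (sites x OTUs).
#' @param path output path.
#' @param orientation orientation to write (see [read_otu_table()]).
#' @param seed optional seed to record in the provenance comment.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path,
                            orientation = c("otus_as_rows", "sites_as_rows"),
                            seed = NULL) {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  if (orientation == "otus_as_rows") m <- t(m)
  id_name <- if (orientation == "otus_as_rows") "otu_id" else "site_id"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_comment(seed), con)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

provenance_comment <- function(seed = NULL) {
  v <- tryCatch(as.character(packageVersion("sedmicro")), error = function(e) "dev")
  s <- if (is.null(seed)) "" else sprintf(" seed=%s", format(seed))
  sprintf("# sedmicro %s%s", v, s)
}

#' Read a phylogenetic tree with branch lengths
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the null-model
#' stage needs: branch lengths present and non-negative.
#'
#' @param path newick file.
#' @return an [ape] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("Could not parse newick in %s.", path))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Tree has no (complete) branch lengths; betaMNTD needs them.")
  }
  if (any(tree$edge.length < 0)) abort("Negative branch lengths in tree.")
  tree
}

#' Report mismatches between tree tips and OTU-table ids
#'
#' Never drops silently: returns the named mismatch sets so the caller can
#' decide whether to prune or fail.
#'
#' @param tree `phylo` object.
#' @param table OTU table.
#' @return list with `missing_in_tree` (OTUs without a tip) and
#'   `missing_in_table` (tips without an OTU column).
#' @export
match_tree_otus <- function(tree, table) {
  otus <- colnames(table)
  list(missing_in_tree = setdiff(otus, tree$tip.label),
       missing_in_table = setdiff(tree$tip.label, otus))
}

#' Read water or sediment chemistry tables
#'
#' TSV with a `site_id` column and unit-bearing numeric columns. Empty cells
#' become `NA` and propagate downstream as "index not computable" (zero is a
#' valid concentration and is never substituted).
#'
#' @param path TSV file.
#' @return tibble with `site_id` as character and all other columns numeric.
#' @export
read_chemistry <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"site_id" %in% names(x)) abort("Chemistry table needs a `site_id` column.")
  x$site_id <- as.character(x$site_id)
  if (anyDuplicated(x$site_id)) abort("Duplicate site_id in chemistry table.")
  for (nm in setdiff(names(x), "site_id")) {
    x[[nm]] <- as.numeric(x[[nm]])
    if (any(x[[nm]] < 0, na.rm = TRUE)) {
      abort(sprintf("Negative values in chemistry column `%s`.", nm))
    }
  }
  as_tibble(x)
}

#' Read a gene catalog from TSV, optionally joining CDS from FASTA
#'
#' The TSV carries `sample_id`, `gene_id`, `label` (one of rrna16S,
#' ribosomal_protein, transposase, other), `length` (bp) and
#' `mean_coverage`; coding sequences, if supplied, come from a FASTA whose
#' record names are gene ids. Labels arrive pre-assigned - gene
#' identification itself is upstream of this package.
#'
#' @param path TSV file.
#' @param cds_fasta optional FASTA of coding sequences keyed by gene_id.
#' @return validated gene catalog tibble (with a `cds` column when a FASTA
#'   was given; FASTA records without a catalog row are reported).
#' @export
read_gene_catalog <- function(path, cds_fasta = NULL) {
  cat_tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  cat_tbl <- validate_catalog(cat_tbl)
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    orphan <- setdiff(ids, cat_tbl$gene_id)
    if (length(orphan)) {
      warn(sprintf("%d FASTA records without a catalog row (e.g. %s)",
                   length(orphan), orphan[1]))
    }
    cds <- as.character(seqs)
    names(cds) <- ids
    cat_tbl$cds <- unname(cds[cat_tbl$gene_id])
  }
  cat_tbl
}

#' Write a tibble of results to TSV with a provenance comment
#'
#' @param x data frame.
#' @param path output path.
#' @param seed optional seed recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_comment(seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the inputs, RNG seed, package version, and every decision
#' threshold actually used (betaNTI +/-2, RC +/-0.95, network rho and FDR
#' cutoffs, ...), so stochastic null-model output can be reproduced.
#'
#' @param path output JSON path.
#' @param seed RNG seed used for the run.
#' @param inputs named list of input paths/descriptions.
#' @param thresholds named list of thresholds; defaults cover the package's
#'   standard settings.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, inputs = list(),
                               thresholds = default_thresholds()) {
  manifest <- list(
    package = "sedmicro",
    version = tryCatch(as.character(packageVersion("sedmicro")),
                       error = function(e) "dev"),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = inputs,
    thresholds = thresholds
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default decision thresholds used across the pipeline
#' @return named list.
#' @export
default_thresholds <- function() {
  list(bnti = 2, rc_bray = 0.95, network_rho = 0.6, network_fdr = 0.001,
       trix_oligotrophic = 4, trix_mesotrophic = 5,
       oi_levels = c(0.05, 0.20, 0.50), on_levels = c(0.0033, 0.066, 0.13),
       null_reps = 999)
}
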