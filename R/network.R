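#' Thresholded Spearman co-occurrence network
#'
#' Restricts to the top `k` OTUs by overall relative abundance (ties broken
#' by OTU id for determinism), computes Spearman's rho over sites for every
#' retained pair, applies Benjamini-Hochberg correction over all tested
#' pairs, and keeps edges with `rho > rho_cutoff` (positive-only, the
#' printed rule; `sign_mode = "absolute"` keeps `|rho| > rho_cutoff`) and
#' FDR-corrected `P < q_cutoff`.
#'
#' P-values use the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on
#' n - 2 degrees of freedom (perfect correlations get P = 0).
#'
#' @param table OTU table (sites x OTUs), at least 4 sites.
#' @param k number of top-abundance OTUs retained (default 1000).
#' @param rho_cutoff Spearman threshold (default 0.6).
#' @param q_cutoff FDR threshold (default 0.001).
#' @param sign_mode `"positive"` (default) or `"absolute"`.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (character), `edges` (tibble otu_a, otu_b, rho, p, q with otu_a < otu_b),
#'   and `parameters`.
#' @export
cooccurrence_network <- function(table, k = 1000, rho_cutoff = 0.6,
                                 q_cutoff = 0.001,
                                 sign_mode = c("positive", "absolute")) {
  sign_mode <- match.arg(sign_mode)
  k <- assert_count(k, "k", lower = 2)
  m <- unclass(table)
  n <- nrow(m)
  if (n < 4) abort("Spearman p-values need at least 4 sites.")
  rel <- colSums(m) / sum(m)
  ord <- order(-rel, colnames(m))
  keep <- sort(ord[seq_len(min(k, ncol(m)))])
  m <- m[, keep, drop = FALSE]
  rho <- suppressWarnings(cor(m, method = "spearman"))
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[iu]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p[is.na(r)] <- NA  # constant OTU columns
  q <- p.adjust(p, method = "BH")
  pass_rho <- if (sign_mode == "positive") r > rho_cutoff else abs(r) > rho_cutoff
  sel <- which(!is.na(r) & pass_rho & !is.na(q) & q < q_cutoff)
  edges <- tibble(
    otu_a = colnames(m)[iu[sel, 1]],
    otu_b = colnames(m)[iu[sel, 2]],
    rho = r[sel], p = p[sel], q = q[sel]
  )
  swap <- edges$otu_a > edges$otu_b
  tmp <- edges$otu_a[swap]
  edges$otu_a[swap] <- edges$otu_b[swap]
  edges$otu_b[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$otu_a, .data$otu_b)
  structure(
    list(nodes = colnames(m), edges = edges,
         parameters = list(k = k, rho_cutoff = rho_cutoff,
                           q_cutoff = q_cutoff, sign_mode = sign_mode,
                           n_sites = n, n_pairs_tested = length(r))),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (rho > %s%s, FDR q < %s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$parameters$sign_mode == "absolute") "|" else "",
              x$parameters$rho_cutoff, x$parameters$q_cutoff))
  invisible(x)
}

#' @describeIn cooccurrence_network edge list as a tibble.
#' @param x a `cooccurrence_network`.
#' @param ... unused.
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @describeIn cooccurrence_network one-row summary (node/edge counts,
#'   degree statistics, thresholds).
#' @export
glance.cooccurrence_network <- function(x, ...) {
  deg <- table(factor(c(x$edges$otu_a, x$edges$otu_b), levels = x$nodes))
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_pairs_tested = x$parameters$n_pairs_tested,
         mean_degree = mean(deg), max_degree = if (length(deg)) max(deg) else 0L,
         rho_cutoff = x$parameters$rho_cutoff,
         q_cutoff = x$parameters$q_cutoff)
}
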