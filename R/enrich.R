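#' Gene universe from a genome layout
#'
#' The enrichment universe is the set of genes tiled on the array, each
#' represented by its transcript interval plus flanks.
#'
#' @param genome genome layout with `tiled` (chrom, start, end, gene_id).
#' @return data.frame (gene_id, chrom, start, end).
#' @export
gene_universe <- function(genome) {
  data.frame(gene_id = genome$tiled$gene_id, chrom = genome$tiled$chrom,
             start = genome$tiled$start, end = genome$tiled$end,
             stringsAsFactors = FALSE)
}

#' Genes hit by selected insertion loci
#'
#' A gene is a hit iff at least one selected locus interval overlaps the
#' gene's universe interval; genes are counted once regardless of how many
#' insertions they carry.
#'
#' @param loci classified loci.
#' @param universe gene universe data.frame ([gene_universe()]).
#' @param categories,families optional selectors (NULL = all); e.g.
#'   `categories = c("singleton", "novel_polymorphic", "known_polymorphic")`
#'   for the non-reference insertion set.
#' @return character vector of hit gene ids.
#' @export
gene_hit_set <- function(loci, universe, categories = NULL, families = NULL) {
  sel <- rep(TRUE, nrow(loci))
  if (!is.null(categories)) sel <- sel & loci$category %in% categories
  if (!is.null(families))
    sel <- sel & (loci$family %in% families |
                    family_group(loci$family) %in% families)
  loci <- loci[sel, , drop = FALSE]
  if (nrow(loci) == 0) {
    message("selector matched no loci; empty hit set")
    return(character(0))
  }
  h <- GenomicRanges::findOverlaps(df_to_granges(loci),
                                   df_to_granges(universe))
  sort(unique(universe$gene_id[S4Vectors::subjectHits(h)]))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least k genes of a K-gene set when drawing n hit genes from a universe of
#' N, all draws exchangeable. Exact tail sum.
#'
#' @param k observed hits in the set.
#' @param K set size within the universe.
#' @param n total hit genes.
#' @param N universe size.
#' @return the exact upper-tail probability.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  stop_if_not(all(c(k, K, n, N) >= 0) && K <= N && n <= N &&
                k <= min(K, n),
              "inconsistent hypergeometric counts (k=%s K=%s n=%s N=%s)",
              k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of insertion-bearing genes
#'
#' Every gene set is intersected with the array universe before counting,
#' so enrichment is assessed against what could have been observed on the
#' array, not the whole genome.
#'
#' @param hits character vector of hit gene ids (see [gene_hit_set()]), or a
#'   named list of such vectors (one per selector).
#' @param gene_sets named list of character vectors of gene ids.
#' @param universe gene universe data.frame.
#' @param correct apply Bonferroni correction across gene sets (off by
#'   default; raw set p-values are reported).
#' @return data.frame of results (selector, set_name, k, K, n, N, p,
#'   neg_log10_p[, p_adj]).
#' @export
enrich_gene_sets <- function(hits, gene_sets, universe, correct = FALSE) {
  if (!is.list(hits)) hits <- list(all = hits)
  N <- length(unique(universe$gene_id))
  rows <- list()
  for (sel in names(hits)) {
    h <- intersect(hits[[sel]], universe$gene_id)
    n <- length(h)
    for (s in names(gene_sets)) {
      set_u <- intersect(gene_sets[[s]], universe$gene_id)
      K <- length(set_u)
      if (K == 0) {
        warning(sprintf("gene set '%s' is disjoint from the universe", s))
        p <- 1
        k <- 0L
      } else {
        k <- length(intersect(h, set_u))
        p <- hypergeom_pvalue(k, K, n, N)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        selector = sel, set_name = s, k = k, K = K, n = n, N = N, p = p,
        neg_log10_p = -log10(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (correct) out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
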