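#' Filter a differential-expression result table
#'
#' Applies the standard post-hoc filters to a DE results table: genes with
#' fewer than `min_total_reads` reads over all samples are removed first
#' (background noise), the p-values are then re-adjusted
#' (Benjamini-Hochberg) over the remaining genes when raw p-values are
#' available, and genes pass if their adjusted p-value is below
#' `padj_cutoff` and their absolute log fold-change exceeds `lfc_cutoff`.
#' The fold-change column is interpreted on the log base the caller's
#' table uses (conventionally log2); the cutoff is applied to its absolute
#' value as-is.
#'
#' @param table data frame with columns `gene_id`, `lfc`, `total_reads`,
#'   and `pvalue` (raw) and/or `padj` (pre-adjusted).
#' @param padj_cutoff adjusted p-value threshold (default 0.05).
#' @param lfc_cutoff absolute log fold-change threshold (default 0.5).
#' @param min_total_reads minimum total read count (default 10).
#' @return list of class `"gene_set"`: `genes` (character vector of
#'   survivors), `universe` (genes surviving the read filter), and the
#'   filtered table with the adjusted p-values used.
#' @export
de_filter <- function(table, padj_cutoff = 0.05, lfc_cutoff = 0.5,
                      min_total_reads = 10) {
  needed <- c("gene_id", "lfc", "total_reads")
  if (!all(needed %in% names(table)) ||
      !any(c("pvalue", "padj") %in% names(table)))
    stop("schema error: need columns gene_id, lfc, total_reads and ",
         "pvalue or padj", call. = FALSE)
  if (nrow(table) == 0)
    return(structure(list(genes = character(0), universe = character(0),
                          table = table), class = "gene_set"))
  tab <- table[table$total_reads >= min_total_reads, , drop = FALSE]
  if ("pvalue" %in% names(tab)) {
    tab$padj <- p.adjust(tab$pvalue, method = "BH")
  }
  pass <- !is.na(tab$padj) & tab$padj < padj_cutoff &
    abs(tab$lfc) > lfc_cutoff
  structure(list(genes = tab$gene_id[pass], universe = tab$gene_id,
                 table = tab[pass, , drop = FALSE]),
            class = "gene_set")
}

#' Overlap statistics between two gene sets
#'
#' Intersection size, Jaccard similarity and a one-sided upper-tail
#' hypergeometric enrichment p-value (probability of observing at least the
#' seen overlap when drawing `|B|` genes from a universe containing `|A|`
#' marked genes).
#'
#' @param a,b character vectors of gene identifiers (or `"gene_set"`
#'   objects, whose `genes` element is used).
#' @param universe_size size of the gene universe both sets are drawn
#'   from; must be at least `|A union B|`.
#' @return list: `n_common`, `jaccard`, `enrichment_p`, `n_a`, `n_b`.
#' @examples
#' overlap_stats(c("g1", "g2", "g3"), c("g2", "g3", "g4"),
#'               universe_size = 100)
#' @export
overlap_stats <- function(a, b, universe_size) {
  if (inherits(a, "gene_set")) a <- a$genes
  if (inherits(b, "gene_set")) b <- b$genes
  a <- unique(a); b <- unique(b)
  n_union <- length(union(a, b))
  if (universe_size < n_union)
    stop("sets exceed the universe", call. = FALSE)
  n_common <- length(intersect(a, b))
  jaccard <- if (n_union == 0) 0 else n_common / n_union
  # P(X >= n_common), X ~ Hypergeom(|A| marked, U - |A| unmarked, |B| draws)
  p <- phyper(n_common - 1, length(a), universe_size - length(a),
              length(b), lower.tail = FALSE)
  list(n_common = n_common, jaccard = jaccard, enrichment_p = p,
       n_a = length(a), n_b = length(b))
}
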