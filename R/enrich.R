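#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided hypergeometric over-representation of a hit list within each
#' gene set, against a stated background universe, with Benjamini-Hochberg
#' adjustment across sets. Sets are restricted to the background before
#' testing; sets with no background overlap are skipped.
#'
#' @param hit_genes Character vector of hits; must be a subset of
#'   `background_genes`.
#' @param background_genes The tested universe.
#' @param gene_sets Either a named list of character vectors or a path to
#'   a GMT file (parsed with [fgsea::gmtPathways()]).
#' @return Data.frame with `set`, `set_size` (within background),
#'   `overlap`, `p` (hypergeometric upper tail), `q` (BH across sets).
#' @export
enrich_gene_set <- function(hit_genes, background_genes, gene_sets) {
  if (length(background_genes) == 0) stop("empty background")
  background_genes <- unique(background_genes)
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% background_genes))
    stop("hit genes must be a subset of the background")
  if (is.character(gene_sets) && length(gene_sets) == 1)
    gene_sets <- fgsea::gmtPathways(gene_sets)
  stopifnot(is.list(gene_sets), length(gene_sets) > 0)
  N <- length(background_genes)
  n <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_genes)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, hit_genes))
    # P(X >= k) with X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               row.names = NULL)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no gene set overlaps the background")
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
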