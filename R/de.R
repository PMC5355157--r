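# Per-study differential expression and cross-study direction-consistent
# consensus. Expression is log2-scale throughout, so the linear fold
# change between classes is 2^(mean difference).

#' Per-feature tumor vs normal differential expression
#'
#' Row-wise Welch two-sample t-test on log2 expression values, with
#' Benjamini-Hochberg adjustment across all features. A feature is called
#' `up`/`down` only when both the linear fold change reaches `fc_cut` and
#' the adjusted p-value is below `q_cut`; otherwise `ns`.
#'
#' @param matrix An [expr_matrix] with at least 2 tumor and 2 normal
#'   samples.
#' @param fc_cut Linear fold-change threshold (applied as
#'   `2^|log2fc| >= fc_cut`).
#' @param q_cut BH-adjusted p-value threshold (applied as `q < q_cut`).
#' @return A `de_table` data.frame: `feature_id`, `log2fc` (tumor minus
#'   normal), `fold_change` (`2^|log2fc|`, the direction rides on
#'   `log2fc`), `p`, `q`, `direction`.
#' @export
differential_expression <- function(matrix, fc_cut = 1.5, q_cut = 0.01) {
  stopifnot(inherits(matrix, "expr_matrix"))
  tum <- matrix$sample_class == "tumor"
  nor <- matrix$sample_class == "normal"
  if (sum(tum) < 2 || sum(nor) < 2)
    stop("need at least 2 samples per class")
  x <- matrix$values
  n1 <- sum(tum); n0 <- sum(nor)
  m1 <- rowMeans(x[, tum, drop = FALSE])
  m0 <- rowMeans(x[, nor, drop = FALSE])
  v1 <- rowSums((x[, tum, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((x[, nor, drop = FALSE] - m0)^2) / (n0 - 1)
  d <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  t <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- ifelse(d[se2 == 0] == 0, 1, 0)  # constant rows
  q <- p.adjust(p, method = "BH")
  direction <- ifelse(2^abs(d) >= fc_cut & q < q_cut,
                      ifelse(d > 0, "up", "down"), "ns")
  out <- data.frame(feature_id = rownames(x), log2fc = d,
                    fold_change = 2^abs(d), p = p, q = q,
                    direction = direction, row.names = NULL)
  attr(out, "fc_cut") <- fc_cut
  attr(out, "q_cut") <- q_cut
  class(out) <- c("de_table", "data.frame")
  out
}

#' Direction-consistent consensus across studies
#'
#' A feature is kept with direction `d` if and only if every study calls
#' it `d` with `d != ns`; anything else is `excluded`. The feature
#' universe is the intersection of the studies' feature ids (features
#' missing from some study are dropped with a warning).
#'
#' @param de_tables List of two or more [differential_expression()]
#'   tables.
#' @return A `consensus_de_table` data.frame with `feature_id`, one
#'   `direction_<i>` column per study, `consensus_direction`
#'   (`up`/`down`/`excluded`), `n_consistent` (studies agreeing on the
#'   modal non-ns direction), and `mean_log2fc` (across studies). Counts
#'   of consensus up/down features are attached as attributes.
#' @export
consensus <- function(de_tables) {
  if (length(de_tables) < 2) stop("need at least 2 DE tables")
  ids <- Reduce(intersect, lapply(de_tables, function(t) t$feature_id))
  if (length(ids) == 0) stop("empty feature-id intersection across studies")
  n_union <- length(Reduce(union, lapply(de_tables, `[[`, "feature_id")))
  if (n_union > length(ids))
    warning(sprintf("%d feature id(s) absent from some study dropped",
                    n_union - length(ids)))
  k <- length(de_tables)
  dirs <- vapply(de_tables, function(t)
    t$direction[match(ids, t$feature_id)], character(length(ids)))
  dirs <- base::matrix(dirs, ncol = k)
  lfc <- vapply(de_tables, function(t)
    t$log2fc[match(ids, t$feature_id)], numeric(length(ids)))
  lfc <- base::matrix(lfc, ncol = k)
  n_up <- rowSums(dirs == "up")
  n_dn <- rowSums(dirs == "down")
  cons <- ifelse(n_up == k, "up", ifelse(n_dn == k, "down", "excluded"))
  out <- data.frame(feature_id = ids, row.names = NULL)
  for (i in seq_len(k)) out[[paste0("direction_", i)]] <- dirs[, i]
  out$consensus_direction <- cons
  out$n_consistent <- pmax(n_up, n_dn)
  out$mean_log2fc <- rowMeans(lfc)
  attr(out, "n_up") <- sum(cons == "up")
  attr(out, "n_down") <- sum(cons == "down")
  attr(out, "n_studies") <- k
  class(out) <- c("consensus_de_table", "data.frame")
  out
}

#' Collapse probe-level consensus calls to gene level
#'
#' Keeps one record per gene among the consensus (non-excluded) probes:
#' when several probes map to the same gene, the probe with the largest
#' study-averaged |log2fc| is retained; genes whose probes carry
#' conflicting consensus directions are excluded and listed in the
#' `conflicts` attribute.
#'
#' @param consensus_table A [consensus()] result.
#' @param probe_gene_map Data.frame with columns `probe` and `gene`.
#' @return A gene-level `consensus_de_table` (with `probe_id` recording
#'   the representative probe); dropped unmapped probes raise a warning.
#' @export
collapse_probes <- function(consensus_table, probe_gene_map) {
  stopifnot(inherits(consensus_table, "consensus_de_table"))
  map <- as.data.frame(probe_gene_map)
  if (!all(c("probe", "gene") %in% names(map)))
    stop("probe_gene_map needs columns 'probe' and 'gene'")
  if (anyNA(map$probe) || anyNA(map$gene) || anyDuplicated(map$probe))
    stop("malformed probe->gene map")
  kept <- consensus_table[consensus_table$consensus_direction != "excluded", ,
                          drop = FALSE]
  gene <- map$gene[match(kept$feature_id, map$probe)]
  if (anyNA(gene)) {
    warning(sprintf("%d retained probe(s) not covered by the map dropped",
                    sum(is.na(gene))))
    kept <- kept[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  conflicts <- character(0)
  rows <- lapply(split(seq_len(nrow(kept)), gene), function(idx) {
    g <- kept[idx, , drop = FALSE]
    if (length(unique(g$consensus_direction)) > 1) {
      conflicts <<- c(conflicts, gene[idx[1]])
      return(NULL)
    }
    g[which.max(abs(g$mean_log2fc)), , drop = FALSE]
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$probe_id <- out$feature_id
  out$feature_id <- names(rows)[!vapply(rows, is.null, logical(1))]
  rownames(out) <- NULL
  if (length(conflicts))
    message(sprintf("%d gene(s) excluded for conflicting probe directions: %s",
                    length(conflicts), paste(conflicts, collapse = ", ")))
  attr(out, "conflicts") <- conflicts
  attr(out, "n_up") <- sum(out$consensus_direction == "up")
  attr(out, "n_down") <- sum(out$consensus_direction == "down")
  class(out) <- c("consensus_de_table", "data.frame")
  out
}
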