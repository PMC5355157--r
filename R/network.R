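# Signed, thresholded Spearman co-expression graph: edges where
# |rho| >= rho_cut and the multiplicity-adjusted correlation p-value
# passes alpha_edge; positive-edge communities; negative-bridge genes
# (outside genes with several negative edges into a community).

#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman rank correlation (average ranks for ties) for every gene pair,
#' with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant genes have undefined
#' correlations; their rows/columns are `NA` and they are excluded from
#' graphs built downstream.
#'
#' @param matrix An [expr_matrix] with >= 10 samples (a warning is raised
#'   below 30, where the t approximation is rough).
#' @return List with `rho`, `p` (symmetric matrices, diagonal `rho = 1`,
#'   `p = NA`), `n_samples`, and `constant` (excluded gene ids).
#' @export
spearman_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  n <- ncol(matrix$values)
  if (n < 10) stop("need at least 10 samples")
  if (n < 30) warning("fewer than 30 samples; correlation p-values are rough")
  const <- apply(matrix$values, 1, function(r) diff(range(r)) == 0)
  if (any(const))
    warning(sprintf("%d constant gene(s) excluded from correlation", sum(const)))
  rho <- suppressWarnings(cor(t(matrix$values), method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(rho) <- ifelse(const, NA, 1)
  diag(p) <- NA
  list(rho = rho, p = p, n_samples = n,
       constant = rownames(matrix$values)[const])
}

#' Build the signed thresholded co-expression graph
#'
#' P-values are adjusted over all n(n-1)/2 unordered gene pairs; an edge
#' is retained iff `|rho| >= rho_cut` and adjusted p `<= alpha_edge`, with
#' its sign taken from the correlation. Genes with undefined correlations
#' contribute no edges.
#'
#' @param rho,p Symmetric matrices from [spearman_matrix()] (or the list
#'   itself passed as `rho`).
#' @param rho_cut Absolute correlation threshold (values above 1 give an
#'   empty edge set).
#' @param adjust Multiple-testing method over pairs (any
#'   [stats::p.adjust()] method; default Bonferroni).
#' @param alpha_edge Adjusted-p threshold, in (0, 1].
#' @param node_attrs Optional data.frame (e.g. a [screen_all()] table)
#'   with `gene_id` and `prognosis_class`, attached to nodes as
#'   `hr_class`.
#' @return Object of class `coex_graph`: `nodes` (gene, hr_class),
#'   `edges` (from, to, rho, sign, p_adj), `params`.
#' @export
build_graph <- function(rho, p = NULL, rho_cut = 0.6,
                        adjust = "bonferroni", alpha_edge = 0.05,
                        node_attrs = NULL) {
  if (is.list(rho) && !is.null(rho$rho)) { p <- rho$p; rho <- rho$rho }
  stopifnot(is.matrix(rho), is.matrix(p),
            nrow(rho) == ncol(rho), all(dim(rho) == dim(p)))
  if (rho_cut <= 0) stop("rho_cut must be positive")
  if (!(alpha_edge > 0 && alpha_edge <= 1))
    stop("alpha_edge must be in (0, 1]")
  genes <- rownames(rho)
  ut <- upper.tri(rho)
  pair_p <- p[ut]
  keep_pair <- !is.na(pair_p)
  p_adj <- rep(NA_real_, length(pair_p))
  p_adj[keep_pair] <- p.adjust(pair_p[keep_pair], method = adjust)
  idx <- which(ut, arr.ind = TRUE)
  sel <- keep_pair & !is.na(rho[ut]) & abs(rho[ut]) >= rho_cut &
    p_adj <= alpha_edge
  sel[is.na(sel)] <- FALSE
  edges <- data.frame(from = genes[idx[sel, 1]],
                      to = genes[idx[sel, 2]],
                      rho = rho[ut][sel],
                      sign = ifelse(rho[ut][sel] >= 0, 1L, -1L),
                      p_adj = p_adj[sel], row.names = NULL)
  nodes <- data.frame(gene = genes, hr_class = NA_character_,
                      row.names = NULL)
  if (!is.null(node_attrs) &&
      all(c("gene_id", "prognosis_class") %in% names(node_attrs)))
    nodes$hr_class <- node_attrs$prognosis_class[
      match(nodes$gene, node_attrs$gene_id)]
  structure(list(nodes = nodes, edges = edges,
                 params = list(rho_cut = rho_cut, adjust = adjust,
                               alpha_edge = alpha_edge)),
            class = "coex_graph")
}

#' @export
print.coex_graph <- function(x, ...) {
  cat(sprintf(
    "<coex_graph> %d node(s), %d edge(s) (%d positive, %d negative) at |rho|>=%s\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
    sum(x$edges$sign < 0), format(x$params$rho_cut)))
  invisible(x)
}

# igraph view of a coex_graph (positive-edge subgraph optional).
.as_igraph <- function(graph, positive_only = FALSE) {
  e <- graph$edges
  if (positive_only) e <- e[e$sign > 0, , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = graph$nodes)
}

#' Positive-edge co-expression communities
#'
#' Communities are connected components of the positive-edge subgraph,
#' optionally refined by greedy modularity optimization
#' ([igraph::cluster_fast_greedy()]). Components smaller than `min_size`
#' are reported as background (community 0). Communities are numbered by
#' decreasing size.
#'
#' @param graph A [build_graph()] result.
#' @param min_size Minimum community size (default 5).
#' @param refine Refine components by greedy modularity (default FALSE;
#'   components suffice when between-block edges are rare).
#' @return Object of class `coex_communities`: `membership` (named
#'   integer, 0 = background/none), `sizes` (per community),
#'   `n_communities`.
#' @export
find_communities <- function(graph, min_size = 5, refine = FALSE) {
  stopifnot(inherits(graph, "coex_graph"))
  ig <- .as_igraph(graph, positive_only = TRUE)
  memb <- if (refine)
    igraph::membership(igraph::cluster_fast_greedy(ig))
  else igraph::components(ig)$membership
  memb <- setNames(as.integer(memb), igraph::V(ig)$name)
  # nodes without a positive edge are background
  pos_deg <- igraph::degree(ig)
  memb[pos_deg == 0] <- 0L
  sizes <- table(memb[memb != 0])
  keep <- names(sizes)[sizes >= min_size]
  memb[!(memb %in% as.integer(keep))] <- 0L
  # renumber by decreasing size
  ord <- as.integer(names(sort(sizes[keep], decreasing = TRUE)))
  renum <- setNames(seq_along(ord), ord)
  memb[memb != 0] <- as.integer(renum[as.character(memb[memb != 0])])
  out_sizes <- if (length(ord)) as.integer(sort(sizes[keep],
                                                decreasing = TRUE))
               else integer(0)
  structure(list(membership = memb,
                 sizes = setNames(out_sizes, seq_along(out_sizes)),
                 n_communities = length(out_sizes),
                 min_size = min_size),
            class = "coex_communities")
}

#' @export
print.coex_communities <- function(x, ...) {
  cat(sprintf("<coex_communities> %d communit%s (min size %d): %s\n",
              x$n_communities,
              if (x$n_communities == 1) "y" else "ies", x$min_size,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Negative-bridge genes into a community
#'
#' Genes outside a community that carry at least `bridge_min` negative
#' edges into it -- the classic candidate-suppressor pattern of a gene
#' anti-correlated with a whole co-expression clique. Ranked by negative
#' degree into the community, then by mean |rho| of those edges.
#'
#' @param graph A [build_graph()] result.
#' @param community Character vector of member gene ids, or a community id
#'   (single number) together with `communities`.
#' @param bridge_min Minimum number of negative edges into the community.
#' @param communities Optional [find_communities()] result used to resolve
#'   a numeric `community` id.
#' @return Data.frame `gene`, `n_negative`, `mean_abs_rho`, ranked.
#' @export
negative_bridges <- function(graph, community, bridge_min = 3,
                             communities = NULL) {
  stopifnot(inherits(graph, "coex_graph"))
  if (is.numeric(community) && length(community) == 1) {
    if (is.null(communities))
      stop("supply `communities` to resolve a community id")
    if (!(community %in% communities$membership))
      stop("unknown community id: ", community)
    community <- names(communities$membership)[
      communities$membership == community]
  }
  community <- as.character(community)
  if (!length(community)) stop("empty community")
  e <- graph$edges[graph$edges$sign < 0, , drop = FALSE]
  into <- e[xor(e$from %in% community, e$to %in% community), , drop = FALSE]
  outside <- ifelse(into$from %in% community, into$to, into$from)
  if (!length(outside))
    return(data.frame(gene = character(0), n_negative = integer(0),
                      mean_abs_rho = numeric(0)))
  agg <- data.frame(gene = outside, rho = abs(into$rho))
  tab <- vapply(split(agg$rho, agg$gene),
                function(r) c(n = length(r), m = mean(r)), numeric(2))
  out <- data.frame(gene = colnames(tab),
                    n_negative = as.integer(tab["n", ]),
                    mean_abs_rho = tab["m", ], row.names = NULL)
  out <- out[out$n_negative >= bridge_min, , drop = FALSE]
  out[order(-out$n_negative, -out$mean_abs_rho), , drop = FALSE]
}

#' Export a co-expression graph
#'
#' GraphML (node attributes: community, hr_class; edge attributes: rho,
#' sign, p_adj) or a 3-column edge-list TSV `source`, `target`, `rho`.
#' Both formats round-trip through [read_coex_graph()].
#'
#' @param graph A [build_graph()] result.
#' @param path Output file.
#' @param format `"graphml"` or `"edges"`.
#' @param communities Optional [find_communities()] result recorded as a
#'   node attribute.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edges"),
                         communities = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "coex_graph"))
  if (format == "edges") {
    write.table(graph$edges[, c("from", "to", "rho")],
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("source", "target", "rho"))
    return(invisible(path))
  }
  g <- graph
  g$nodes$community <- if (!is.null(communities))
    as.integer(communities$membership[g$nodes$gene]) else NA_integer_
  g$nodes$hr_class[is.na(g$nodes$hr_class)] <- ""
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read back an exported co-expression graph
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"edges"`.
#' @return For GraphML, a `coex_graph`; for an edge list, its data.frame.
#' @export
read_coex_graph <- function(path, format = c("graphml", "edges")) {
  format <- match.arg(format)
  if (format == "edges")
    return(read.delim(path, stringsAsFactors = FALSE))
  ig <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(ig, what = "edges")
  nd <- igraph::as_data_frame(ig, what = "vertices")
  names(nd)[names(nd) == "name"] <- "gene"
  ed$sign <- as.integer(ed$sign)
  structure(list(nodes = nd,
                 edges = ed[, c("from", "to", "rho", "sign", "p_adj")],
                 params = list()),
            class = "coex_graph")
}
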