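# internal: edge mask under the network thresholds (strict inequalities)
edge_mask <- function(rho, q, rho_min = 0.6, q_max = 0.001) {
  !is.na(rho) & !is.na(q) & abs(rho) > rho_min & q < q_max
}

#' Build a cross-kingdom co-occurrence network
#'
#' Candidate nodes are the phylotypes of one abundance class, drawn from all
#' organism groups, that pass an occupancy (prevalence) filter. All pairwise
#' Spearman correlations are computed on per-sample relative abundances
#' (normalized within each group so depth differences between groups cannot
#' fabricate edges), p-values are Benjamini-Hochberg corrected across all
#' tested pairs, and an edge is kept when |rho| > `rho_min` and the adjusted
#' q < `q_max` (both strict).
#'
#' @param tables named list of [community_table()]s, samples aligned.
#' @param classes matching named list of [abundance_classes()].
#' @param label `"abundant"` or `"rare"` (any class label works).
#' @param prevalence_min minimum occupancy fraction for candidate nodes
#'   (default 0.2; rank correlations at |rho| > 0.6 need a reasonably dense
#'   matrix to be stable).
#' @param rho_min,q_max edge thresholds (defaults 0.6 and 0.001).
#' @return Object of class `cooc_network`: `nodes` (data frame with id,
#'   group, label, degree, support_score, displayed), `edges` (data frame
#'   with from, to, rho, q), `thresholds`, `graph` (an igraph object),
#'   `abundance` (the node relative-abundance matrix, kept for scoring).
#' @export
build_network <- function(tables, classes, label, prevalence_min = 0.2,
                          rho_min = 0.6, q_max = 0.001) {
  mat <- pool_class_matrix(tables, classes, label)
  prev <- colMeans(mat > 0)
  mat <- mat[, prev >= prevalence_min, drop = FALSE]
  if (ncol(mat) < 2) stop("fewer than 2 candidate nodes after the prevalence filter")
  message(sprintf("network (%s): %d candidate nodes after prevalence >= %g",
                  label, ncol(mat), prevalence_min))
  sp <- spearman_matrix(mat, mat)
  n <- ncol(mat)
  ut <- upper.tri(sp$rho)
  q <- matrix(NA_real_, n, n)
  q[ut] <- stats::p.adjust(sp$p[ut], method = "BH")
  keep <- which(edge_mask(sp$rho, q, rho_min, q_max) & ut, arr.ind = TRUE)
  ids <- colnames(mat)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      rho = sp$rho[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  grp <- sub("\\|.*$", "", ids)
  nodes <- data.frame(id = ids, group = grp, label = label,
                      degree = as.numeric(igraph::degree(g)),
                      support_score = NA_real_, displayed = NA,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 graph = g, abundance = mat),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %s taxa: %d nodes, %d edges (|rho| > %g, q < %g)\n",
              x$nodes$label[1], nrow(x$nodes), nrow(x$edges),
              x$thresholds["rho_min"], x$thresholds["q_max"]))
  invisible(x)
}

#' Score nodes by their support for multifunctionality
#'
#' Pearson correlation between each node's per-sample relative abundance and
#' a multifunctionality index. Nodes with r > 0 get `displayed = TRUE`
#' (the display convention that highlights positive supporters); constant
#' abundance gives an undefined score and `displayed = FALSE`.
#'
#' @param net a [build_network()] result.
#' @param mf multifunctionality vector aligned with the network's samples.
#' @return The network with `support_score` and `displayed` filled in.
#' @export
node_support_scores <- function(net, mf) {
  stopifnot(inherits(net, "cooc_network"))
  if (length(mf) != nrow(net$abundance)) stop("mf misaligned with network samples")
  r <- suppressWarnings(stats::cor(net$abundance, mf))[, 1]
  net$nodes$support_score <- unname(r)
  net$nodes$displayed <- !is.na(r) & r > 0
  net
}

#' Regression of multifunctionality support on node degree
#'
#' OLS of the node support score on node degree over displayed nodes
#' (support score > 0 and defined).
#'
#' @param net a scored network (after [node_support_scores()]).
#' @return A [bef_regression()] result.
#' @export
degree_support_regression <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (all(is.na(net$nodes$displayed))) stop("run node_support_scores() first")
  nd <- net$nodes[net$nodes$displayed %in% TRUE, ]
  if (nrow(nd) < 3) stop("need at least 3 displayed nodes")
  if (stats::sd(nd$degree) == 0) stop("all displayed nodes have equal degree")
  bef_regression(nd$degree, nd$support_score)
}

#' Export a network as GraphML, GEXF and TSV tables
#'
#' GraphML through igraph; GEXF 1.2 through a minimal built-in writer
#' (both load into Gephi); nodes and edges additionally as TSV.
#'
#' @param net a `cooc_network`.
#' @param prefix output path prefix; files `<prefix>.graphml`,
#'   `<prefix>.gexf`, `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` are written.
#' @return Character vector of written paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  idx <- match(igraph::V(g)$name, net$nodes$id)
  igraph::V(g)$group <- net$nodes$group[idx]
  sc <- net$nodes$support_score[idx]
  igraph::V(g)$support_score <- ifelse(is.na(sc), 0, sc)
  paths <- paste0(prefix, c(".graphml", ".gexf", "_nodes.tsv", "_edges.tsv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  write_gexf(net, paths[2])
  utils::write.table(net$nodes, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# minimal GEXF 1.2 writer (undirected, node group/score attributes)
write_gexf <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
               '  <graph mode="static" defaultedgetype="undirected">',
               '    <attributes class="node">',
               '      <attribute id="0" title="group" type="string"/>',
               '      <attribute id="1" title="support_score" type="double"/>',
               '    </attributes>',
               '    <nodes>'), con)
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    writeLines(sprintf(
      '      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/><attvalue for="1" value="%s"/></attvalues></node>',
      esc(nd$id), esc(nd$id), esc(nd$group),
      ifelse(is.na(nd$support_score), "0", format(nd$support_score, digits = 6))), con)
  }
  writeLines('    </nodes>', con)
  writeLines('    <edges>', con)
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      ed <- net$edges[i, ]
      writeLines(sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
                         i - 1L, esc(ed$from), esc(ed$to),
                         format(abs(ed$rho), digits = 6)), con)
    }
  }
  writeLines(c('    </edges>', '  </graph>', '</gexf>'), con)
  invisible(path)
}
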