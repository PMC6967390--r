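
# Thin wrappers around igraph for the unweighted family network.

#' Build an undirected, unweighted graph over family ids
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix (or data.frame) of unordered
#'   pairs; self-loops and duplicate pairs are rejected.
#' @return an igraph object with named vertices.
#' @export
family_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_casnet("duplicate node names")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop_casnet("`edges` must have two columns")
    if (any(edges[, 1L] == edges[, 2L])) stop_casnet("self-loops not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop_casnet("duplicate edges")
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g
}

#' Extract the edge set of a graph as a sorted two-column matrix
#'
#' Rows are unordered pairs, each sorted within-row and then by row, so two
#' graphs with the same edge set produce identical matrices.
#'
#' @param g an igraph object with named vertices.
#' @return character matrix with columns `from`, `to`.
#' @export
edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) {
    return(matrix(character(0L), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  dimnames(el) <- list(NULL, c("from", "to"))
  el
}

#' Write a graph as an edge-list TSV
#'
#' @param g igraph object with named vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(g, path) {
  utils::write.table(as.data.frame(edge_set(g)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an edge-list TSV into a graph
#'
#' @param path TSV with columns `from`, `to`.
#' @param nodes optional full node set (isolated nodes are not recoverable
#'   from an edge list alone).
#' @return an igraph object.
#' @export
read_edgelist_tsv <- function(path, nodes = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(tab[[1L]], tab[[2L]]))
  family_graph(nodes, as.matrix(tab[, 1:2]))
}

#' Write a graph as GraphML
#'
#' @param g igraph object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Precision/recall/F1 of a recovered edge set against planted truth.

#' Edge-recovery performance against a planted edge set
#'
#' @param g recovered igraph.
#' @param true_edges two-column character matrix of planted unordered pairs.
#' @return list with tp, fp, fn, precision, recall, f1.
#' @export
edge_recovery <- function(g, true_edges) {
  est <- edge_set(g)
  key <- function(m) {
    if (NROW(m) == 0L) return(character(0L))
    paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  }
  ek <- key(est)
  tk <- key(as.matrix(true_edges))
  tp <- length(intersect(ek, tk))
  fp <- length(setdiff(ek, tk))
  fn <- length(setdiff(tk, ek))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
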