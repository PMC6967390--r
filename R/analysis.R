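
# network_analysis: hop distances to labeled cas nodes, the clustering
# statistic with its random-node-set null, and putative subtype assignment
# from typed network neighbors.

#' Hop distance from every node to the nearest POSITIVE node
#'
#' Multi-source breadth-first search from all POSITIVE-labeled nodes on the
#' unweighted graph. POSITIVE nodes get distance 0; nodes unreachable from
#' any POSITIVE node get `Inf`.
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()] covering the graph's nodes.
#' @return named numeric vector of hop counts (or `Inf`).
#' @export
distances_to_labeled <- function(g, labels) {
  nodes <- igraph::V(g)$name
  pos <- names(labels)[labels == "POSITIVE"]
  pos <- intersect(pos, nodes)
  if (length(pos) == 0L) stop_casnet("no POSITIVE node in graph")
  d <- igraph::distances(g, v = pos, to = nodes)
  out <- apply(d, 2L, min)
  names(out) <- nodes
  out
}

#' Clustering of POSITIVE nodes relative to random node sets
#'
#' Observed statistic: the mean, over POSITIVE nodes, of the hop distance to
#' the nearest *other* POSITIVE node. Null: the same statistic for `n_draws`
#' uniformly random node sets of the same size. Small observed values mean
#' the positives cluster. Unreachable (infinite) distances are excluded from
#' the mean, with the excluded count reported. The empirical p-value uses
#' the add-one rule, `(1 + #[null <= observed]) / (1 + n_draws)`, so it is
#' never zero.
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()]; needs at least 2 POSITIVE nodes in `g`.
#' @param n_draws number of null draws; default 999.
#' @param seed integer seed.
#' @return list: `observed`, `null` (numeric vector), `p_value`,
#'   `n_excluded_inf` (positives with no reachable other positive).
#' @export
clustering_statistic <- function(g, labels, n_draws = 999L, seed = 1L) {
  nodes <- igraph::V(g)$name
  pos <- intersect(names(labels)[labels == "POSITIVE"], nodes)
  m <- length(pos)
  if (m < 2L) stop_casnet("need at least 2 POSITIVE nodes")
  D <- igraph::distances(g)  # hop counts, symmetric
  nearest_other_mean <- function(idx) {
    sub <- D[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mins <- apply(sub, 1L, min)
    mean(mins[is.finite(mins)])
  }
  obs_idx <- match(pos, nodes)
  sub <- D[obs_idx, obs_idx, drop = FALSE]
  diag(sub) <- Inf
  mins <- apply(sub, 1L, min)
  n_inf <- sum(!is.finite(mins))
  observed <- mean(mins[is.finite(mins)])
  null <- with_seed(seed, vapply(seq_len(n_draws), function(r) {
    nearest_other_mean(sample.int(length(nodes), m))
  }, numeric(1L)))
  p <- (1 + sum(null <= observed, na.rm = TRUE)) / (1 + n_draws)
  if (n_inf > 0L) {
    message(n_inf, " POSITIVE node(s) had no reachable other POSITIVE node; ",
            "excluded from the observed mean")
  }
  list(observed = observed, null = null, p_value = p, n_excluded_inf = n_inf)
}

#' Assign a putative CRISPR subtype from typed network neighbors
#'
#' Collects known-cas families with a subtype annotation within hop distance
#' 2 of the node. The modal subtype, when supported by at least two such
#' neighbors, gives a CONFIDENT assignment; exactly one typed neighbor gives
#' a SINGLE_NEIGHBOR assignment; no typed neighbor, or a tie among modal
#' subtypes (logged), gives NONE.
#'
#' @param g igraph with named vertices.
#' @param node family id present in `g`.
#' @param type_map named character vector: family id -> subtype (e.g. "I-E").
#' @return list: `family`, `type` (subtype or `NA`), `confidence`
#'   (`"CONFIDENT"`, `"SINGLE_NEIGHBOR"` or `"NONE"`), `n_support`.
#' @export
assign_putative_type <- function(g, node, type_map) {
  if (!node %in% igraph::V(g)$name) stop_casnet("node not in graph: ", node)
  nb <- igraph::ego(g, order = 2L, nodes = node)[[1L]]$name
  nb <- setdiff(nb, node)
  typed <- type_map[intersect(nb, names(type_map))]
  typed <- typed[!is.na(typed) & nzchar(typed)]
  if (length(typed) == 0L) {
    return(list(family = node, type = NA_character_, confidence = "NONE",
                n_support = 0L))
  }
  tab <- sort(table(typed), decreasing = TRUE)
  if (length(typed) == 1L) {
    return(list(family = node, type = names(tab)[1L],
                confidence = "SINGLE_NEIGHBOR", n_support = 1L))
  }
  if (tab[1L] < 2L || (length(tab) > 1L && tab[2L] == tab[1L])) {
    if (length(tab) > 1L && tab[2L] == tab[1L]) {
      message("subtype tie at ", node, ": ",
              paste(names(tab)[tab == tab[1L]], collapse = " vs "))
    }
    return(list(family = node, type = NA_character_, confidence = "NONE",
                n_support = as.integer(tab[1L])))
  }
  list(family = node, type = names(tab)[1L], confidence = "CONFIDENT",
       n_support = as.integer(tab[1L]))
}

#' Tabulate putative types for a set of nodes
#'
#' @param g igraph.
#' @param nodes family ids to annotate.
#' @param type_map named character vector of known subtypes.
#' @return data.frame (family, type, confidence, n_support).
#' @export
assign_putative_types <- function(g, nodes, type_map) {
  rows <- lapply(nodes, function(nd) {
    as.data.frame(assign_putative_type(g, nd, type_map),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
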