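# Independent oracles used across the suite. These deliberately share no
# code with the package: the lasso oracle enumerates KKT sign patterns in
# closed form, the BFS oracle is a hand-rolled queue, the distance oracle an
# exhaustive pairwise scan, and the line-fit oracle a plain grid search.

# Global lasso minimizer by enumerating every support and sign pattern.
# G = X'X/n over candidates, cvec = X'y/n, syy = y'y/n.
# Objective: 0.5*syy - b'c + 0.5*b'Gb + lambda*||b||_1.
oracle_lasso <- function(G, cvec, syy, lambda) {
  k <- length(cvec)
  obj <- function(b) 0.5 * syy - sum(b * cvec) + 0.5 * t(b) %*% G %*% b +
    lambda * sum(abs(b))
  best <- list(objective = obj(numeric(k)), b = numeric(k))
  for (sz in seq_len(k)) {
    supports <- utils::combn(k, sz, simplify = FALSE)
    for (S in supports) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), sz)))
      for (r in seq_len(nrow(signs))) {
        sg <- signs[r, ]
        bS <- try(solve(G[S, S, drop = FALSE], cvec[S] - lambda * sg),
                  silent = TRUE)
        if (inherits(bS, "try-error")) next
        if (any(sign(bS) != sg)) next
        b <- numeric(k)
        b[S] <- bS
        o <- obj(b)
        if (o < best$objective) best <- list(objective = o, b = b)
      }
    }
  }
  best$support <- which(abs(best$b) > 1e-8)
  best
}

# Single-source BFS hop distances on an edge list (character matrix).
oracle_bfs <- function(nodes, edges, source) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]
      b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Exhaustive all-pairs minimum gap between a family's genes and cas genes.
oracle_min_distance <- function(table, family) {
  inst <- table[table$family_id == family & !table$is_cas, , drop = FALSE]
  cas <- table[table$is_cas, , drop = FALSE]
  genomes <- unique(inst$genome_id)
  out <- stats::setNames(rep(Inf, length(genomes)), genomes)
  for (g in genomes) {
    for (i in which(inst$genome_id == g)) {
      for (j in which(cas$genome_id == g)) {
        if (inst$contig_id[i] != cas$contig_id[j]) next
        s1 <- inst$start[i]; e1 <- inst$end[i]
        s2 <- cas$start[j]; e2 <- cas$end[j]
        d <- if (s1 > e2) s1 - e2 else if (s2 > e1) s2 - e1 else 0
        out[g] <- min(out[g], d)
      }
    }
  }
  out
}

# Plain grid search over (alpha, q) for the separating line; no crossing
# augmentation, arbitrary grid size.
oracle_fit_line_f1 <- function(pos_in, neg_in, y, grid) {
  P <- sum(y)
  best <- 0
  for (a in pi / 2 * seq_len(grid) / (grid + 1L)) {
    s <- sin(a) * pos_in - cos(a) * neg_in
    o <- order(-s)
    tp <- cumsum(y[o])
    f1 <- 2 * tp / (seq_along(s) + P)
    boundary <- c(s[o][-length(s)] > s[o][-1L], TRUE)
    f1[!boundary] <- 0
    best <- max(best, f1)
  }
  best
}

# Small random gene table with known structure for distance oracles.
random_gene_table <- function(seed, n_genomes = 3L, genes = 12L) {
  casnet:::with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_genomes)) {
      for (ct in 1:2) {
        start <- cumsum(sample(200:1200, genes))
        end <- start + sample(100:800, genes)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = sprintf("G%d", g),
          contig_id = sprintf("G%d_C%d", g, ct),
          start = as.integer(start), end = as.integer(end),
          strand = sample(c("+", "-"), genes, replace = TRUE),
          family_id = sample(c("FAMX", sprintf("B%d", 1:6)), genes,
                             replace = TRUE),
          is_cas = sample(c(TRUE, FALSE), genes, replace = TRUE,
                          prob = c(0.2, 0.8)),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab$family_id[tab$is_cas] <- "CAS"
    tab
  })
}

# Random Erdos-Renyi edge set over named nodes.
random_graph_fixture <- function(seed, n, p_edge) {
  casnet:::with_seed(seed, {
    nodes <- sprintf("V%03d", seq_len(n))
    pairs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pairs)) < p_edge
    list(nodes = nodes,
         edges = cbind(nodes[pairs[1L, keep]], nodes[pairs[2L, keep]]))
  })
}
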