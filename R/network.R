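
# network_inference: nonparanormal transform, sure independence screening,
# Meinshausen-Buhlmann neighborhood selection along a lambda path,
# rotation-based regularization selection, OR/AND symmetrization.
#
# The lasso is solved by cyclic coordinate descent on the Gram matrix with
# the objective (1/2n)*RSS + lambda*||b||_1 (no intercept; columns already
# standardized by the nonparanormal transform), convergence when the largest
# coefficient change in a sweep is < 1e-7, support = |coef| > 1e-8.

NPN_ZERO_TOL <- 1e-8
CD_TOL <- 1e-7
CD_MAX_IT <- 10000L

#' Nonparanormal (rank-Gaussian) transform of an abundance matrix
#'
#' Each family's values are replaced by standard-normal quantiles of their
#' shrunken empirical ranks, r/(n+1) (ties get average ranks), then centered
#' and scaled to unit sample variance. The output depends on the data only
#' through within-family ranks, so it is invariant to strictly monotone
#' per-family transforms -- the property that lets Gaussian graphical-model
#' machinery run on skewed, heavy-tailed abundance data.
#'
#' @param A an [abundance_matrix()] or plain numeric matrix
#'   (families x samples) with at least 3 samples.
#' @return numeric matrix of the same shape, class `npn_matrix`; each row has
#'   mean 0 and sample variance 1.
#' @export
npn_transform <- function(A) {
  vals <- unclass(A)
  if (ncol(vals) < 3L) stop_casnet("need at least 3 samples")
  const <- apply(vals, 1L, function(x) all(x == x[1L]))
  if (any(const)) {
    stop_casnet("constant row(s): ",
                paste(rownames(vals)[const], collapse = ", "),
                " (filter before transforming)")
  }
  n <- ncol(vals)
  out <- t(apply(vals, 1L, function(x) {
    z <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
    z <- z - mean(z)
    z / stats::sd(z)
  }))
  dimnames(out) <- dimnames(vals)
  class(out) <- c("npn_matrix", "matrix", "array")
  out
}

# Gram matrix of families over samples: S[i,j] = <x_i, x_j>/n. This is the
# only statistic the lasso path needs; computing it once makes the whole
# path cheap. On npn rows, S approximately equals the correlation matrix
# (exactly cor * (n-1)/n).
family_gram <- function(X) {
  n <- ncol(X)
  tcrossprod(unclass(X)) / n
}

#' Sure-independence-screening candidate set for one node
#'
#' The k families (excluding the node itself) with the largest absolute
#' Pearson correlation to the node; ties broken deterministically by family
#' order. k larger than p-1 is clamped.
#'
#' @param X an `npn_matrix` (families x samples).
#' @param node family id or row index.
#' @param k number of candidates to keep.
#' @return character vector of candidate family ids.
#' @export
screen_candidates <- function(X, node, k) {
  stopifnot(k >= 1L)
  S <- family_gram(X)
  screen_candidates_gram(S, node, k, rownames(X))
}

screen_candidates_gram <- function(S, node, k, ids) {
  i <- if (is.character(node)) match(node, ids) else node
  a <- abs(S[i, ])
  a[i] <- -Inf
  k <- min(k, length(ids) - 1L)
  # order() is stable: ties resolve in family-id (row) order
  ids[order(-a)[seq_len(k)]]
}

# Default screening budget: the standard n/log(n) sure-screening size.
default_screen_k <- function(p, n) {
  min(p - 1L, as.integer(ceiling(n / log(n))))
}

# Cyclic coordinate descent for the lasso on a Gram submatrix.
# G: k x k Gram of candidates, c: length-k <x_j, y>/n, lambda: penalty.
lasso_cd <- function(G, c, lambda, b0 = NULL) {
  k <- length(c)
  b <- if (is.null(b0)) numeric(k) else b0
  d <- diag(G)
  for (it in seq_len(CD_MAX_IT)) {
    delta <- 0
    for (j in seq_len(k)) {
      rj <- c[j] - sum(G[j, ] * b) + d[j] * b[j]
      bn <- sign(rj) * max(abs(rj) - lambda, 0) / d[j]
      delta <- max(delta, abs(bn - b[j]))
      b[j] <- bn
    }
    if (delta < CD_TOL) return(b)
  }
  stop_casnet("lasso coordinate descent did not converge after ", CD_MAX_IT,
              " sweeps (lambda = ", signif(lambda, 4), ", k = ", k, ")")
}

#' Meinshausen-Buhlmann lasso neighborhood of one node
#'
#' Solves the lasso regression of the node's profile on the candidate
#' profiles (objective `(1/2n)*RSS + lambda*L1`, no intercept) and returns
#' the candidates with nonzero coefficients.
#'
#' @param X an `npn_matrix`.
#' @param node family id.
#' @param lambda positive penalty.
#' @param candidates character vector of candidate family ids; defaults to
#'   all other families.
#' @return character vector of selected neighbor ids.
#' @export
mb_neighborhood <- function(X, node, lambda, candidates = NULL) {
  ids <- rownames(X)
  if (is.null(candidates)) candidates <- setdiff(ids, node)
  S <- family_gram(X)
  i <- match(node, ids)
  j <- match(candidates, ids)
  b <- lasso_cd(S[j, j, drop = FALSE], S[j, i], lambda)
  candidates[abs(b) > NPN_ZERO_TOL]
}

#' Fit the Meinshausen-Buhlmann graph path
#'
#' Lambdas are log-spaced from the global null threshold `lambda_max` (the
#' largest absolute pairwise inner product `<x_i,x_j>/n`, at which every
#' neighborhood is empty) down to `lambda_max * lambda_min_ratio`. At each
#' lambda, every node's lasso neighborhood is computed (with sure
#' independence screening by default) and neighborhoods are symmetrized into
#' an unweighted graph: OR rule keeps an edge if either endpoint selects the
#' other, AND requires both.
#'
#' @param X an `npn_matrix` (families x samples).
#' @param nlambda path length; default 30.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`;
#'   default 0.1.
#' @param screen use sure independence screening; default TRUE.
#' @param screen_k screening budget per node; default
#'   `min(p-1, ceiling(n/log(n)))`.
#' @param sym `"or"` (default) or `"and"` symmetrization.
#' @return list of class `mb_path`: `lambdas` (decreasing), `graphs` (one
#'   igraph per lambda), `edge_counts`, `lambda_max`, `sym`.
#' @export
fit_path <- function(X, nlambda = 30L, lambda_min_ratio = 0.1,
                     screen = TRUE, screen_k = NULL, sym = c("or", "and")) {
  sym <- match.arg(sym)
  stopifnot(nlambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
  ids <- rownames(X)
  p <- nrow(X)
  n <- ncol(X)
  S <- family_gram(X)
  off <- abs(S)
  diag(off) <- 0
  lambda_max <- max(off)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = nlambda))
  if (is.null(screen_k)) screen_k <- default_screen_k(p, n)
  cand <- lapply(seq_len(p), function(i) {
    if (screen) {
      match(screen_candidates_gram(S, i, screen_k, ids), ids)
    } else {
      setdiff(seq_len(p), i)
    }
  })
  graphs <- vector("list", nlambda)
  warm <- vector("list", p)
  for (l in seq_along(lambdas)) {
    lam <- lambdas[l]
    nb <- matrix(FALSE, p, p)
    for (i in seq_len(p)) {
      j <- cand[[i]]
      b <- lasso_cd(S[j, j, drop = FALSE], S[j, i], lam, b0 = warm[[i]])
      warm[[i]] <- b
      nb[i, j[abs(b) > NPN_ZERO_TOL]] <- TRUE
    }
    adj <- if (sym == "or") nb | t(nb) else nb & t(nb)
    ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
    graphs[[l]] <- family_graph(ids, cbind(ids[ut[, 1L]], ids[ut[, 2L]]))
  }
  structure(list(lambdas = lambdas, graphs = graphs,
                 edge_counts = vapply(graphs, function(g)
                   as.integer(igraph::ecount(g)), integer(1L)),
                 lambda_max = lambda_max, sym = sym),
            class = "mb_path")
}

#' Select the regularization parameter by random rotations
#'
#' For each rotation the sample order of every family is permuted
#' independently, destroying all cross-family dependence while preserving
#' marginals; the smallest lambda at which the rotated data's graph is empty
#' is its null threshold `lambda_max`. The selected lambda is the mean of
#' these null thresholds over rotations, snapped to the smallest path lambda
#' greater than or equal to it (clamped to the path's ends). This is a
#' reconstruction in the spirit of the rotation information criterion used
#' with neighborhood-selection software; the selected lambda is always
#' reported.
#'
#' @param X the `npn_matrix` the path was fitted on.
#' @param path an `mb_path` from [fit_path()].
#' @param n_rotations number of rotations; default 20.
#' @param seed integer seed.
#' @return list: `lambda` (selected value), `index` (position in the path),
#'   `graph` (the selected igraph), `rotation_lambda_max` (per-rotation null
#'   thresholds).
#' @export
select_ric <- function(X, path, n_rotations = 20L, seed = 1L) {
  stopifnot(inherits(path, "mb_path"), n_rotations >= 1L)
  vals <- unclass(X)
  n <- ncol(vals)
  rot_max <- with_seed(seed, vapply(seq_len(n_rotations), function(r) {
    rot <- t(apply(vals, 1L, function(x) x[sample.int(n)]))
    S <- tcrossprod(rot) / n
    off <- abs(S)
    diag(off) <- 0
    max(off)
  }, numeric(1L)))
  target <- mean(rot_max)
  ge <- which(path$lambdas >= target)
  idx <- if (length(ge) == 0L) 1L else max(ge)  # lambdas decreasing
  message("rotation-selected lambda: ", signif(path$lambdas[idx], 4),
          " (rotation mean ", signif(target, 4), ", path index ", idx, ")")
  list(lambda = path$lambdas[idx], index = idx, graph = path$graphs[[idx]],
       rotation_lambda_max = rot_max)
}

#' Write a path summary (lambda, edge count) as TSV
#'
#' @param path an `mb_path`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path_summary <- function(path, file) {
  utils::write.table(
    data.frame(lambda = path$lambdas, n_edges = path$edge_counts),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
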