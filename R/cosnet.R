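
# cosnet_propagation: imbalance-aware Hopfield label propagation.
#
# Labeled nodes are projected to (positive-neighbor input, negative-neighbor
# input) points; a line through that plane, parameterized by an activation
# angle alpha and intercept q, is fitted to maximize F1 on the labeled set;
# the unlabeled sub-network then runs clamped asynchronous Hopfield dynamics
# with bipolar states {sin(alpha), -cos(alpha)} and per-node thresholds
# theta_i = q + eta - (clamped-neighbor input). Terminal states at
# sin(alpha) are the predicted positives.

#' Hopfield parameters
#'
#' @param alpha activation angle in (0, pi/2): positive state `sin(alpha)`,
#'   negative state `-cos(alpha)`.
#' @param q intercept of the separating line (neuron threshold base).
#' @param eta regularization added to every unlabeled neuron's threshold,
#'   biasing against positive states; the reference analysis uses 1e-4.
#' @return list of class `hopfield_params`.
#' @export
hopfield_params <- function(alpha, q, eta = 1e-4) {
  stopifnot(alpha > 0, alpha < pi / 2, eta >= 0)
  structure(list(alpha = alpha, q = q, eta = eta), class = "hopfield_params")
}

#' Project labeled nodes to neighbor-input space
#'
#' For every labeled (POSITIVE or NEGATIVE) node, counts its labeled
#' POSITIVE neighbors (`pos_input`) and labeled NEGATIVE neighbors
#' (`neg_input`) on the unweighted graph. Unlabeled neighbors contribute
#' nothing.
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()].
#' @return data.frame (family, pos_input, neg_input, label).
#' @export
project_labeled <- function(g, labels) {
  nodes <- igraph::V(g)$name
  lab <- labels[nodes]
  labeled <- nodes[lab %in% c("POSITIVE", "NEGATIVE")]
  adj <- igraph::adjacent_vertices(g, labeled)
  rows <- lapply(seq_along(labeled), function(i) {
    nb <- adj[[i]]$name
    nb_lab <- lab[match(nb, nodes)]
    data.frame(family = labeled[i],
               pos_input = sum(nb_lab == "POSITIVE"),
               neg_input = sum(nb_lab == "NEGATIVE"),
               label = as.character(lab[match(labeled[i], nodes)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(family = character(0L), pos_input = numeric(0L),
               neg_input = numeric(0L), label = character(0L))
  out
}

#' Fit the F1-optimal separating line in neighbor-input space
#'
#' Candidate angles are an even grid over (0, pi/2) augmented with the exact
#' crossing angles between projected points (midpoints of consecutive
#' crossings), so the returned optimum is exact over all (alpha, q) pairs:
#' for each candidate alpha, the score `s_i = sin(alpha)*pos_i -
#' cos(alpha)*neg_i` is computed and every intercept between consecutive
#' sorted scores is scanned; a point is classified positive iff `s_i > q`.
#' Ties in F1 are broken toward the most conservative classifier: fewest
#' predicted positives on the labeled set, then the largest alpha (strongest
#' positive activation relative to the negative one), the intercept being
#' the midpoint above the last predicted positive.
#'
#' @param points data.frame from [project_labeled()] (columns `pos_input`,
#'   `neg_input`).
#' @param labels logical vector (TRUE = POSITIVE) or character labels
#'   aligned with `points`.
#' @param angle_grid_size size of the base angle grid; default 180.
#' @param eta regularization passed through to the returned params.
#' @return a [hopfield_params()] with attributes `f1` (training F1) and
#'   `degenerate`.
#' @export
fit_line <- function(points, labels, angle_grid_size = 180L, eta = 1e-4) {
  pos_in <- points$pos_input
  neg_in <- points$neg_input
  y <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "POSITIVE"
  } else {
    as.logical(labels)
  }
  stopifnot(length(y) == length(pos_in))
  if (!any(y) || all(y)) {
    stop_casnet("need at least one POSITIVE and one NEGATIVE labeled point")
  }
  pts <- unique(data.frame(p = pos_in, n = neg_in))
  if (nrow(pts) == 1L) {
    s <- sin(pi / 4) * pts$p - cos(pi / 4) * pts$n
    warning("all projected points identical; returning degenerate line")
    par <- hopfield_params(pi / 4, s + 1e-6, eta)
    attr(par, "f1") <- 0
    attr(par, "degenerate") <- TRUE
    return(par)
  }
  alphas <- pi / 2 * seq_len(angle_grid_size) / (angle_grid_size + 1L)
  # exact crossing angles: tan(a) = (n_i - n_j) / (p_i - p_j) when > 0
  cmb <- utils::combn(nrow(pts), 2L)
  dp <- pts$p[cmb[1L, ]] - pts$p[cmb[2L, ]]
  dn <- pts$n[cmb[1L, ]] - pts$n[cmb[2L, ]]
  ratio <- dn / dp
  cross <- sort(unique(atan(ratio[is.finite(ratio) & ratio > 0])))
  if (length(cross) > 0L) {
    knots <- c(0, cross, pi / 2)
    alphas <- sort(unique(c(alphas, cross, (knots[-1L] + knots[-length(knots)]) / 2)))
  }
  alphas <- alphas[alphas > 0 & alphas < pi / 2]
  P <- sum(y)
  best <- list(f1 = -Inf, k = .Machine$integer.max, alpha = -Inf, q = NA_real_)
  for (a in alphas) {
    s <- sin(a) * pos_in - cos(a) * neg_in
    o <- order(-s)
    ss <- s[o]
    tp <- cumsum(y[o])
    kk <- seq_along(ss)
    # valid cut positions: after the last occurrence of each distinct score
    boundary <- c(ss[-length(ss)] > ss[-1L], TRUE)
    f1 <- 2 * tp / (kk + P)  # = 2tp / (2tp + fp + fn)
    f1[!boundary] <- -Inf
    k_best <- which.max(f1)  # ties -> smallest k (fewest positives)
    f1_best <- f1[k_best]
    for (cd in list(list(f1 = 0, k = 0L),
                    list(f1 = f1_best, k = k_best))) {
      better <- cd$f1 > best$f1 + 1e-12 ||
        (abs(cd$f1 - best$f1) <= 1e-12 &&
           (cd$k < best$k || (cd$k == best$k && a > best$alpha)))
      if (better) {
        q <- if (cd$k == 0L) {
          ss[1L]
        } else if (cd$k == length(ss)) {
          ss[length(ss)] - 1
        } else {
          (ss[cd$k] + ss[cd$k + 1L]) / 2
        }
        best <- list(f1 = cd$f1, k = cd$k, alpha = a, q = q)
      }
    }
  }
  par <- hopfield_params(best$alpha, best$q, eta)
  attr(par, "f1") <- best$f1
  attr(par, "degenerate") <- FALSE
  par
}

#' Run clamped asynchronous Hopfield dynamics on the unlabeled sub-network
#'
#' Labeled nodes are clamped at `sin(alpha)` (POSITIVE) or `-cos(alpha)`
#' (NEGATIVE) and folded into per-node thresholds
#' `theta_i = q + eta - sum_j W_ij x_j` over labeled neighbors j. Unlabeled
#' states start neutral (0), so the first sweep classifies every unlabeled
#' node exactly as the fitted line classifies its clamped-neighbor input,
#' and subsequent sweeps propagate; updates are asynchronous in a freshly
#' drawn random permutation each sweep:
#' `x_i <- sin(alpha)` iff the unlabeled-neighbor input exceeds `theta_i`.
#' The energy `E = -1/2 sum W_ij x_i x_j + sum theta_i x_i` (sums over
#' unlabeled nodes) is recorded after every sweep and is non-increasing;
#' the run stops at the first unchanged sweep (a fixed point) or at
#' `max_sweeps` (flagged, not fatal).
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()] over the graph's nodes.
#' @param params a [hopfield_params()].
#' @param max_sweeps sweep budget; default 100.
#' @param seed integer seed for the update permutations.
#' @return list of class `hopfield_state`: `state` (named vector over
#'   unlabeled nodes), `energies` (one per sweep), `converged`, `n_sweeps`,
#'   `params`.
#' @export
run_dynamics <- function(g, labels, params, max_sweeps = 100L, seed = 1L) {
  stopifnot(inherits(params, "hopfield_params"))
  nodes <- igraph::V(g)$name
  lab <- labels[nodes]
  if (anyNA(lab)) stop_casnet("labels missing for some graph nodes")
  s_pos <- sin(params$alpha)
  s_neg <- -cos(params$alpha)
  is_un <- lab == "UNANNOTATED"
  un <- which(is_un)
  clamp <- ifelse(lab == "POSITIVE", s_pos, s_neg)
  adj <- igraph::as_adj_list(g)
  nb_idx <- lapply(adj, function(v) as.integer(v))
  # threshold: q + eta minus clamped-neighbor input
  theta <- vapply(un, function(i) {
    nb <- nb_idx[[i]]
    params$q + params$eta - sum(clamp[nb[!is_un[nb]]])
  }, numeric(1L))
  names(theta) <- nodes[un]
  # neighbors restricted to the unlabeled sub-network, re-indexed into `un`
  pos_of <- integer(length(nodes))
  pos_of[un] <- seq_along(un)
  nb_un <- lapply(un, function(i) pos_of[nb_idx[[i]][is_un[nb_idx[[i]]]]])
  x <- numeric(length(un))  # neutral start; bipolar after the first sweep
  energies <- numeric(0L)
  converged <- FALSE
  n_sweeps <- 0L
  energy <- function(x) {
    inter <- sum(vapply(seq_along(un), function(k) {
      x[k] * sum(x[nb_un[[k]]])
    }, numeric(1L))) / 2
    -inter + sum(theta * x)
  }
  with_seed(seed, {
    for (sw in seq_len(max_sweeps)) {
      changed <- FALSE
      for (k in sample.int(length(un))) {
        input <- sum(x[nb_un[[k]]])
        newx <- if (input - theta[k] > 0) s_pos else s_neg
        if (newx != x[k]) {
          x[k] <- newx
          changed <- TRUE
        }
      }
      n_sweeps <- sw
      energies <- c(energies, energy(x))
      if (!changed) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged && length(un) > 0L) {
    warning("Hopfield dynamics hit max_sweeps without a fixed point")
  }
  if (length(un) == 0L) converged <- TRUE
  structure(list(state = stats::setNames(x, nodes[un]), energies = energies,
                 converged = converged, n_sweeps = n_sweeps, params = params),
            class = "hopfield_state")
}

#' Predict positive (cas) families by label propagation
#'
#' Full pipeline: project labeled nodes, fit the F1-optimal line, run the
#' clamped Hopfield dynamics, and report the unlabeled nodes whose terminal
#' state is the positive activation. Deterministic under a fixed seed.
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()]; needs at least one POSITIVE node.
#' @param eta threshold regularization; default 1e-4.
#' @param seed integer seed.
#' @param angle_grid_size passed to [fit_line()].
#' @param max_sweeps passed to [run_dynamics()].
#' @return list: `predicted` (character vector of predicted-positive
#'   unlabeled nodes), `state` (`hopfield_state`), `params`, `projection`.
#' @export
predict_cas <- function(g, labels, eta = 1e-4, seed = 1L,
                        angle_grid_size = 180L, max_sweeps = 100L) {
  nodes <- igraph::V(g)$name
  lab <- labels[nodes]
  if (!any(lab == "POSITIVE")) stop_casnet("no POSITIVE labeled node")
  proj <- project_labeled(g, labels)
  params <- fit_line(proj, proj$label, angle_grid_size = angle_grid_size,
                     eta = eta)
  st <- run_dynamics(g, labels, params, max_sweeps = max_sweeps, seed = seed)
  predicted <- names(st$state)[st$state == sin(params$alpha)]
  list(predicted = predicted, state = st, params = params, projection = proj)
}

# Confusion counts -> derived metrics.
perf_metrics <- function(tp, fp, tn, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn, precision = precision,
       recall = recall, f1 = f1, fpr = fpr)
}

#' Stratified k-fold cross-validation of the propagation pipeline
#'
#' POSITIVE nodes are dealt round-robin across folds after a seeded shuffle
#' (so fold positive counts differ by at most one); the remaining annotated
#' (NEGATIVE) nodes are spread the same way. For each fold the held-out
#' labels are set to UNANNOTATED for propagation and predictions are scored
#' only against the held-out annotated nodes; never-annotated nodes
#' participate in propagation but never in metrics.
#'
#' @param g igraph with named vertices.
#' @param labels a [label_vector()]; needs at least `k` POSITIVE nodes.
#' @param k number of folds; default 5.
#' @param eta threshold regularization; default 1e-4.
#' @param seed integer seed (fold assignment + per-fold dynamics).
#' @param ... passed to [predict_cas()].
#' @return list: `folds` (per-fold metric data.frame), `pooled` (metrics on
#'   pooled counts), `assignment` (named fold index per annotated node).
#' @export
cross_validate <- function(g, labels, k = 5L, eta = 1e-4, seed = 1L, ...) {
  nodes <- igraph::V(g)$name
  lab <- labels[nodes]
  pos <- nodes[lab == "POSITIVE"]
  neg <- nodes[lab == "NEGATIVE"]
  if (length(pos) < k) stop_casnet("fewer POSITIVE nodes than folds")
  seeds <- derive_seeds(seed, k + 1L)
  fold <- with_seed(seeds[1L], {
    f <- c(stats::setNames(rep_len(seq_len(k), length(pos)), sample(pos)),
           stats::setNames(rep_len(seq_len(k), length(neg)), sample(neg)))
    f
  })
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    held <- names(fold)[fold == f]
    lab_f <- lab
    names(lab_f) <- nodes
    lab_f[held] <- "UNANNOTATED"
    pred <- predict_cas(g, label_vector(lab_f), eta = eta,
                        seed = seeds[f + 1L], ...)
    is_pred <- held %in% pred$predicted
    truth_pos <- held %in% pos
    m <- perf_metrics(tp = sum(is_pred & truth_pos),
                      fp = sum(is_pred & !truth_pos),
                      tn = sum(!is_pred & !truth_pos),
                      fn = sum(!is_pred & truth_pos))
    rows[[f]] <- data.frame(fold = f, as.data.frame(m))
  }
  folds <- do.call(rbind, rows)
  pooled <- perf_metrics(sum(folds$tp), sum(folds$fp), sum(folds$tn),
                         sum(folds$fn))
  list(folds = folds, pooled = pooled, assignment = fold)
}

#' Random-guess null model for the prediction problem
#'
#' Each repetition predicts a uniformly random subset of `n_pos` of the
#' `n_annotated` annotated nodes as positive and scores it against the fixed
#' true positive set of the same size, reproducing a null that knows only
#' how many cas genes the network contains. Expected precision and recall
#' are both `n_pos / n_annotated`.
#'
#' @param n_annotated number of annotated nodes.
#' @param n_pos number of true positives (and of predicted positives).
#' @param reps repetitions; default 1000.
#' @param seed integer seed.
#' @return data.frame with one row of metrics per repetition.
#' @export
null_model <- function(n_annotated, n_pos, reps = 1000L, seed = 1L) {
  stopifnot(n_pos <= n_annotated, n_pos >= 0L)
  truth <- seq_len(n_pos)
  with_seed(seed, {
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      pred <- sample.int(n_annotated, n_pos)
      tp <- sum(pred %in% truth)
      out[[r]] <- as.data.frame(perf_metrics(
        tp = tp, fp = n_pos - tp,
        tn = n_annotated - 2L * n_pos + tp, fn = n_pos - tp))
    }
    cbind(rep = seq_len(reps), do.call(rbind, out))
  })
}
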