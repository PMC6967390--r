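# Hopfield label propagation: projection, line fitting, dynamics,
# prediction, cross-validation and the random null model.

two_community_graph <- function(seed = 1L) {
  simulate_label_graph(n_nodes = 120L, module_size = 20L, p_within = 0.6,
                       p_background = 0.02, annotated_frac = 0.5,
                       held_out_fraction = 0.5, seed = seed)
}

test_that("project_labeled counts labeled neighbors only", {
  g <- family_graph(c("x", "p1", "p2", "p3", "n1", "u1", "iso"),
                    rbind(c("x", "p1"), c("x", "p2"), c("x", "p3"),
                          c("x", "n1"), c("x", "u1")))
  lab <- label_vector(c(x = "NEGATIVE", p1 = "POSITIVE", p2 = "POSITIVE",
                        p3 = "POSITIVE", n1 = "NEGATIVE", u1 = "UNANNOTATED",
                        iso = "POSITIVE"))
  proj <- project_labeled(g, lab)
  x <- proj[proj$family == "x", ]
  expect_equal(c(x$pos_input, x$neg_input), c(3, 1))
  iso <- proj[proj$family == "iso", ]
  expect_equal(c(iso$pos_input, iso$neg_input), c(0, 0))
  expect_false("u1" %in% proj$family)

  # brute-force neighbor scan on a random 30-node graph
  fx <- random_graph_fixture(8, 30, 0.12)
  g2 <- family_graph(fx$nodes, fx$edges)
  lab2 <- casnet:::with_seed(9, stats::setNames(
    sample(c("POSITIVE", "NEGATIVE", "UNANNOTATED"), 30, replace = TRUE),
    fx$nodes))
  proj2 <- project_labeled(g2, label_vector(lab2))
  for (r in seq_len(nrow(proj2))) {
    f <- proj2$family[r]
    nb <- unique(c(fx$edges[fx$edges[, 1] == f, 2],
                   fx$edges[fx$edges[, 2] == f, 1]))
    expect_equal(proj2$pos_input[r], sum(lab2[nb] == "POSITIVE"))
    expect_equal(proj2$neg_input[r], sum(lab2[nb] == "NEGATIVE"))
  }
})

test_that("fit_line separates separable data and beats a 10x finer grid", {
  # separable: positives high pos_input, negatives high neg_input
  pts <- data.frame(pos_input = c(5, 6, 7, 0, 1, 0),
                    neg_input = c(0, 1, 0, 4, 5, 6))
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  par <- fit_line(pts, y)
  expect_equal(attr(par, "f1"), 1)
  s <- sin(par$alpha) * pts$pos_input - cos(par$alpha) * pts$neg_input
  expect_equal(s > par$q, y)

  # finer-grid oracle on random integer instances
  for (s in 1:20) {
    inst <- casnet:::with_seed(s, data.frame(
      pos_input = sample(0:6, 15, replace = TRUE),
      neg_input = sample(0:6, 15, replace = TRUE)))
    yy <- casnet:::with_seed(s + 100, sample(c(TRUE, FALSE), 15,
                                             replace = TRUE, prob = c(.3, .7)))
    if (!any(yy) || all(yy)) next
    par <- fit_line(inst, yy)
    oracle <- oracle_fit_line_f1(inst$pos_input, inst$neg_input, yy, 1800L)
    expect_gte(attr(par, "f1"), oracle - 1e-6)
  }

  # degenerate: identical points
  same <- data.frame(pos_input = c(2, 2), neg_input = c(1, 1))
  expect_warning(par_d <- fit_line(same, c(TRUE, FALSE)), "degenerate")
  expect_equal(par_d$alpha, pi / 4)
})

test_that("run_dynamics follows clamped inputs and regularization", {
  # unlabeled node ringed by clamped positives converges positive
  star <- family_graph(c("u", paste0("p", 1:6)),
                       cbind("u", paste0("p", 1:6)))
  lab <- label_vector(stats::setNames(c("UNANNOTATED", rep("POSITIVE", 6)),
                                      c("u", paste0("p", 1:6))))
  par <- hopfield_params(alpha = pi / 4, q = 0.5, eta = 1e-4)
  st <- run_dynamics(star, lab, par, seed = 2L)
  expect_equal(unname(st$state["u"]), sin(pi / 4))
  expect_true(st$converged)

  # huge eta suppresses every positive
  par_big <- hopfield_params(alpha = pi / 4, q = 0.5, eta = 100)
  st2 <- run_dynamics(star, lab, par_big, seed = 2L)
  expect_equal(unname(st2$state["u"]), -cos(pi / 4))
})

test_that("energy is non-increasing and terminal states are fixed points", {
  for (s in 1:50) {
    fx <- random_graph_fixture(200 + s, 20, 0.15)
    g <- family_graph(fx$nodes, fx$edges)
    lab <- casnet:::with_seed(s, stats::setNames(
      sample(c("POSITIVE", "NEGATIVE", "UNANNOTATED"), 20, replace = TRUE,
             prob = c(0.2, 0.3, 0.5)), fx$nodes))
    lab <- label_vector(lab)
    par <- casnet:::with_seed(s, hopfield_params(runif(1, 0.2, 1.3),
                                                 runif(1, -1, 1), 1e-4))
    st <- run_dynamics(g, lab, par, seed = s)
    if (length(st$energies) > 1L) {
      expect_true(all(diff(st$energies) <= 1e-12))
    }
    # fixed-point audit: re-evaluate every update rule by hand
    nodes <- igraph::V(g)$name
    state_all <- c(st$state,
                   stats::setNames(ifelse(lab[lab != "UNANNOTATED"] == "POSITIVE",
                                          sin(par$alpha), -cos(par$alpha)),
                                   names(lab)[lab != "UNANNOTATED"]))
    for (u in names(st$state)) {
      nb <- unique(c(fx$edges[fx$edges[, 1] == u, 2],
                     fx$edges[fx$edges[, 2] == u, 1]))
      un_nb <- nb[nb %in% names(st$state)]
      cl_nb <- setdiff(nb, un_nb)
      theta <- par$q + par$eta - sum(state_all[cl_nb])
      want <- if (sum(state_all[un_nb]) - theta > 0) sin(par$alpha) else -cos(par$alpha)
      expect_equal(unname(st$state[u]), want)
    }
  }
})

test_that("predict_cas recovers the planted community and stays quiet without signal", {
  bench <- two_community_graph(seed = 6L)
  res <- predict_cas(bench$graph, bench$labels, seed = 6L)
  hidden_pos <- setdiff(bench$true_cas,
                        names(bench$labels)[bench$labels == "POSITIVE"])
  outside <- setdiff(names(res$state$state), bench$true_cas)
  expect_gt(mean(hidden_pos %in% res$predicted), 0.5)
  expect_lte(mean(outside %in% res$predicted), 0.05)

  # labeled and unlabeled components disconnected -> nothing propagates:
  # clean labeled structure (a positive and a negative clique), plus an
  # unlabeled pair no label can reach
  nodes <- c(paste0("p", 1:4), paste0("n", 1:4), "u1", "u2")
  edges <- rbind(t(utils::combn(paste0("p", 1:4), 2)),
                 t(utils::combn(paste0("n", 1:4), 2)),
                 c("u1", "u2"))
  g <- family_graph(nodes, edges)
  lab <- label_vector(stats::setNames(
    c(rep("POSITIVE", 4), rep("NEGATIVE", 4), "UNANNOTATED", "UNANNOTATED"),
    nodes))
  res2 <- predict_cas(g, lab, seed = 1L)
  expect_length(res2$predicted, 0L)
})

test_that("regularization eta has only a small effect", {
  bench <- two_community_graph(seed = 16L)
  r0 <- predict_cas(bench$graph, bench$labels, eta = 0, seed = 3L)
  r1 <- predict_cas(bench$graph, bench$labels, eta = 1e-4, seed = 3L)
  sym_diff <- union(setdiff(r0$predicted, r1$predicted),
                    setdiff(r1$predicted, r0$predicted))
  expect_lte(length(sym_diff), max(2L, 0.1 * length(r0$predicted)))
})

test_that("cross_validate balances folds and scores only held-out annotated nodes", {
  # 10 positives, k = 5 -> exactly 2 positives per fold
  bench <- simulate_label_graph(n_nodes = 60L, module_size = 10L,
                                p_within = 0.7, p_background = 0.03,
                                annotated_frac = 0.6, seed = 21L)
  cv <- cross_validate(bench$graph, bench$labels, k = 5L, seed = 21L)
  pos <- names(bench$labels)[bench$labels == "POSITIVE"]
  per_fold <- table(cv$assignment[pos])
  expect_true(all(per_fold == 2L))
  # per-fold counts only cover annotated nodes
  ann <- sum(bench$labels != "UNANNOTATED")
  expect_equal(sum(cv$folds$tp + cv$folds$fp + cv$folds$tn + cv$folds$fn), ann)
  expect_error(cross_validate(bench$graph, bench$labels, k = 11L), "fewer")

  # harness check: a trivially separable world (a positive clique and a
  # negative clique) scores perfectly
  nodes <- c(paste0("P", 1:10), paste0("N", 1:10))
  edges <- rbind(t(utils::combn(paste0("P", 1:10), 2)),
                 t(utils::combn(paste0("N", 1:10), 2)))
  g <- family_graph(nodes, edges)
  lab <- label_vector(stats::setNames(rep(c("POSITIVE", "NEGATIVE"), each = 10),
                                      nodes))
  cvp <- cross_validate(g, lab, k = 5L, seed = 2L)
  expect_equal(cvp$pooled$precision, 1)
  expect_equal(cvp$pooled$recall, 1)
  expect_equal(cvp$pooled$f1, 1)
})

test_that("null_model matches its analytic expectation", {
  # degenerate: predicting everything positive
  nm_all <- null_model(20L, 20L, reps = 5L, seed = 1L)
  expect_true(all(nm_all$precision == 1 & nm_all$recall == 1))

  nm <- null_model(200L, 10L, reps = 4000L, seed = 8L)
  se <- stats::sd(nm$precision) / sqrt(nrow(nm))
  expect_lt(abs(mean(nm$precision) - 10 / 200), 3 * se)
  expect_equal(mean(nm$precision), mean(nm$recall))  # same denominator here

  # determinism
  nm2 <- null_model(200L, 10L, reps = 100L, seed = 8L)
  nm3 <- null_model(200L, 10L, reps = 100L, seed = 8L)
  expect_identical(nm2, nm3)
})
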