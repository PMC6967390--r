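
# cli_pipeline: configuration handling, end-to-end orchestration and the
# planted-truth simulation suite. A thin Rscript front end lives in
# inst/cli/casnet.R; all logic is in these exported functions.

#' Default run configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' stochastic stage's seed derived from one master seed. Fields can be
#' overridden by `...` or by a JSON config file via [read_run_config()].
#'
#' Defaults: 10% prevalence filter, 30-lambda path with sure independence
#' screening and OR symmetrization, 20 rotations for lambda selection,
#' 1e-4 threshold regularization, 5 balanced folds.
#'
#' @param seed master seed; default 1.
#' @param ... overrides for any configuration field.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  seeds <- derive_seeds(seed, 5L)
  cfg <- list(
    seed = as.integer(seed),
    synthetic = list(p = 60L, n = 300L, module_sizes = c(10L, 10L),
                     within_module_partial_corr = 0.4, zero_inflation = 0,
                     n_markers = 10L, cas_module_index = 1L,
                     labeled_fraction = 0.5, seed = seeds[1L]),
    # profile_path / label_path / marker_path / type_map_path are optional
    # overrides; when absent the synthetic generator supplies the inputs
    min_frac = 0.10,
    nlambda = 30L, lambda_min_ratio = 0.1, screen = TRUE, sym = "or",
    n_rotations = 20L,
    eta = 1e-4, k_folds = 5L,
    clustering_draws = 999L,
    max_sweeps = 100L,
    seed_network = seeds[2L], seed_clustering = seeds[3L],
    seed_cv = seeds[4L], seed_predict = seeds[5L])
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a JSON run configuration
#'
#' Any field present in the file overrides the default configuration built
#' from the file's `seed` (or 1); the result round-trips unchanged through
#' [write_run_config()].
#'
#' @param path JSON file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_casnet("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (nm in names(raw)) {
    if (nm == "synthetic" && is.list(raw[[nm]])) {
      cfg$synthetic[names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration as JSON
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Null-world (pi_coloc = 0) permutation p-values, one synthetic genome
# collection per seed with heterogeneous contig structure.
calibration_pvalues <- function(cal_seeds, n_genomes = 150L, n_perm = 599L) {
  vapply(cal_seeds, function(s) {
    shape <- with_seed(s, c(sample(3:8, 1L), sample(10:30, 1L)))
    gcfg <- synthetic_genome_config(
      n_genomes = n_genomes,
      contigs_per_genome = shape[1L],
      genes_per_contig = shape[2L],
      pi_coloc = 0, seed = s)
    tab <- simulate_genomes(gcfg)
    orf_reassignment_test(tab, "FAMCOLOC", n_perm = n_perm, seed = s)$p_value
  }, numeric(1L))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_casnet("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full prediction pipeline
#'
#' Executes normalize -> prevalence filter -> nonparanormal transform ->
#' network inference (path + rotation selection) -> clustering check ->
#' cross-validation -> prediction -> putative-type assignment, writing all
#' artifacts plus a manifest (configuration, seeds, stage summaries) into
#' `out_dir`. Inputs are either files named in the config or, by default,
#' the bundled synthetic generator, in which case ground truth is also
#' written. Fully deterministic for a fixed config.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("casnet")))

  truth <- NULL
  if (!is.null(config$profile_path)) {
    A <- run_stage("read_profiles", {
      if (!file.exists(config$profile_path)) {
        stop("missing input path: ", config$profile_path)
      }
      read_profile_table(config$profile_path)
    })
    labels_all <- run_stage("read_labels", read_label_map(config$label_path))
    markers <- run_stage("read_markers",
                         readLines(config$marker_path, encoding = "UTF-8"))
  } else {
    sim <- run_stage("simulate", {
      scfg <- do.call(synthetic_network_config, config$synthetic)
      prec <- make_precision(scfg)
      list(cfg = scfg, prec = prec, A = sample_abundances(prec$omega, scfg))
    })
    A <- sim$A
    truth <- sim$prec$truth
    labels_all <- synthetic_labels(sim$cfg, truth)
    markers <- synthetic_family_ids(sim$cfg)$markers
    utils::write.table(data.frame(from = truth$edges[, 1L],
                                  to = truth$edges[, 2L]),
                       file.path(out_dir, "true_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  norm <- run_stage("normalize", normalize_by_markers(A, markers))
  filt <- run_stage("filter", filter_prevalence(norm, config$min_frac))
  manifest$n_families_in <- nrow(A)
  manifest$n_families_filtered <- nrow(filt)

  X <- run_stage("npn", npn_transform(filt))
  path <- run_stage("network", fit_path(X, nlambda = config$nlambda,
                                        lambda_min_ratio = config$lambda_min_ratio,
                                        screen = config$screen,
                                        sym = config$sym))
  sel <- run_stage("select", select_ric(X, path,
                                        n_rotations = config$n_rotations,
                                        seed = config$seed_network))
  g <- sel$graph
  manifest$selected_lambda <- sel$lambda
  manifest$n_edges <- igraph::ecount(g)
  write_path_summary(path, file.path(out_dir, "path_summary.tsv"))
  write_edgelist_tsv(g, file.path(out_dir, "network_edges.tsv"))
  write_graphml(g, file.path(out_dir, "network.graphml"))

  labels <- label_vector(labels_all[igraph::V(g)$name])

  clust <- run_stage("clustering", {
    clustering_statistic(g, labels, n_draws = config$clustering_draws,
                         seed = config$seed_clustering)
  })
  manifest$clustering <- list(observed = clust$observed,
                              p_value = clust$p_value)
  dist_prof <- distances_to_labeled(g, labels)
  utils::write.table(
    data.frame(family = names(dist_prof),
               hops_to_cas = ifelse(is.finite(dist_prof), dist_prof, NA)),
    file.path(out_dir, "distance_to_cas.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  cv <- run_stage("cross_validate", {
    cross_validate(g, labels, k = config$k_folds, eta = config$eta,
                   seed = config$seed_cv, max_sweeps = config$max_sweeps)
  })
  utils::write.table(cv$folds, file.path(out_dir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$cv_pooled <- cv$pooled

  pred <- run_stage("predict", {
    predict_cas(g, labels, eta = config$eta, seed = config$seed_predict,
                max_sweeps = config$max_sweeps)
  })
  pred_tab <- data.frame(family = names(pred$state$state),
                         score = as.numeric(pred$state$state),
                         predicted_cas = names(pred$state$state) %in%
                           pred$predicted)
  pred_tab <- pred_tab[order(pred_tab$family), ]
  utils::write.table(pred_tab, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$n_predicted <- length(pred$predicted)
  manifest$hopfield <- list(alpha = pred$params$alpha, q = pred$params$q,
                            eta = pred$params$eta,
                            sweeps = pred$state$n_sweeps,
                            converged = pred$state$converged)

  if (!is.null(config$type_map_path)) {
    tm <- utils::read.table(config$type_map_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    type_map <- stats::setNames(tm[[2L]], tm[[1L]])
    types <- run_stage("types",
                       assign_putative_types(g, pred$predicted, type_map))
    utils::write.table(types, file.path(out_dir, "putative_types.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(truth)) {
    manifest$edge_recovery <- edge_recovery(g, truth$edges)
    manifest$true_cas_predicted <-
      length(intersect(pred$predicted, truth$true_cas))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Run the planted-truth benchmark suite
#'
#' Re-runs the package's three headline benchmarks -- conditional-dependence
#' network recovery, propagation recovery under cross-validation, and
#' permutation-test calibration -- against fixed thresholds, and returns a
#' pass/fail table. `reduced = TRUE` scales the replication counts down
#' (faster, lower power; thresholds unchanged except the calibration
#' family count).
#'
#' @param seed master seed; default 1.
#' @param reduced scale replication counts down; default FALSE.
#' @return data.frame (check, value, threshold, pass).
#' @export
run_simulation_suite <- function(seed = 1L, reduced = FALSE) {
  seeds <- derive_seeds(seed, 4L)
  checks <- list()

  # 1. network recovery on the default synthetic world
  scfg <- synthetic_network_config(seed = seeds[1L])
  prec <- make_precision(scfg)
  A <- sample_abundances(prec$omega, scfg)
  X <- npn_transform(filter_prevalence(
    normalize_by_markers(A, synthetic_family_ids(scfg)$markers)))
  path <- fit_path(X)
  sel <- select_ric(X, path, seed = seeds[1L])
  rec <- edge_recovery(sel$graph, prec$truth$edges)
  checks$network_recovery_f1 <- list(value = rec$f1, threshold = 0.6,
                                     pass = rec$f1 >= 0.6)

  # 2. propagation recovery on the planted-community benchmark
  bench <- simulate_label_graph(seed = seeds[2L])
  cv <- cross_validate(bench$graph, bench$labels, k = 5L, seed = seeds[2L])
  nm <- null_model(n_annotated = sum(bench$labels != "UNANNOTATED"),
                   n_pos = sum(bench$labels == "POSITIVE"),
                   reps = if (reduced) 1000L else 10000L, seed = seeds[2L])
  null_q <- stats::quantile(nm$f1, 0.975, names = FALSE)
  checks$propagation_fpr <- list(value = cv$pooled$fpr, threshold = 0.05,
                                 pass = cv$pooled$fpr < 0.05)
  checks$propagation_f1_vs_null <- list(value = cv$pooled$f1,
                                        threshold = null_q,
                                        pass = cv$pooled$f1 > null_q)

  # 3. permutation calibration under the null (pi_coloc = 0); 150 genomes
  # so the 1/n_genomes lattice of the statistic is fine enough for KS
  n_fam <- if (reduced) 50L else 200L
  cal_seeds <- derive_seeds(seeds[3L], n_fam)
  pvals <- calibration_pvalues(cal_seeds)
  # ties are expected (discrete statistic); they only make the test
  # conservative, so the KS warning is suppressed
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  checks$calibration_ks_p <- list(value = ks$p.value, threshold = 0.01,
                                  pass = ks$p.value > 0.01)

  # planted colocation must be detected at the add-one floor
  gcfg1 <- synthetic_genome_config(pi_coloc = 1, n_genomes = 40L,
                                   seed = seeds[4L])
  pt <- orf_reassignment_test(simulate_genomes(gcfg1), "FAMCOLOC",
                              n_perm = if (reduced) 999L else 10000L,
                              seed = seeds[4L])
  floor_p <- 1 / (pt$n_perm + 1)
  checks$planted_colocation_p <- list(value = pt$p_value, threshold = floor_p,
                                      pass = pt$p_value == floor_p)

  data.frame(check = names(checks),
             value = vapply(checks, function(x) x$value, numeric(1L)),
             threshold = vapply(checks, function(x) x$threshold, numeric(1L)),
             pass = vapply(checks, function(x) x$pass, logical(1L)),
             row.names = NULL)
}
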