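
# synthetic_data: latent Gaussian-copula abundance matrices with a planted
# sparse precision matrix, planted community graphs for label propagation,
# and synthetic genomes with planted cas-adjacent families.

#' Configuration for the synthetic abundance generator
#'
#' The generator emulates a marine-metagenome functional profile: `p` gene
#' families measured across `n` samples, with conditional dependence planted
#' as chain-structured modules in a sparse precision matrix, a set of
#' single-copy marker families (independent of everything), and optional
#' zero-inflation mimicking rare families. One module (by default the first)
#' is the "cas module" carrying the positive labels.
#'
#' Modules are chains rather than fully connected blocks: an equicorrelated
#' partial-correlation block of size m is positive definite only for
#' r < 1/(m-1), so a common partial correlation of, say, 0.4 across a
#' 10-member module is impossible. A chain attains the requested pairwise
#' partial correlation exactly on every planted edge, stays diagonally
#' dominant for any module size whenever r < 0.5, and matches the standard
#' "band" benchmark used for graphical-model recovery.
#'
#' @param p total number of families (modules + markers + background).
#' @param n number of samples.
#' @param module_sizes integer vector of planted chain-module sizes.
#' @param within_module_partial_corr common partial correlation on planted
#'   edges, in `[0, 0.5)`.
#' @param zero_inflation probability a non-marker cell is zeroed, in `[0, 1)`.
#' @param n_markers number of single-copy marker families.
#' @param cas_module_index which module carries the POSITIVE labels.
#' @param labeled_fraction fraction of cas-module members labeled POSITIVE
#'   (the rest stay UNANNOTATED, emulating unannotated true cas families).
#' @param depth_sd log-scale standard deviation of the per-sample depth
#'   factor multiplying every family (the nuisance marker normalization is
#'   designed to remove); default 0.5.
#' @param marker_noise_sd log-scale noise of marker families; default 0.1.
#'   Single-copy markers have essentially constant copy number per genome,
#'   so their abundance varies with sequencing depth, not biology -- which
#'   is exactly what makes their median a depth estimator.
#' @param seed integer seed.
#' @return a list of class `synthetic_network_config`.
#' @export
synthetic_network_config <- function(p = 60L, n = 300L,
                                     module_sizes = c(10L, 10L),
                                     within_module_partial_corr = 0.4,
                                     zero_inflation = 0,
                                     n_markers = 10L,
                                     cas_module_index = 1L,
                                     labeled_fraction = 0.5,
                                     depth_sd = 0.5,
                                     marker_noise_sd = 0.1,
                                     seed = 1L) {
  r <- within_module_partial_corr
  stopifnot(p >= sum(module_sizes) + n_markers, n >= 3L,
            r >= 0, zero_inflation >= 0, zero_inflation < 1,
            n_markers >= 1L, length(module_sizes) >= 1L,
            cas_module_index >= 1L, cas_module_index <= length(module_sizes),
            labeled_fraction >= 0, labeled_fraction <= 1,
            depth_sd >= 0, marker_noise_sd > 0)
  if (r >= 0.5) {
    stop_casnet("within_module_partial_corr must be < 0.5 for a diagonally ",
                "dominant chain-module precision matrix")
  }
  structure(list(p = as.integer(p), n = as.integer(n),
                 module_sizes = as.integer(module_sizes),
                 within_module_partial_corr = r,
                 zero_inflation = zero_inflation,
                 n_markers = as.integer(n_markers),
                 cas_module_index = as.integer(cas_module_index),
                 labeled_fraction = labeled_fraction,
                 depth_sd = depth_sd, marker_noise_sd = marker_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_network_config")
}

#' Family-id layout of a synthetic configuration
#'
#' @param cfg a [synthetic_network_config()].
#' @return list with `modules` (module member ids, in module order),
#'   `markers`, `background` and `all` (the full row order of the generated
#'   matrix).
#' @export
synthetic_family_ids <- function(cfg) {
  mod <- unlist(lapply(seq_along(cfg$module_sizes), function(k) {
    sprintf("MOD%d_%03d", k, seq_len(cfg$module_sizes[k]))
  }))
  mrk <- sprintf("MARKER%02d", seq_len(cfg$n_markers))
  nbg <- cfg$p - length(mod) - cfg$n_markers
  bg <- if (nbg > 0L) sprintf("BG%04d", seq_len(nbg)) else character(0L)
  list(modules = mod, markers = mrk, background = bg,
       all = c(mod, mrk, bg))
}

#' Build the planted sparse precision matrix and its ground truth
#'
#' Unit diagonal; each planted module is a chain whose edges carry
#' off-diagonal entries `-r`, giving pairwise partial correlation exactly
#' `r` on every edge; markers and background families are singletons.
#' Positive definiteness is verified by eigen-decomposition.
#'
#' @param cfg a [synthetic_network_config()].
#' @return list with `omega` (p x p precision matrix with family dimnames)
#'   and `truth`, itself a list with `edges` (two-column character matrix of
#'   unordered planted pairs) and `true_cas` (ids of the cas module).
#' @export
make_precision <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_network_config"))
  ids <- synthetic_family_ids(cfg)
  p <- cfg$p
  omega <- diag(p)
  dimnames(omega) <- list(ids$all, ids$all)
  r <- cfg$within_module_partial_corr
  edges <- matrix(character(0L), ncol = 2L)
  offset <- 0L
  for (m in cfg$module_sizes) {
    if (m >= 2L && r > 0) {
      i <- offset + seq_len(m - 1L)
      for (k in i) {
        omega[k, k + 1L] <- omega[k + 1L, k] <- -r
      }
      edges <- rbind(edges, cbind(ids$all[i], ids$all[i + 1L]))
    }
    offset <- offset + m
  }
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop_casnet("planted precision matrix is not positive definite")
  cas_ids <- ids$modules[grepl(sprintf("^MOD%d_", cfg$cas_module_index),
                               ids$modules)]
  list(omega = omega,
       truth = list(edges = edges, true_cas = cas_ids))
}

#' Sample a synthetic abundance matrix from the planted model
#'
#' Draws `n` latent vectors from the zero-mean Gaussian with covariance
#' `solve(omega)` and maps family f in sample s to
#' `depth_s * scale_f * exp(sd_f * z_fs)`: a per-sample sequencing-depth
#' factor (log-sd `depth_sd`) multiplying every family, a log-normal
#' per-family scale emulating abundance heterogeneity (scale 1 for
#' markers), and the strictly monotone exponential link. Marker families
#' use `sd_f = marker_noise_sd` (single-copy markers are nearly constant
#' per genome), so the per-sample marker median is approximately `depth_s`
#' and marker normalization recovers copy numbers with median ~1. Finally,
#' each non-marker cell is zeroed independently with probability
#' `zero_inflation`. Deterministic given `cfg$seed`.
#'
#' @param omega positive-definite precision matrix with family dimnames
#'   (from [make_precision()]).
#' @param cfg the matching [synthetic_network_config()].
#' @return an [abundance_matrix()] (families x samples).
#' @export
sample_abundances <- function(omega, cfg) {
  stopifnot(inherits(cfg, "synthetic_network_config"),
            nrow(omega) == cfg$p)
  ids <- synthetic_family_ids(cfg)
  sigma <- solve(omega)
  ch <- chol(sigma)
  with_seed(cfg$seed, {
    z <- matrix(stats::rnorm(cfg$n * cfg$p), nrow = cfg$n) %*% ch  # n x p
    z <- t(z)                                                      # p x n
    scale <- stats::rlnorm(cfg$p, meanlog = 0, sdlog = 0.5)
    is_marker <- ids$all %in% ids$markers
    scale[is_marker] <- 1
    sd_f <- ifelse(is_marker, cfg$marker_noise_sd, 1)
    depth <- stats::rlnorm(cfg$n, meanlog = 0, sdlog = cfg$depth_sd)
    vals <- sweep(scale * exp(sd_f * z), 2L, depth, `*`)
    if (cfg$zero_inflation > 0) {
      drop <- matrix(stats::runif(cfg$p * cfg$n) < cfg$zero_inflation,
                     nrow = cfg$p)
      drop[is_marker, ] <- FALSE
      vals[drop] <- 0
    }
    abundance_matrix(vals, family_ids = ids$all,
                     sample_ids = sprintf("S%03d", seq_len(cfg$n)))
  })
}

#' Labels implied by a synthetic config
#'
#' The first `labeled_fraction` of the cas module (deterministic prefix, so
#' label sets are stable across seeds of downstream stages) are POSITIVE;
#' background families are NEGATIVE (annotated non-cas); the remaining cas
#' module members, the other modules and the markers are left as stated.
#'
#' @param cfg a [synthetic_network_config()].
#' @param truth the ground truth from [make_precision()].
#' @return a [label_vector()] over all families.
#' @export
synthetic_labels <- function(cfg, truth) {
  ids <- synthetic_family_ids(cfg)
  lab <- stats::setNames(rep("UNANNOTATED", cfg$p), ids$all)
  lab[ids$background] <- "NEGATIVE"
  lab[ids$markers] <- "NEGATIVE"
  n_pos <- ceiling(cfg$labeled_fraction * length(truth$true_cas))
  lab[truth$true_cas[seq_len(n_pos)]] <- "POSITIVE"
  label_vector(lab)
}

#' Planted-community graph for label-propagation benchmarks
#'
#' Generates an unweighted graph with one densely connected positive module
#' embedded in a sparse background (a two-block stochastic block model), plus
#' the labels a metagenome annotation would provide: all module members are
#' true cas, a fraction of non-module nodes are annotated NEGATIVE, the rest
#' UNANNOTATED. Used by the propagation recovery benchmarks, where ground
#' truth on nodes (not edges) is needed.
#'
#' @param n_nodes total nodes; default 500.
#' @param module_size positive-module size; default 25.
#' @param p_within edge probability inside the module; default 0.5.
#' @param p_background edge probability elsewhere; default 0.012
#'   (mean background degree about 6).
#' @param annotated_frac fraction of non-module nodes with a (NEGATIVE)
#'   annotation; default 0.34, matching the roughly one-third annotation
#'   rate of large functional-profile networks.
#' @param held_out_fraction fraction of the module left UNANNOTATED (truth
#'   known, label hidden); default 0 (all module members labeled POSITIVE).
#' @param seed integer seed.
#' @return list with `graph` (igraph), `labels` ([label_vector()]) and
#'   `true_cas` (character vector of module node names).
#' @export
simulate_label_graph <- function(n_nodes = 500L, module_size = 25L,
                                 p_within = 0.5, p_background = 0.012,
                                 annotated_frac = 0.34,
                                 held_out_fraction = 0, seed = 1L) {
  stopifnot(module_size < n_nodes, p_within >= 0, p_within <= 1,
            p_background >= 0, p_background <= 1)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  mod <- nodes[seq_len(module_size)]
  with_seed(seed, {
    pairs <- utils::combn(n_nodes, 2L)
    in_mod <- pairs[1L, ] <= module_size & pairs[2L, ] <= module_size
    prob <- ifelse(in_mod, p_within, p_background)
    keep <- stats::runif(ncol(pairs)) < prob
    g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    igraph::V(g)$name <- nodes
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(rbind(nodes[pairs[1L, keep]],
                                                nodes[pairs[2L, keep]])))
    }
    lab <- stats::setNames(rep("UNANNOTATED", n_nodes), nodes)
    lab[mod] <- "POSITIVE"
    n_hidden <- floor(held_out_fraction * module_size)
    if (n_hidden > 0L) {
      lab[sample(mod, n_hidden)] <- "UNANNOTATED"
    }
    bg <- setdiff(nodes, mod)
    n_ann <- round(annotated_frac * length(bg))
    lab[sample(bg, n_ann)] <- "NEGATIVE"
    list(graph = g, labels = label_vector(lab), true_cas = mod)
  })
}

#' Configuration for the synthetic genome generator
#'
#' @param n_genomes number of genomes; default 25 (a desk-scale stand-in for
#'   a metagenome-assembled-genome collection).
#' @param contigs_per_genome contigs per genome; default 5.
#' @param genes_per_contig genes per contig; default 20.
#' @param mean_gene_len mean gene length in bp; default 900 (typical
#'   prokaryotic gene).
#' @param mean_intergenic_len mean intergenic gap in bp; default 120.
#' @param colocated_families ids of families planted adjacent to cas operons
#'   with probability `pi_coloc`.
#' @param background_families ids of filler families placed uniformly.
#' @param pi_coloc probability a colocated-family instance lands within two
#'   genes of the cas operon; default 1.
#' @param seed integer seed.
#' @return a list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_genomes = 25L, contigs_per_genome = 5L,
                                    genes_per_contig = 20L,
                                    mean_gene_len = 900,
                                    mean_intergenic_len = 120,
                                    colocated_families = "FAMCOLOC",
                                    background_families = sprintf("FAMBG%02d", 1:10),
                                    pi_coloc = 1, seed = 1L) {
  stopifnot(n_genomes >= 1L, contigs_per_genome >= 1L, genes_per_contig >= 2L,
            mean_gene_len > 0, mean_intergenic_len > 0,
            pi_coloc >= 0, pi_coloc <= 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 contigs_per_genome = as.integer(contigs_per_genome),
                 genes_per_contig = as.integer(genes_per_contig),
                 mean_gene_len = mean_gene_len,
                 mean_intergenic_len = mean_intergenic_len,
                 colocated_families = as.character(colocated_families),
                 background_families = as.character(background_families),
                 pi_coloc = pi_coloc, seed = as.integer(seed)),
            class = "synthetic_genome_config")
}

#' Simulate genomes with a planted cas operon and cas-adjacent families
#'
#' Each genome consists of contigs of sequentially placed, non-overlapping
#' genes (1-based inclusive coordinates, GFF3 convention; gene lengths
#' uniform within +/-50% of the mean, intergenic gaps likewise). One contig
#' per genome carries a cas operon: a run of 3-8 consecutive genes flagged
#' `is_cas`. Each colocated family is placed, once per genome, within two
#' gene slots of the operon with probability `pi_coloc` and uniformly among
#' non-cas slots otherwise; remaining slots are filled with background
#' families.
#'
#' @param cfg a [synthetic_genome_config()].
#' @return a `gene_table` data.frame with columns genome_id, contig_id,
#'   start, end, strand, family_id, is_cas.
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_genome_config"))
  with_seed(cfg$seed, {
    out <- vector("list", cfg$n_genomes)
    for (g in seq_len(cfg$n_genomes)) {
      genome <- sprintf("G%03d", g)
      rows <- vector("list", cfg$contigs_per_genome)
      for (ct in seq_len(cfg$contigs_per_genome)) {
        ng <- cfg$genes_per_contig
        glen <- round(stats::runif(ng, 0.5, 1.5) * cfg$mean_gene_len)
        gap <- round(stats::runif(ng, 0.5, 1.5) * cfg$mean_intergenic_len)
        start <- cumsum(c(1, glen[-ng] + gap[-ng]))
        rows[[ct]] <- data.frame(
          genome_id = genome,
          contig_id = sprintf("%s_C%02d", genome, ct),
          start = as.integer(start),
          end = as.integer(start + glen - 1L),
          strand = sample(c("+", "-"), ng, replace = TRUE),
          family_id = NA_character_,
          is_cas = FALSE,
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      # plant the cas operon: a run of 3-8 genes on one contig
      op_contig <- sample(unique(tab$contig_id), 1L)
      slots <- which(tab$contig_id == op_contig)
      op_len <- min(sample(3:8, 1L), length(slots))
      op_from <- sample(seq_len(length(slots) - op_len + 1L), 1L)
      op_idx <- slots[op_from:(op_from + op_len - 1L)]
      tab$is_cas[op_idx] <- TRUE
      tab$family_id[op_idx] <- sprintf("CAS%02d", seq_len(op_len))
      # colocated families: within two gene slots of the operon w.p. pi_coloc
      near <- setdiff(slots[pmax(1L, op_from - 2L):
                            pmin(length(slots), op_from + op_len + 1L)], op_idx)
      for (fam in cfg$colocated_families) {
        free <- which(is.na(tab$family_id))
        near_free <- intersect(near, free)
        idx <- if (stats::runif(1) < cfg$pi_coloc && length(near_free) > 0L) {
          if (length(near_free) == 1L) near_free else sample(near_free, 1L)
        } else {
          if (length(free) == 1L) free else sample(free, 1L)
        }
        tab$family_id[idx] <- fam
      }
      free <- which(is.na(tab$family_id))
      tab$family_id[free] <- sample(cfg$background_families, length(free),
                                    replace = TRUE)
      out[[g]] <- tab
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    class(tab) <- c("gene_table", class(tab))
    tab
  })
}

#' Write a gene table as flat TSV
#'
#' @param table a `gene_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a flat-TSV gene table
#'
#' @param path TSV with columns genome_id, contig_id, start, end, strand,
#'   family_id, is_cas.
#' @return a `gene_table` data.frame.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("genome_id", "contig_id", "start", "end", "strand",
            "family_id", "is_cas")
  if (!all(need %in% names(tab))) {
    stop_casnet("gene table missing column(s): ",
                paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab$is_cas <- as.logical(tab$is_cas)
  if (any(tab$start > tab$end)) stop_casnet("gene with start > end")
  class(tab) <- c("gene_table", class(tab))
  tab
}

#' Write a gene table as GFF3
#'
#' Coordinates are emitted as-is (already 1-based inclusive); family and cas
#' status travel in the attributes column as `family=...;is_cas=...`.
#'
#' @param table a `gene_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table_gff3 <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tcasnet\tgene\t%d\t%d\t.\t%s\t.\tID=gene%06d;genome=%s;family=%s;is_cas=%s",
                   table$contig_id, table$start, table$end, table$strand,
                   seq_len(nrow(table)), table$genome_id, table$family_id,
                   ifelse(table$is_cas, "true", "false"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 gene table written by [write_gene_table_gff3()]
#'
#' @param path GFF3 path; attributes must carry `genome=`, `family=` and
#'   `is_cas=` tags.
#' @return a `gene_table` data.frame.
#' @export
read_gene_table_gff3 <- function(path) {
  ln <- readLines(path, encoding = "UTF-8")
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0L) stop_casnet("no feature rows in ", path)
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop_casnet("malformed GFF3 row in ", path)
  f <- do.call(rbind, f)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    sub(paste0("^;?", key, "="), "", m)
  }
  tab <- data.frame(
    genome_id = attr_get(f[, 9L], "genome"),
    contig_id = f[, 1L],
    start = as.integer(f[, 4L]),
    end = as.integer(f[, 5L]),
    strand = f[, 7L],
    family_id = attr_get(f[, 9L], "family"),
    is_cas = attr_get(f[, 9L], "is_cas") == "true",
    stringsAsFactors = FALSE)
  class(tab) <- c("gene_table", class(tab))
  tab
}
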