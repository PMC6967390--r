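
# colocation_tests: hmmer hit-table filtering, same-contig cooccurrence with
# an ORF-reassignment permutation null, minimum-bp-distance to cas with a
# random-location null, and the transmembrane flag.

#' Read an hmmscan/hmmsearch `--tblout`-style hit table
#'
#' Whitespace-delimited, `#`-comment rows skipped; the first four columns
#' are target name, target accession, query name, query accession, and the
#' fifth is the full-sequence E-value.
#'
#' @param path path to the tabular output.
#' @return data.frame (target, query, evalue).
#' @export
read_hmmer_tbl <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  if (length(ln) == 0L) {
    return(data.frame(target = character(0L), query = character(0L),
                      evalue = numeric(0L)))
  }
  f <- strsplit(trimws(ln), "[[:space:]]+")
  if (any(lengths(f) < 5L)) stop_casnet("malformed hit row in ", path)
  data.frame(target = vapply(f, `[`, "", 1L),
             query = vapply(f, `[`, "", 3L),
             evalue = as.numeric(vapply(f, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Filter homology hits at a genome-count-corrected E-value cutoff
#'
#' Retains hits with E-value strictly below `base_cutoff / n_targets`
#' (the per-genome correction used when the same profile set is searched
#' against many genomes), then keeps a single family call per gene: the hit
#' with the smallest E-value.
#'
#' @param hits data.frame with at least columns `target` (gene), `query`
#'   (family) and `evalue`.
#' @param n_targets number of genomes searched (cutoff divisor).
#' @param base_cutoff base E-value cutoff; default 0.01.
#' @return the filtered data.frame, one row per gene.
#' @export
filter_hits <- function(hits, n_targets, base_cutoff = 0.01) {
  if (!"evalue" %in% names(hits)) stop_casnet("missing E-value column")
  stopifnot(n_targets >= 1L, base_cutoff > 0)
  keep <- hits[hits$evalue < base_cutoff / n_targets, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  keep <- keep[order(keep$evalue), , drop = FALSE]
  keep <- keep[!duplicated(keep$target), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Mean same-contig cooccurrence of a family with cas genes
#'
#' For each genome containing the family, the fraction of that family's
#' instances sharing a contig with at least one cas gene; the observed
#' statistic is the mean of those per-genome fractions (for single-copy
#' families this is the fraction of genomes with same-contig cooccurrence).
#'
#' @param table a `gene_table` data.frame (possibly many genomes).
#' @param family family id; must occur in at least one genome.
#' @return list: `observed`, `per_genome` (named vector), `n_genomes`.
#' @export
contig_cooccurrence <- function(table, family) {
  inst <- table[table$family_id == family & !table$is_cas, , drop = FALSE]
  if (nrow(inst) == 0L) stop_casnet("family not found in any genome: ", family)
  cas_contigs <- unique(table$contig_id[table$is_cas])
  per <- tapply(inst$contig_id %in% cas_contigs, inst$genome_id, mean)
  per <- stats::setNames(as.numeric(per), names(per))
  list(observed = mean(per), per_genome = per, n_genomes = length(per))
}

#' ORF-reassignment permutation test for same-contig cooccurrence
#'
#' Each permutation independently relocates every instance of the family to
#' the location of another uniformly chosen non-cas ORF within its own
#' genome (cas genes never move, and their locations are not valid targets:
#' a family instance cannot occupy a slot held by a cas gene, and allowing
#' such targets would hand the null free same-contig cooccurrences and make
#' the test anti-conservative under the null) and recomputes the
#' cooccurrence statistic; the p-value is
#' `(1 + #[null >= observed]) / (1 + n_perm)` (add-one rule, never zero).
#' Genomes with fewer than two eligible ORFs are excluded with a warning.
#' With 1e4 permutations a family exceeding every null draw reports the
#' add-one value 1/(1e4+1), printed as "< 1e-04".
#'
#' @param table a `gene_table` data.frame.
#' @param family family id under test.
#' @param n_perm number of permutations; default 10000.
#' @param seed integer seed.
#' @return list of class `perm_test`: `family`, `observed`, `null`
#'   (numeric vector of length `n_perm`), `p_value`, `p_label`, `n_perm`.
#' @export
orf_reassignment_test <- function(table, family, n_perm = 10000L, seed = 1L) {
  obs <- contig_cooccurrence(table, family)
  genomes <- names(obs$per_genome)
  cas_contigs <- unique(table$contig_id[table$is_cas])
  per_genome_null <- vector("list", length(genomes))
  ok <- logical(length(genomes))
  with_seed(seed, {
    for (gi in seq_along(genomes)) {
      gtab <- table[table$genome_id == genomes[gi], , drop = FALSE]
      eligible <- which(!gtab$is_cas)  # valid slots for a non-cas family
      inst_rows <- match(which(gtab$family_id == family & !gtab$is_cas),
                         eligible)
      m <- length(eligible)
      if (m < 2L) {
        warning("genome ", genomes[gi],
                " has fewer than 2 eligible ORFs; excluded")
        next
      }
      on_cas <- gtab$contig_id[eligible] %in% cas_contigs
      # each instance picks one of the other m-1 eligible ORFs, every perm
      draws <- matrix(0L, nrow = length(inst_rows), ncol = n_perm)
      for (ii in seq_along(inst_rows)) {
        d <- sample.int(m - 1L, n_perm, replace = TRUE)
        d <- d + (d >= inst_rows[ii])  # skip the instance's own slot
        draws[ii, ] <- d
      }
      hit <- matrix(on_cas[draws], nrow = length(inst_rows))
      per_genome_null[[gi]] <- colMeans(hit)
      ok[gi] <- TRUE
    }
  })
  if (!any(ok)) stop_casnet("no genome with >= 2 ORFs contains the family")
  null_mat <- do.call(rbind, per_genome_null[ok])
  null <- colMeans(null_mat)
  observed <- mean(obs$per_genome[ok])
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  p_label <- if (sum(null >= observed) == 0L) {
    sprintf("< %.0e", 1 / n_perm)
  } else {
    format(p, digits = 4L)
  }
  structure(list(family = family, observed = observed, null = null,
                 p_value = p, p_label = p_label, n_perm = as.integer(n_perm)),
            class = "perm_test")
}

# Gap in bp between two 1-based inclusive intervals on the same contig:
# 0 if they overlap or abut, otherwise larger start - smaller end.
interval_gap <- function(s1, e1, s2, e2) {
  ifelse(s1 > e2, s1 - e2, ifelse(s2 > e1, s2 - e1, 0))
}

#' Minimum base-pair distance from a family to any cas gene
#'
#' Distance between two genes on the same contig is the inter-boundary gap
#' (`larger start - smaller end`, floored at 0 for overlapping or abutting
#' genes); gene pairs on different contigs are infinitely far apart. The
#' per-genome value is the minimum over all (family instance, cas gene)
#' pairs; the overall value is the minimum across genomes. Strand is
#' ignored and contigs are treated as linear.
#'
#' @param table a `gene_table` data.frame.
#' @param family family id.
#' @return list: `per_genome` (named numeric, `Inf` when no shared contig)
#'   and `overall`.
#' @export
min_distance_to_cas <- function(table, family) {
  inst <- table[table$family_id == family & !table$is_cas, , drop = FALSE]
  if (nrow(inst) == 0L) stop_casnet("family not found: ", family)
  cas <- table[table$is_cas, , drop = FALSE]
  genomes <- unique(inst$genome_id)
  per <- stats::setNames(rep(Inf, length(genomes)), genomes)
  for (g in genomes) {
    gi <- inst[inst$genome_id == g, , drop = FALSE]
    gc <- cas[cas$genome_id == g, , drop = FALSE]
    if (nrow(gc) == 0L) next
    for (r in seq_len(nrow(gi))) {
      same <- gc[gc$contig_id == gi$contig_id[r], , drop = FALSE]
      if (nrow(same) == 0L) next
      d <- interval_gap(gi$start[r], gi$end[r], same$start, same$end)
      per[g] <- min(per[g], d)
    }
  }
  list(per_genome = per, overall = min(per))
}

#' Random-location null distribution of distances to cas
#'
#' For every genome and every repetition, draws one uniformly random bp
#' position on the genome (contig chosen proportional to length, then a
#' uniform position within it) and records its distance to the nearest cas
#' gene on that contig (0 inside a cas gene, `Inf` if the contig carries
#' none). Each repetition yields one distance per genome -- the null
#' distribution of random gene locations with respect to cas.
#'
#' @param table a `gene_table` data.frame.
#' @param n_reps repetitions; default 100.
#' @param seed integer seed.
#' @return numeric matrix, `n_reps` x genomes.
#' @export
random_location_null <- function(table, n_reps = 100L, seed = 1L) {
  genomes <- unique(table$genome_id)
  contig_len <- tapply(table$end, table$contig_id, max)
  out <- matrix(NA_real_, nrow = n_reps, ncol = length(genomes),
                dimnames = list(NULL, genomes))
  with_seed(seed, {
    for (g in genomes) {
      contigs <- unique(table$contig_id[table$genome_id == g])
      lens <- contig_len[contigs]
      cas_g <- table[table$genome_id == g & table$is_cas, , drop = FALSE]
      ct <- sample(contigs, n_reps, replace = TRUE, prob = lens / sum(lens))
      pos <- floor(stats::runif(n_reps) * lens[ct]) + 1
      for (r in seq_len(n_reps)) {
        cg <- cas_g[cas_g$contig_id == ct[r], , drop = FALSE]
        out[r, g] <- if (nrow(cg) == 0L) {
          Inf
        } else {
          min(interval_gap(pos[r], pos[r], cg$start, cg$end))
        }
      }
    }
  })
  out
}

#' Transmembrane flag from predicted helix residue counts
#'
#' A protein counts as transmembrane when at least 18 of its amino acids
#' are predicted to lie in transmembrane helices.
#'
#' @param tm_aa_count non-negative count(s) of residues in predicted
#'   transmembrane helices.
#' @param min_aa threshold; default 18.
#' @return logical vector.
#' @export
tm_flag <- function(tm_aa_count, min_aa = 18L) {
  stopifnot(all(tm_aa_count >= 0))
  tm_aa_count >= min_aa
}
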