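# Hit filtering, contig cooccurrence, the two permutation nulls, distances.

test_that("filter_hits applies the corrected cutoff and the best-hit rule", {
  hits <- data.frame(target = c("g1", "g1", "g2", "g3"),
                     query = c("FAMA", "FAMB", "FAMA", "FAMC"),
                     evalue = c(1e-6, 1e-9, 0.004, 0.5))
  # 0.01 / 10 = 0.001: g2's 0.004 and g3's 0.5 are dropped
  out <- filter_hits(hits, n_targets = 10L)
  expect_setequal(out$target, "g1")
  # best E-value wins for the duplicated gene
  expect_equal(out$query[out$target == "g1"], "FAMB")
  # far below threshold always retained
  expect_true("g1" %in% filter_hits(hits, n_targets = 10000L)$target)
  expect_error(filter_hits(data.frame(target = "g", query = "q"), 10L),
               "E-value")
})

test_that("read_hmmer_tbl parses tblout-style output", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment line",
    "gene001   -   FAMA   -   1.2e-07   55.1   0.0",
    "gene002   -   FAMB   -   0.2      10.0   0.1"), path)
  tab <- read_hmmer_tbl(path)
  expect_equal(tab$target, c("gene001", "gene002"))
  expect_equal(tab$evalue, c(1.2e-07, 0.2))
})

test_that("contig_cooccurrence averages per-genome sharing", {
  mk <- function(genome, contig, fam, cas, start = 1L) {
    data.frame(genome_id = genome, contig_id = contig,
               start = start, end = start + 500L, strand = "+",
               family_id = fam, is_cas = cas, stringsAsFactors = FALSE)
  }
  tab <- rbind(mk("G1", "G1_C1", "FAMX", FALSE), mk("G1", "G1_C1", "CAS1", TRUE, 1000L),
               mk("G2", "G2_C1", "FAMX", FALSE), mk("G2", "G2_C2", "CAS1", TRUE))
  res <- contig_cooccurrence(tab, "FAMX")
  expect_equal(res$observed, 0.5)   # shares in G1, not in G2
  expect_equal(unname(res$per_genome[c("G1", "G2")]), c(1, 0))
  expect_error(contig_cooccurrence(tab, "NOPE"), "not found")

  # randomized placements vs independent recount
  tab2 <- random_gene_table(44)
  res2 <- contig_cooccurrence(tab2, "FAMX")
  cas_contigs <- unique(tab2$contig_id[tab2$is_cas])
  inst <- tab2[tab2$family_id == "FAMX" & !tab2$is_cas, ]
  oracle <- mean(tapply(inst$contig_id %in% cas_contigs, inst$genome_id, mean))
  expect_equal(res2$observed, oracle)
})

test_that("orf_reassignment_test is deterministic and detects planted colocation", {
  cfg <- synthetic_genome_config(n_genomes = 30L, pi_coloc = 1, seed = 5L)
  tab <- simulate_genomes(cfg)
  r1 <- orf_reassignment_test(tab, "FAMCOLOC", n_perm = 500L, seed = 9L)
  r2 <- orf_reassignment_test(tab, "FAMCOLOC", n_perm = 500L, seed = 9L)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$observed, 1)
  expect_equal(r1$p_value, 1 / 501)
  expect_true(all(r1$null >= 0 & r1$null <= 1))

  # relocation never touches cas genes: null statistic distribution depends
  # only on non-cas slots, so a genome whose non-cas genes all sit on the
  # cas contig yields null draws of exactly 1
  one <- data.frame(genome_id = "G1", contig_id = "G1_C1",
                    start = c(1L, 600L, 1200L), end = c(500L, 1100L, 1700L),
                    strand = "+", family_id = c("CAS1", "FAMX", "B1"),
                    is_cas = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  ro <- orf_reassignment_test(one, "FAMX", n_perm = 50L, seed = 1L)
  expect_true(all(ro$null == 1))
  expect_equal(ro$p_value, 1)
})

test_that("null p is near the add-one floor when cas occupies 1 of many contigs", {
  # family adjacent to cas on one contig; 99 other contigs of equal size
  rows <- list()
  for (ct in 1:100) {
    start <- seq(1L, by = 1000L, length.out = 5L)
    rows[[ct]] <- data.frame(
      genome_id = "G1", contig_id = sprintf("C%03d", ct),
      start = start, end = start + 800L, strand = "+",
      family_id = sprintf("B%d_%d", ct, 1:5), is_cas = FALSE,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$is_cas[1] <- TRUE
  tab$family_id[1] <- "CAS1"
  tab$family_id[2] <- "FAMX"   # same contig as the cas gene
  res <- orf_reassignment_test(tab, "FAMX", n_perm = 2000L, seed = 3L)
  # per-draw null hit probability is 3/498 ~ 0.006
  expect_equal(res$observed, 1)
  expect_lt(res$p_value, 0.02)
})

test_that("pi_coloc = 0 permutation p-values are uniform (calibration)", {
  seeds <- casnet:::derive_seeds(77L, 60L)
  pvals <- casnet:::calibration_pvalues(seeds, n_genomes = 150L,
                                        n_perm = 399L)
  expect_true(all(pvals > 0 & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("min_distance_to_cas uses the inter-boundary gap convention", {
  tab <- data.frame(
    genome_id = "G1", contig_id = c("C1", "C1", "C1", "C2"),
    start = c(100L, 501L, 350L, 10L), end = c(400L, 900L, 420L, 600L),
    strand = c("+", "-", "+", "+"),
    family_id = c("FAMX", "CAS1", "CAS2", "CAS3"),
    is_cas = c(FALSE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  res <- min_distance_to_cas(tab, "FAMX")
  # gap to CAS1 is 501-400 = 101, but CAS2 overlaps FAMX -> 0
  expect_equal(unname(res$per_genome["G1"]), 0)
  res2 <- min_distance_to_cas(tab[tab$family_id != "CAS2", ], "FAMX")
  expect_equal(unname(res2$per_genome["G1"]), 101)
  expect_equal(res2$overall, 101)

  # cross-contig only -> Inf
  res3 <- min_distance_to_cas(tab[!tab$contig_id %in% "C1" |
                                    tab$family_id == "FAMX", ], "FAMX")
  expect_equal(res3$overall, Inf)

  # exhaustive all-pairs oracle on random tables; strand never matters
  for (s in 1:100) {
    rt <- random_gene_table(s)
    got <- min_distance_to_cas(rt, "FAMX")
    want <- oracle_min_distance(rt, "FAMX")
    expect_equal(got$per_genome[sort(names(got$per_genome))],
                 want[sort(names(want))])
    rt2 <- rt
    rt2$strand <- "-"
    expect_equal(min_distance_to_cas(rt2, "FAMX")$overall, got$overall)
  }
})

test_that("random_location_null matches closed-form expectations", {
  # genome fully covered by one cas gene -> all distances 0
  cover <- data.frame(genome_id = "G1", contig_id = "C1", start = 1L,
                      end = 10000L, strand = "+", family_id = "CAS1",
                      is_cas = TRUE, stringsAsFactors = FALSE)
  expect_true(all(random_location_null(cover, n_reps = 20L, seed = 1L) == 0))

  # short cas gene at the center of a length-L contig: E|U - L/2| = L/4
  L <- 100000L
  center <- data.frame(genome_id = "G1", contig_id = "C1",
                       start = c(L / 2L, L - 10L), end = c(L / 2L + 1L, L),
                       strand = "+", family_id = c("CAS1", "B1"),
                       is_cas = c(TRUE, FALSE), stringsAsFactors = FALSE)
  null <- random_location_null(center, n_reps = 4000L, seed = 2L)
  expect_lt(abs(mean(null) - L / 4) / (L / 4), 0.06)

  # determinism
  expect_identical(random_location_null(center, n_reps = 50L, seed = 7L),
                   random_location_null(center, n_reps = 50L, seed = 7L))
})

test_that("tm_flag applies the 18-residue threshold inclusively", {
  expect_equal(tm_flag(c(18, 17, 0, 40)), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(tm_flag(-1))
})
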