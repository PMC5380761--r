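test_that("LRT statistics and p-values match hand-checked rows", {
  r1 <- lrt_pvalue(-47761.1425, -47755.93314)
  expect_equal(r1$stat, 10.41872, tolerance = 1e-6)
  expect_equal(r1$p, 0.0012474, tolerance = 1e-4)
  r2 <- lrt_pvalue(-80168.41936, -80165.39924)
  expect_equal(r2$p, 0.013983, tolerance = 1e-4)
  same <- lrt_pvalue(-100, -100)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  # optimizer noise: lnL1 slightly below lnL0 clamps to 0
  clamped <- lrt_pvalue(-100, -100.01)
  expect_equal(clamped$stat, 0)
  expect_equal(clamped$p, 1)
  expect_error(lrt_pvalue(NaN, -1), "finite")
})

test_that("p-values decrease strictly with the statistic", {
  stats <- seq(0.5, 30, by = 0.5)
  ps <- lrt_pvalue(-1000, -1000 + stats / 2)$p
  expect_true(all(diff(ps) < 0))
})

test_that("Bonferroni two-tier coding matches the printed scheme", {
  sch <- mt_scheme(24)
  expect_equal(sch$thresholds, c(0.05, 0.01) / 24)
  expect_equal(significance_code(0.0012474, sch), "*")
  expect_equal(significance_code(0.2960935, sch), "ns")
  expect_equal(significance_code(3.21923e-09, sch), "**")
  # boundaries: thresholds themselves are not significant at their own tier
  expect_equal(significance_code(0.01 / 24, sch), "*")
  expect_equal(significance_code(0.05 / 24, sch), "ns")
  expect_error(significance_code(1.2, sch), "\\[0, 1\\]")
  expect_error(mt_scheme(0), "n_tests")
})

test_that("BEB filtering is strictly greater than the threshold", {
  sites <- data.frame(position = 0:3,
                      posterior = c(0.95, 0.96, 0.40, 0.99))
  kept <- filter_beb_sites(sites)
  expect_equal(kept$position, c(1, 3))
  expect_equal(nrow(filter_beb_sites(sites[0, ])), 0)
})

test_that("sites map to unique domains with conserved totals", {
  p <- simulate_protein(architecture_spec(10, islands = list(c(5, 60))),
                        seed = 8)
  a <- p$arch
  in_lrr <- a$hits$start[2] + 3
  in_island <- a$islands$start[1] + 10
  in_tm <- a$tm[1] + 5
  in_kd <- a$kd[1] + 12
  res <- map_sites_to_domains(c(in_lrr, in_island, in_tm, in_kd, 2L), a)
  expect_equal(res$total, 5)
  expect_equal(sum(res$domains), 5)
  expect_equal(unname(res$domains["LRR"]), 1)
  expect_equal(unname(res$domains["island"]), 1)
  expect_equal(unname(res$domains["TM"]), 1)
  expect_equal(unname(res$domains["KD"]), 1)
  # TM sites count in neither ECD nor ICD
  expect_equal(res$ecd + res$icd, 4)
  expect_equal(res$tm, 1)
  expect_equal(map_sites_to_domains(integer(0), a)$total, 0)
  expect_true(all(map_sites_to_domains(integer(0), a)$domains == 0))
  expect_error(map_sites_to_domains(a$seq_length + 5L, a), "outside")
})

test_that("LRR phase classification separates canonical positions", {
  spec <- lrr_motif_spec()
  hits <- data.frame(start = c(100), end = c(124), score = 11)
  at_start <- lrr_phase_classify(100L, hits, spec)
  expect_equal(at_start$phase, 0)
  expect_true(at_start$canonical)   # position 0 is the template L
  at_1 <- lrr_phase_classify(101L, hits, spec)
  expect_false(at_1$canonical)      # position 1 is an x
  expect_error(lrr_phase_classify(50L, hits, spec), "outside")
  # uniform sites over the motif: canonical fraction near 11/24
  set.seed(9)
  pos <- sample(100:123, 3000, replace = TRUE)
  frac <- mean(vapply(pos, function(p)
    lrr_phase_classify(p, hits, spec)$canonical, TRUE))
  expect_lt(abs(frac - 11 / 24), 0.03)
})

test_that("domain density chi-square matches hand computations", {
  even <- domain_density_test(c(10, 10), c(100, 100))
  expect_equal(even$stat, 0)
  expect_equal(even$p, 1)
  skew <- domain_density_test(c(20, 0), c(100, 100))
  expect_equal(skew$stat, 20)
  expect_equal(skew$p, 7.74e-6, tolerance = 1e-3)
  expect_equal(skew$df, 1)
  expect_error(domain_density_test(c(1, 2), c(0, 10)), "zero-length")
  expect_error(domain_density_test(c(1), c(10)), "2 domains")
})

test_that("branch-test simulation honours its ground truth", {
  tr <- branch_test_truth("b", has_selection = TRUE, ncp = 25,
                          true_sites = c(3, 77), aln_length = 200)
  b1 <- simulate_branch_test(tr, seed = 5)
  b2 <- simulate_branch_test(tr, seed = 5)
  expect_identical(b1$lnl0, b2$lnl0)
  expect_identical(b1$lnl1, b2$lnl1)
  expect_equal(b1$np1, b1$np0 + 1)
  kept <- filter_beb_sites(b1$sites)
  expect_equal(kept$position, c(3, 77))
  null <- simulate_branch_test(branch_test_truth("n"), seed = 2)
  expect_equal(nrow(filter_beb_sites(null$sites)), 0)
  expect_error(branch_test_truth("x", FALSE, true_sites = 1), "empty")
})

test_that("null p-values are uniform (KS test at n = 5000)", {
  ps <- vapply(1:5000, function(s) {
    b <- simulate_branch_test(branch_test_truth("null"), seed = s)
    lrt_pvalue(b$lnl0, b$lnl1)$p
  }, 1)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the packaged branch table reproduces its printed summaries", {
  df <- process_branch_tests(load_branch_tests())
  expect_equal(nrow(df), 24)
  s <- summarize_selection(df)
  expect_equal(s$total_sites, 141)
  expect_equal(unname(s$pair_class_counts),
               c(2, 2, 8))
  # the two no-signal pairs are the BIR and the FLS2-like pairs
  no_sig <- names(s$pair_classes)[s$pair_classes == "no_signal"]
  expect_setequal(df$sg[df$pair %in% no_sig], c("SG_Xa", "SG_XIIa"))
  s0 <- summarize_selection(df[0, ])
  expect_equal(s0$total_sites, 0)
})

test_that("fixture bundles round-trip through standard formats", {
  dir <- withr::local_tempdir()
  p <- simulate_protein(architecture_spec(5), seed = 1)
  st <- lrr_species_tree()
  fam <- simulate_gene_family(st, sim_config(0, 0, seed = 2))
  bt <- simulate_branch_test(branch_test_truth("b1"), seed = 3)
  paths <- write_fixture_bundle(dir, proteins = list(p1 = p),
                                trees = list(assign_supports(fam)),
                                branch_tests = list(bt))
  expect_true(all(file.exists(paths)))
  fa <- seqinr::read.fasta(file.path(dir, "proteins.fasta"),
                           seqtype = "AA", as.string = TRUE)
  expect_equal(toupper(as.character(fa[[1]])), p$sequence)
  t2 <- read.delim(file.path(dir, "table2_branch_tests.tsv"))
  expect_equal(nrow(t2), 24)
  t1 <- read.delim(file.path(dir, "table1_og_counts.tsv"))
  expect_equal(nrow(t1), 20)
  # empty bundle still writes valid files
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture_bundle(dir2)
  expect_true(all(file.exists(paths2)))
})
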