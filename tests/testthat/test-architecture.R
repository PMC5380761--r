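# the 24-residue template with its x positions made concrete ('Q' is never
# canonical and keeps the unit hydrophilic), for direct constructions
concrete_unit <- function() gsub("x", "Q", "LxxLxxLxLxxNxLSGxIPxxLxx")

test_that("scan_lrr finds implanted template copies and nothing else", {
  expect_equal(nrow(scan_lrr(strrep("A", 30))), 0)
  set.seed(1)
  flank <- function(n) paste(sample(c("D", "E", "K", "Q", "T"), n, TRUE),
                             collapse = "")
  seqs <- paste0(flank(10), strrep(concrete_unit(), 5), flank(10))
  hits <- scan_lrr(seqs)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$start, 10 + 24 * (0:4))
  expect_true(all(hits$score == 11))
})

test_that("canonical-mismatch scoring obeys the >= 9/11 threshold", {
  unit <- strsplit(concrete_unit(), "")[[1]]
  two_off <- unit; two_off[c(1, 4)] <- "E"   # positions 0 and 3 canonical
  three_off <- unit; three_off[c(1, 4, 7)] <- "E"
  expect_equal(nrow(scan_lrr(paste(two_off, collapse = ""))), 1)
  expect_equal(scan_lrr(paste(two_off, collapse = ""))$score, 9)
  expect_equal(nrow(scan_lrr(paste(three_off, collapse = ""))), 0)
})

test_that("scan_lrr rejects illegal residues naming the position", {
  expect_error(scan_lrr("AAAB1AAA"), "position 4")
})

test_that("scanner output is translation invariant", {
  set.seed(2)
  core <- paste0(strrep(concrete_unit(), 3))
  base <- scan_lrr(core)
  for (k in c(1, 7, 30)) {
    shifted <- scan_lrr(paste0(strrep("E", k), core))
    expect_equal(shifted$start, base$start + k)
  }
})

test_that("islands come from inter-LRR gaps at the 48-residue floor", {
  hits2 <- data.frame(start = c(0, 24), end = c(24, 48), score = 11)
  expect_equal(nrow(detect_islands(hits2)), 0)
  gap60 <- data.frame(start = c(0, 84), end = c(24, 108), score = 11)
  isl <- detect_islands(gap60)
  expect_equal(isl$length, 60)
  expect_equal(isl$lrr_equivalents, 2)
  gap47 <- data.frame(start = c(0, 71), end = c(24, 95), score = 11)
  expect_equal(nrow(detect_islands(gap47, min_gap = 48)), 0)
  gap48 <- data.frame(start = c(0, 72), end = c(24, 96), score = 11)
  expect_equal(detect_islands(gap48, min_gap = 48)$lrr_equivalents, 2)
  expect_error(detect_islands(data.frame(start = c(30, 0),
                                         end = c(54, 24), score = 11)),
               "sorted")
})

test_that("GDPC motifs are located exactly", {
  expect_equal(detect_gdpc("AAAGDPCAAA"), 3)
  expect_equal(detect_gdpc("AAAQAAA"), integer(0))
  expect_equal(detect_gdpc("GDPCGDPC"), c(0, 4))
  expect_equal(detect_gdpc("AAAGDPCAAA", region = c(4, 10)), integer(0))
})

test_that("Cys-pairs are detected in the right flanking regions", {
  unit <- concrete_unit()
  arch_of <- function(seq) domain_architecture(seq)
  base <- paste0(strrep("E", 10), unit, strrep("E", 10))
  a <- arch_of(base)
  expect_false(a$cys_n); expect_false(a$cys_c)
  with_n <- paste0(strrep("E", 5), "CAC", strrep("E", 2), unit,
                   strrep("E", 10))
  a2 <- arch_of(with_n)
  expect_true(a2$cys_n); expect_false(a2$cys_c)
  # two Cys farther apart than the window do not pair
  far <- paste0("C", strrep("E", 9), "C", unit, strrep("E", 10))
  expect_false(arch_of(far)$cys_n)
  expect_error(detect_cys_pairs("ACCA", list(hits = data.frame()), 1),
               "pair_window")
})

test_that("hydropathy segments split into SP and TM by position", {
  expect_equal(nrow(detect_hydrophobic_segments(strrep("Q", 100))$segments), 0)
  seqs <- paste0(strrep("Q", 5), strrep("L", 25), strrep("Q", 270),
                 strrep("L", 25), strrep("Q", 20))
  segs <- detect_hydrophobic_segments(seqs)
  expect_false(is.null(segs$sp)); expect_false(is.null(segs$tm))
  expect_lt(segs$sp[1], 40); expect_gt(segs$tm[1], 250)
  none <- detect_hydrophobic_segments(seqs, threshold = 5)
  expect_null(none$sp); expect_null(none$tm)
})

test_that("simulated architectures round-trip through the scanner", {
  set.seed(10)
  for (s in 1:25) {
    n <- sample(0:25, 1)
    isl <- if (n >= 10) list(c(sample(3:(n - 2), 1), 60)) else list()
    spec <- architecture_spec(n, cys_n = s %% 2 == 0, cys_c = n > 0 && s %% 3 == 0,
                              has_gdpc = s %% 4 == 0, islands = isl,
                              has_sp = s %% 5 != 0)
    p <- simulate_protein(spec, seed = s)
    a <- domain_architecture(p$sequence)
    expect_equal(a$n_lrr, n)
    expect_identical(a$hits$start, p$arch$hits$start)
    expect_equal(nrow(a$islands), length(isl))
    if (length(isl)) expect_equal(a$islands$length, 60)
    if (n > 0) {
      expect_equal(a$cys_n, spec$cys_n)
      expect_equal(a$cys_c, spec$cys_c)
    }
    expect_equal(a$has_sp, spec$has_sp)
    expect_true(a$has_tm); expect_true(a$has_kd)
    expect_length(a$gdpc, as.integer(spec$has_gdpc))
  }
})

test_that("LRR hits and islands tile without overlap", {
  p <- simulate_protein(architecture_spec(21, islands = list(c(13, 60))),
                        seed = 4)
  a <- domain_architecture(p$sequence)
  iv <- rbind(as.matrix(a$hits[, c("start", "end")]),
              as.matrix(a$islands[, c("start", "end")]))
  iv <- iv[order(iv[, 1]), ]
  expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
  expect_equal(sum(a$hits$end - a$hits$start), 24 * a$n_lrr)
})

test_that("architecture classification follows the decision list", {
  cls <- function(spec, seed = 1)
    classify_architecture(domain_architecture(simulate_protein(spec, seed)$sequence,
      has_mld = spec$has_mld,
      mld_placement = if (spec$has_mld) spec$mld_placement else NA))
  expect_equal(cls(architecture_spec(0)), "No_LRR")
  expect_equal(cls(architecture_spec(5, cys_n = TRUE, cys_c = TRUE)),
               "LRR_small_cys2")
  expect_equal(cls(architecture_spec(21, islands = list(c(13, 80)))),
               "LRR_island3plus")
  expect_equal(cls(architecture_spec(21, islands = list(c(13, 60)))),
               "LRR_island2")
  expect_equal(cls(architecture_spec(21)), "LRR_large")
  expect_equal(cls(architecture_spec(10)), "LRR_mid")
  expect_equal(cls(architecture_spec(12, has_mld = TRUE,
                                     mld_placement = "nterm")), "MLD_Nterm")
  expect_equal(cls(architecture_spec(12, has_mld = TRUE,
                                     mld_placement = "pretm")), "MLD_preTM")
})

test_that("LRR count histogram counts and finds modes", {
  h0 <- lrr_count_histogram(integer(0))
  expect_length(h0$modes, 0)
  h <- lrr_count_histogram(c(5, 5, 21))
  expect_equal(as.integer(h$counts[c("5", "21")]), c(2, 1))
  expect_equal(h$modes, 5)
  # cohort drawn with modes at 5 and 21 recovers them
  set.seed(3)
  cohort <- c(rep(5, 40), rep(21, 40), sample(c(8:15), 30, TRUE))
  hh <- lrr_count_histogram(cohort)
  expect_setequal(hh$modes, c(5, 21))
})
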