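#' Ground truth for a simulated branch-site test
#'
#' @param branch_id name of the foreground branch.
#' @param has_selection whether sites on the branch truly evolved under
#'   positive selection.
#' @param ncp noncentrality of the likelihood-ratio statistic under
#'   selection (0 under the null).
#' @param true_sites 0-based alignment positions of the truly selected
#'   sites; must be empty when `has_selection` is `FALSE`.
#' @param aln_length alignment length in codons.
#' @param np0 parameter count of the null model.
#' @param lnl0_base baseline null log-likelihood.
#' @return An object of class `branch_test_truth`.
#' @export
branch_test_truth <- function(branch_id, has_selection = FALSE, ncp = 0,
                              true_sites = integer(0), aln_length = 500,
                              np0 = 203, lnl0_base = -50000) {
  if (ncp < 0) stop_("ncp must be >= 0")
  if (!has_selection && length(true_sites))
    stop_("true_sites must be empty without selection")
  if (length(true_sites) && (any(true_sites < 0) ||
                             any(true_sites >= aln_length)))
    stop_("true sites must lie within the alignment")
  structure(list(branch_id = branch_id, has_selection = has_selection,
                 ncp = ncp, true_sites = as.integer(true_sites),
                 aln_length = as.integer(aln_length), np0 = as.integer(np0),
                 lnl0_base = lnl0_base),
            class = "branch_test_truth")
}

#' Simulate one branch-site test record
#'
#' Samples the likelihood-ratio statistic directly: central chi-square
#' (df = 1) without selection, noncentral chi-square (df = 1, the stated
#' ncp) with it; `lnL1 = lnL0 + stat / 2` and `np1 = np0 + 1`. Bayes
#' empirical Bayes posteriors are drawn above 0.95 at the true sites and
#' below 0.90 elsewhere.
#'
#' @param truth a [branch_test_truth()].
#' @param seed integer seed; the record is a pure function of
#'   `(truth, seed)`.
#' @return List with `branch_id`, `np0`, `np1`, `lnl0`, `lnl1`, and `sites`
#'   (data frame `position` (0-based), `posterior`).
#' @export
simulate_branch_test <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "branch_test_truth"))
  withr::with_seed(as.integer(seed), {
    lnl0 <- truth$lnl0_base + rnorm(1, 0, 5)
    ncp <- if (truth$has_selection) truth$ncp else 0
    stat <- rchisq(1, df = 1, ncp = ncp)
    post <- runif(truth$aln_length, 0, 0.90)
    post[truth$true_sites + 1L] <- runif(length(truth$true_sites), 0.96, 1)
    list(branch_id = truth$branch_id, np0 = truth$np0,
         np1 = truth$np0 + 1L, lnl0 = lnl0, lnl1 = lnl0 + stat / 2,
         sites = data.frame(position = seq_len(truth$aln_length) - 1L,
                            posterior = post))
  })
}

#' Write simulated objects as a plain-text fixture bundle
#'
#' Writes protein sequences as FASTA, gene trees as Newick (supports as
#' internal node labels), truth tables and branch-test records as TSV, and
#' copies of the packaged branch-test (24 rows) and per-SG OG count (20
#' rows) tables.
#'
#' @param dir output directory (created if needed).
#' @param proteins named list of [simulate_protein()] results.
#' @param trees named list of `phylo` objects.
#' @param branch_tests list of [simulate_branch_test()] results.
#' @return Invisibly, the vector of written paths.
#' @export
write_fixture_bundle <- function(dir, proteins = list(), trees = list(),
                                 branch_tests = list()) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_("cannot create directory %s", dir)
  written <- character(0)
  w <- function(p) { written <<- c(written, p); p }

  fa <- w(file.path(dir, "proteins.fasta"))
  seqinr::write.fasta(lapply(proteins, `[[`, "sequence"),
                      names = names(proteins) %||% character(0),
                      file.out = fa)
  nwk <- w(file.path(dir, "gene_trees.nwk"))
  if (length(trees)) ape::write.tree(trees[[1]], file = nwk,
                                     tree.names = FALSE)
  if (length(trees) > 1)
    for (t in trees[-1]) ape::write.tree(t, file = nwk, append = TRUE)
  if (!length(trees)) cat("", file = nwk)

  bt <- do.call(rbind, lapply(branch_tests, function(b)
    data.frame(branch = b$branch_id, np0 = b$np0, np1 = b$np1,
               lnl0 = b$lnl0, lnl1 = b$lnl1)))
  bt <- bt %||% data.frame(branch = character(), np0 = integer(),
                           np1 = integer(), lnl0 = numeric(),
                           lnl1 = numeric())
  write.table(bt, w(file.path(dir, "branch_tests.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)

  file.copy(lrr_extdata("table2_branch_tests.tsv"),
            w(file.path(dir, "table2_branch_tests.tsv")), overwrite = TRUE)
  file.copy(lrr_extdata("table1_og_counts.tsv"),
            w(file.path(dir, "table1_og_counts.tsv")), overwrite = TRUE)
  invisible(written)
}
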