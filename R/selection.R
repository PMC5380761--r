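#' Likelihood-ratio test from paired branch-site log-likelihoods
#'
#' The statistic is `max(0, 2 * (lnL1 - lnL0))` -- negative differences,
#' which optimizers occasionally produce, are clamped to zero -- and the
#' p-value is the upper tail of a chi-square with one degree of freedom
#' (p = 1 at statistic 0).
#'
#' @param lnl0,lnl1 log-likelihoods of the null model (A0) and the positive
#'   selection model (A); vectorized.
#' @return Data frame with columns `stat`, `p`.
#' @export
lrt_pvalue <- function(lnl0, lnl1) {
  if (any(!is.finite(lnl0)) || any(!is.finite(lnl1)))
    stop_("log-likelihoods must be finite")
  stat <- pmax(0, 2 * (lnl1 - lnl0))
  data.frame(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni multiple-testing scheme over tested branches
#'
#' Family-wise alpha levels divided by the number of tested branches. The
#' default reproduces the design with 24 foreground branches: thresholds
#' 0.05/24 and 0.01/24.
#'
#' @param n_tests number of branch tests (default 24).
#' @param alpha two family-wise levels, `c(single, double)` star.
#' @return An object of class `mt_scheme` with the derived per-test
#'   thresholds.
#' @export
mt_scheme <- function(n_tests = 24, alpha = c(0.05, 0.01)) {
  if (n_tests < 1) stop_("n_tests must be >= 1")
  if (length(alpha) != 2 || alpha[2] >= alpha[1])
    stop_("alpha must be two decreasing levels")
  structure(list(n_tests = n_tests, alpha = alpha,
                 thresholds = alpha / n_tests), class = "mt_scheme")
}

#' Significance code of a branch test
#'
#' `**` when `p < 0.01/n`, `*` when `0.01/n <= p < 0.05/n`, `ns` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param scheme an [mt_scheme()].
#' @return Character vector over `{"ns", "*", "**"}`.
#' @export
significance_code <- function(p, scheme = mt_scheme()) {
  if (any(p < 0 | p > 1 | is.na(p))) stop_("p must lie in [0, 1]")
  ifelse(p < scheme$thresholds[2], "**",
         ifelse(p < scheme$thresholds[1], "*", "ns"))
}

#' Filter Bayes empirical Bayes site posteriors
#'
#' Keeps sites whose posterior probability of omega > 1 is strictly above
#' the threshold (default 0.95: "strictly above 95%"; a posterior of exactly
#' 0.95 is excluded).
#'
#' @param sites data frame with a `posterior` column.
#' @param threshold posterior cutoff.
#' @return The retained rows.
#' @export
filter_beb_sites <- function(sites, threshold = 0.95) {
  if (nrow(sites) == 0) return(sites)
  if (any(sites$posterior < 0 | sites$posterior > 1))
    stop_("posteriors must lie in [0, 1]")
  sites[sites$posterior > threshold, , drop = FALSE]
}

#' Map selected sites onto protein domains
#'
#' Assigns each site (0-based residue position) to exactly one domain of an
#' annotated architecture by interval lookup: LRR hits, islands, SP, TM, KD,
#' MLD, with the remainder split into `other_ECD` (N-terminal of the TM
#' start) and `other_ICD` (C-terminal of the TM end). The ECD total counts
#' everything before the TM start, the ICD total everything after the TM
#' end; TM sites belong to neither, so ECD + ICD can undershoot the site
#' total.
#'
#' @param positions integer vector of 0-based site positions.
#' @param arch a `domain_architecture`.
#' @return List with `domains` (named counts), `ecd`, `icd`, `tm`, `total`.
#' @export
map_sites_to_domains <- function(positions, arch) {
  stopifnot(inherits(arch, "domain_architecture"))
  if (length(positions) && (any(positions < 0) ||
                            any(positions >= arch$seq_length)))
    stop_("site %d outside sequence of length %d",
          positions[which(positions < 0 | positions >= arch$seq_length)[1]],
          arch$seq_length)
  in_iv <- function(p, iv) !is.null(iv) && p >= iv[1] && p < iv[2]
  tm_start <- if (!is.null(arch$tm)) arch$tm[1] else arch$seq_length
  tm_end <- if (!is.null(arch$tm)) arch$tm[2] else arch$seq_length
  doms <- c("SP", "MLD", "LRR", "island", "TM", "KD", "other_ECD",
            "other_ICD")
  counts <- setNames(integer(length(doms)), doms)
  for (p in positions) {
    d <- if (any(p >= arch$hits$start & p < arch$hits$end)) "LRR"
    else if (nrow(arch$islands) &&
             any(p >= arch$islands$start & p < arch$islands$end)) "island"
    else if (in_iv(p, arch$sp)) "SP"
    else if (in_iv(p, arch$mld)) "MLD"
    else if (in_iv(p, arch$tm)) "TM"
    else if (in_iv(p, arch$kd)) "KD"
    else if (p < tm_start) "other_ECD"
    else "other_ICD"
    counts[d] <- counts[d] + 1L
  }
  list(domains = counts,
       ecd = sum(positions < tm_start),
       icd = sum(positions >= tm_end),
       tm = sum(positions >= tm_start & positions < tm_end),
       total = length(positions))
}

#' Phase and canonical status of a site within the LRR motif
#'
#' @param position 0-based residue position lying inside an LRR hit.
#' @param hits LRR hit table ([scan_lrr()] output).
#' @param spec an [lrr_motif_spec()].
#' @return List with `phase` (position within the 24-residue motif, 0-based)
#'   and `canonical` (whether it is one of the 11 canonical positions).
#' @export
lrr_phase_classify <- function(position, hits, spec = lrr_motif_spec()) {
  hit <- which(position >= hits$start & position < hits$end)
  if (!length(hit)) stop_("site %d lies outside every LRR hit", position)
  phase <- (position - hits$start[hit[1]]) %% spec$length
  list(phase = phase, canonical = phase %in% spec$canonical)
}

#' Chi-square test of site density across domains
#'
#' Goodness-of-fit of observed per-domain site counts against expectations
#' proportional to domain lengths (the size normalization used to compare
#' LRR and kinase domains).
#'
#' @param counts observed site counts per domain.
#' @param lengths domain lengths in codons, same order.
#' @return List with `stat`, `p`, `df`.
#' @export
domain_density_test <- function(counts, lengths) {
  if (length(counts) < 2 || length(counts) != length(lengths))
    stop_("need matching counts and lengths for >= 2 domains")
  if (any(lengths <= 0)) stop_("zero-length domain")
  ht <- suppressWarnings(chisq.test(counts, p = lengths / sum(lengths)))
  list(stat = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Load the packaged branch-test table
#'
#' The 24 foreground-branch records of the positive-selection scan: paired
#' null/alternative log-likelihoods, parameter counts, the printed p-values
#' and significance codes, and validated site counts with their ECD/ICD
#' split. Rows are grouped into the 12 OG pairs via the `pair` column.
#'
#' @return Data frame, one row per tested branch; `n_sites`, `ecd`, `icd`
#'   are integers with `NA` where no site was validated.
#' @export
load_branch_tests <- function() {
  df <- read.delim(lrr_extdata("table2_branch_tests.tsv"),
                   stringsAsFactors = FALSE,
                   colClasses = list(p_printed = "character"))
  for (col in c("n_sites", "ecd", "icd")) {
    df[[col]][df[[col]] == "-"] <- NA
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Recompute LRT statistics and significance codes for a branch table
#'
#' @param df branch table with `np0`, `np1`, `lnl0`, `lnl1` columns (see
#'   [load_branch_tests()]).
#' @param scheme an [mt_scheme()]; defaults to 0.05 and 0.01 over 24 tests.
#' @return The table with `stat`, `p` and `code` columns appended.
#' @export
process_branch_tests <- function(df, scheme = mt_scheme()) {
  if (any(df$np1 != df$np0 + 1))
    stop_("model A must have exactly one parameter more than A0")
  res <- lrt_pvalue(df$lnl0, df$lnl1)
  df$stat <- res$stat
  df$p <- res$p
  df$code <- significance_code(res$p, scheme)
  df
}

#' Totals and pair-level classification of branch tests
#'
#' @param df processed branch table (needs `pair`, `code`, `n_sites`).
#' @return List with `total_sites` (validated sites summed over branches,
#'   missing = 0), `branches_by_code`, `pair_classes` (per pair:
#'   `no_signal`, `one_branch` or `both_branches`), and `pair_class_counts`.
#' @export
summarize_selection <- function(df) {
  if (nrow(df) == 0)
    return(list(total_sites = 0L,
                branches_by_code = c(ns = 0L, `*` = 0L, `**` = 0L),
                pair_classes = character(0),
                pair_class_counts = c(no_signal = 0L, one_branch = 0L,
                                      both_branches = 0L)))
  by_code <- vapply(c("ns", "*", "**"), function(cd) sum(df$code == cd), 1L)
  pair_classes <- vapply(split(df$code, df$pair), function(codes) {
    n_sig <- sum(codes != "ns")
    if (n_sig == 0) "no_signal"
    else if (n_sig == length(codes)) "both_branches"
    else "one_branch"
  }, "")
  counts <- vapply(c("no_signal", "one_branch", "both_branches"),
                   function(cl) sum(pair_classes == cl), 1L)
  list(total_sites = sum(df$n_sites, na.rm = TRUE),
       branches_by_code = by_code,
       pair_classes = pair_classes,
       pair_class_counts = counts)
}
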