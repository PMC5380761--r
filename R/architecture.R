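#' Scan a protein for LRR motifs
#'
#' Slides the 24-position template of an [lrr_motif_spec()] along the
#' sequence and greedily selects non-overlapping windows, left to right,
#' whose canonical-match score reaches the acceptance threshold. `X`
#' residues score 0 at their position. Coordinates are 0-based, half-open.
#'
#' @param sequence protein string (20-letter alphabet, `X` tolerated).
#' @param spec an [lrr_motif_spec()].
#' @return Data frame with columns `start`, `end`, `score`, sorted by
#'   `start`; zero rows when nothing scores.
#' @export
scan_lrr <- function(sequence, spec = lrr_motif_spec()) {
  chars <- aa_residues(sequence)
  n <- length(chars)
  empty <- data.frame(start = integer(), end = integer(), score = integer())
  if (n < spec$length) return(empty)
  nwin <- n - spec$length + 1L
  score <- integer(nwin)
  for (c0 in spec$canonical) {
    score <- score + (chars[seq_len(nwin) + c0] == spec$template[c0 + 1L])
  }
  starts <- integer(0); scores <- integer(0)
  i <- 1L
  while (i <= nwin) {
    if (score[i] >= spec$threshold) {
      starts <- c(starts, i - 1L)
      scores <- c(scores, score[i])
      i <- i + spec$length
    } else i <- i + 1L
  }
  data.frame(start = starts, end = starts + spec$length, score = scores)
}

#' Island domains between LRR motifs
#'
#' An island is a non-LRR stretch lying strictly between two LRR hits whose
#' length reaches `min_gap` residues (default 48 = two LRR units). Its size
#' in LRR-equivalents is `floor(length / 24)`.
#'
#' @param hits LRR hit table from [scan_lrr()] (sorted, non-overlapping).
#' @param min_gap minimum inter-LRR gap, residues.
#' @return Data frame `start`, `end`, `length`, `lrr_equivalents`,
#'   `after_lrr` (1-based index of the flanking LRR on the N side).
#' @export
detect_islands <- function(hits, min_gap = 48) {
  if (nrow(hits) &&
      (is.unsorted(hits$start) || any(diff(hits$start) < 0) ||
       any(hits$end[-nrow(hits)] > hits$start[-1])))
    stop_("LRR hits must be sorted and non-overlapping")
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    lrr_equivalents = integer(), after_lrr = integer())
  if (nrow(hits) < 2) return(out)
  gap_start <- hits$end[-nrow(hits)]
  gap_end <- hits$start[-1]
  len <- gap_end - gap_start
  keep <- len >= min_gap
  data.frame(start = gap_start[keep], end = gap_end[keep],
             length = len[keep],
             lrr_equivalents = len[keep] %/% 24L,
             after_lrr = which(keep))
}

#' Find GDPC cleavage motifs
#'
#' Returns 0-based start positions of every literal `GDPC` substring within
#' the search region.
#'
#' @param sequence protein string.
#' @param region 0-based half-open `c(start, end)`; default whole sequence.
#' @return Integer vector of 0-based positions.
#' @export
detect_gdpc <- function(sequence, region = NULL) {
  chars <- aa_residues(sequence)
  region <- region %||% c(0L, length(chars))
  if (region[1] < 0 || region[2] > length(chars) || region[1] > region[2])
    stop_("region out of bounds")
  sub <- substr(sequence, region[1] + 1L, region[2])
  m <- gregexpr("GDPC", sub, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L + region[1]
}

#' Detect the two Cys-pairs flanking the LRR block
#'
#' The N-side pair sits between the signal-peptide end (or position 0) and
#' the first LRR; the C-side pair between the last LRR and the TM start (or
#' the sequence end). A pair is two Cys residues at most `pair_window`
#' positions apart.
#'
#' @param sequence protein string.
#' @param arch a partially filled `domain_architecture` (needs the LRR hit
#'   table and, if present, SP/TM intervals).
#' @param pair_window maximum Cys separation (default 8).
#' @return Logical vector `c(n_side, c_side)`; both `NA` when the
#'   architecture has no LRR to delimit the regions.
#' @export
detect_cys_pairs <- function(sequence, arch, pair_window = 8) {
  if (pair_window < 2) stop_("pair_window must be >= 2")
  chars <- aa_residues(sequence)
  if (nrow(arch$hits) == 0) return(c(n_side = NA, c_side = NA))
  has_pair <- function(from, to) {
    if (to <= from) return(FALSE)
    cys <- which(chars[(from + 1L):to] == "C")
    length(cys) >= 2 && any(diff(cys) <= pair_window)
  }
  n_from <- if (!is.null(arch$sp)) arch$sp[2] else 0L
  c_to <- if (!is.null(arch$tm)) arch$tm[1] else length(chars)
  c(n_side = has_pair(n_from, arch$hits$start[1]),
    c_side = has_pair(arch$hits$end[nrow(arch$hits)], c_to))
}

#' Hydrophobic segments: signal peptide and transmembrane candidates
#'
#' Slides a window over the Kyte--Doolittle hydropathy profile; windows with
#' mean hydropathy at or above `threshold` are merged into segments. A
#' segment starting within the first `sp_cutoff` residues is labeled SP; the
#' first later segment is the TM candidate.
#'
#' @param sequence protein string.
#' @param window window width in residues (default 19).
#' @param threshold mean hydropathy cutoff (default 1.6).
#' @param sp_cutoff latest 0-based start for a signal peptide (default 40).
#' @return List with `sp` and `tm` (each a 0-based half-open `c(start, end)`
#'   or `NULL`) and `segments`, a data frame of all merged segments.
#' @export
detect_hydrophobic_segments <- function(sequence, window = 19,
                                        threshold = 1.6, sp_cutoff = 40) {
  chars <- aa_residues(sequence)
  n <- length(chars)
  out <- list(sp = NULL, tm = NULL,
              segments = data.frame(start = integer(), end = integer()))
  if (n < window) return(out)
  h <- KD_HYDROPATHY[chars]
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 1))
  means <- means[window:n]  # means[i] = window starting at residue i (1-based)
  flagged <- which(means >= threshold)
  if (!length(flagged)) return(out)
  # merge overlapping windows into segments
  starts0 <- flagged - 1L
  brk <- c(0L, which(diff(starts0) > window), length(starts0))
  segs <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
    grp <- starts0[(brk[k] + 1L):brk[k + 1L]]
    data.frame(start = grp[1], end = grp[length(grp)] + window)
  }))
  out$segments <- segs
  sp_idx <- which(segs$start < sp_cutoff)
  if (length(sp_idx)) out$sp <- c(segs$start[sp_idx[1]], segs$end[sp_idx[1]])
  tm_idx <- setdiff(seq_len(nrow(segs)), sp_idx[1])
  if (length(tm_idx)) out$tm <- c(segs$start[tm_idx[1]], segs$end[tm_idx[1]])
  out
}

# shared constructor for annotated and simulated architectures
new_domain_architecture <- function(seq_length, hits, islands, sp, tm, kd,
                                    cys_n, cys_c, gdpc, has_mld = FALSE,
                                    mld_placement = NA_character_,
                                    mld = NULL) {
  structure(list(
    seq_length = as.integer(seq_length), hits = hits, islands = islands,
    n_lrr = nrow(hits), sp = sp, tm = tm, kd = kd, mld = mld,
    has_sp = !is.null(sp), has_tm = !is.null(tm), has_kd = !is.null(kd),
    has_mld = has_mld, mld_placement = mld_placement,
    cys_n = cys_n, cys_c = cys_c, gdpc = gdpc),
    class = "domain_architecture")
}

#' Annotate the full domain architecture of a receptor sequence
#'
#' Combines the individual detectors: hydrophobic SP/TM segments, LRR motif
#' scan, island detection, Cys-pair flags, GDPC motifs (searched between the
#' SP end and the first LRR), and a kinase-domain flag (HRD and DFG
#' hallmarks downstream of the TM). Malectin-like domains are not detectable
#' from sequence here and enter via the `has_mld`/`mld_placement` arguments
#' (annotation-driven, as for receptors whose MLD is known from curation).
#'
#' @param sequence protein string.
#' @param spec an [lrr_motif_spec()].
#' @param min_gap island detection floor, residues.
#' @param pair_window Cys-pair window.
#' @param window,threshold,sp_cutoff hydropathy parameters, see
#'   [detect_hydrophobic_segments()].
#' @param has_mld,mld_placement externally supplied malectin annotation
#'   (`"nterm"` or `"pretm"`).
#' @return A `domain_architecture` object.
#' @export
domain_architecture <- function(sequence, spec = lrr_motif_spec(),
                                min_gap = 48, pair_window = 8,
                                window = 19, threshold = 1.6, sp_cutoff = 40,
                                has_mld = FALSE,
                                mld_placement = NA_character_) {
  chars <- aa_residues(sequence)
  segs <- detect_hydrophobic_segments(sequence, window, threshold, sp_cutoff)
  hits <- scan_lrr(sequence, spec)
  islands <- detect_islands(hits, min_gap)
  arch <- new_domain_architecture(length(chars), hits, islands,
                                  sp = segs$sp, tm = segs$tm, kd = NULL,
                                  cys_n = FALSE, cys_c = FALSE,
                                  gdpc = integer(0),
                                  has_mld = has_mld,
                                  mld_placement = mld_placement)
  cys <- detect_cys_pairs(sequence, arch, pair_window)
  arch$cys_n <- isTRUE(cys[[1]]); arch$cys_c <- isTRUE(cys[[2]])
  n_to <- if (nrow(hits)) hits$start[1] else length(chars)
  arch$gdpc <- detect_gdpc(sequence, c(0L, n_to))
  if (!is.null(segs$tm)) {
    icd <- substr(sequence, segs$tm[2] + 1L, length(chars))
    if (grepl("HRD", icd, fixed = TRUE) && grepl("DFG", icd, fixed = TRUE)) {
      arch$kd <- c(segs$tm[2], length(chars))
      arch$has_kd <- TRUE
    }
  }
  arch
}

#' Structural class label of an architecture
#'
#' Deterministic decision list mirroring the extracellular-domain
#' subclassification of the family. Label grammar:
#' `No_LRR`; `MLD_Nterm` (SYMRK-like N-terminal malectin); `MLD_preTM`
#' (malectin between LRRs and TM); `LRR_island3plus` / `LRR_island2`
#' (BRI1-like island of >= 3 LRR-equivalents, or a 2-equivalent island);
#' otherwise `LRR_<bucket>` with bucket `small` (<= 8 LRRs, the SERK-type
#' co-receptor range), `large` (>= 15, ligand-binding receptors) or `mid`,
#' suffixed `_cys2`, `_cysN` or `_cysC` by Cys-pair content.
#'
#' @param arch a `domain_architecture`.
#' @return A single character label.
#' @export
classify_architecture <- function(arch) {
  stopifnot(inherits(arch, "domain_architecture"))
  if (arch$n_lrr == 0) return("No_LRR")
  if (isTRUE(arch$has_mld)) {
    return(if (identical(arch$mld_placement, "pretm")) "MLD_preTM"
           else "MLD_Nterm")
  }
  if (nrow(arch$islands)) {
    eq <- max(arch$islands$lrr_equivalents)
    if (eq >= 3) return("LRR_island3plus")
    if (eq >= 2) return("LRR_island2")
  }
  bucket <- if (arch$n_lrr <= 8) "small" else if (arch$n_lrr >= 15) "large"
            else "mid"
  suffix <- if (isTRUE(arch$cys_n) && isTRUE(arch$cys_c)) "_cys2"
            else if (isTRUE(arch$cys_n)) "_cysN"
            else if (isTRUE(arch$cys_c)) "_cysC" else ""
  paste0("LRR_", bucket, suffix)
}

#' Histogram of LRR counts across proteins
#'
#' @param archs list of `domain_architecture` objects (or an integer vector
#'   of LRR counts).
#' @return List with `counts` (named integer table over observed `n_LRR`
#'   values) and `modes` (the most frequent counts).
#' @export
lrr_count_histogram <- function(archs) {
  n <- if (is.numeric(archs)) as.integer(archs)
       else vapply(archs, function(a) a$n_lrr, 1L)
  if (!length(n)) return(list(counts = integer(0), modes = integer(0)))
  counts <- table(n)
  modes <- as.integer(names(counts)[counts == max(counts)])
  list(counts = counts, modes = modes)
}
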