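# residue pools used by the generator. Linker/island residues deliberately
# avoid Cys and the six canonical LRR consensus residues (L,N,S,G,I,P) so a
# construction can never create spurious motif hits, Cys-pairs or
# hydrophobic windows: the round trip through the scanner is exact by
# design.
.HYDROPHOBIC <- c("L", "I", "V", "F")
.LINKER <- c("D", "E", "K", "R", "Q", "T", "H")
# non-canonical LRR positions draw hydrophilic residues only, so an LRR
# array can never cross the TM hydropathy threshold
.LRR_X <- c("D", "E", "H", "K", "Q", "R", "T", "Y")

#' Architecture specification for protein simulation
#'
#' Describes the domain layout of one receptor to be generated by
#' [simulate_protein()]: SP--(MLD)--Cys-pair--(GDPC)--LRRxn with islands--
#' Cys-pair--TM--KD. `n_lrr = 0` describes a kinase-only `No_LRR` homolog.
#'
#' @param n_lrr number of LRR units (>= 0).
#' @param has_sp,has_tm,has_kd,has_mld,has_gdpc domain flags.
#' @param mld_placement `"nterm"` (SYMRK-like) or `"pretm"`.
#' @param islands list of `c(after, length)` pairs: an island of `length`
#'   residues inserted after LRR number `after` (1-based, `after < n_lrr`).
#'   Lengths below 48 (the island detection floor of two LRR units) or above
#'   `max_island` are rejected.
#' @param cys_n,cys_c Cys-pair flags (N side / C side of the LRR block).
#' @param max_island maximum island length, residues.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_lrr, has_sp = TRUE, has_tm = TRUE,
                              has_kd = TRUE, has_mld = FALSE,
                              mld_placement = c("nterm", "pretm"),
                              islands = list(), cys_n = FALSE, cys_c = FALSE,
                              has_gdpc = FALSE, max_island = 300) {
  mld_placement <- match.arg(mld_placement)
  if (n_lrr < 0) stop_("n_lrr must be >= 0")
  for (isl in islands) {
    if (length(isl) != 2) stop_("each island must be c(after, length)")
    if (isl[1] < 1 || isl[1] >= n_lrr)
      stop_("island insertion index %d must lie strictly inside 1..%d",
            isl[1], n_lrr)
    if (isl[2] > max_island)
      stop_("island of %d residues exceeds max_island = %d", isl[2],
            max_island)
    if (isl[2] < 48)
      stop_("island of %d residues is below the 48-residue detection floor",
            isl[2])
  }
  structure(list(n_lrr = as.integer(n_lrr), has_sp = has_sp, has_tm = has_tm,
                 has_kd = has_kd, has_mld = has_mld,
                 mld_placement = mld_placement, islands = islands,
                 cys_n = cys_n, cys_c = cys_c, has_gdpc = has_gdpc,
                 max_island = max_island),
            class = "architecture_spec")
}

#' Simulate a receptor protein with known architecture
#'
#' Emits an amino-acid sequence assembled from an [architecture_spec()],
#' instantiating each LRR unit from the 24-position template (canonical
#' positions fixed, the 13 non-canonical positions drawn at random) and
#' returning the true coordinates of every element (0-based half-open).
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed; output is a pure function of `(spec, seed)`.
#' @param motif an [lrr_motif_spec()].
#' @return List with `sequence` (string) and `arch` (the true
#'   `domain_architecture`).
#' @export
simulate_protein <- function(spec, seed = 1, motif = lrr_motif_spec()) {
  stopifnot(inherits(spec, "architecture_spec"))
  withr::with_seed(as.integer(seed), {
    parts <- character(0)
    pos <- 0L
    sp_iv <- tm_iv <- kd_iv <- mld_iv <- NULL
    gdpc_pos <- integer(0)
    lrr_start <- lrr_end <- integer(0)
    isl <- data.frame(start = integer(), end = integer(), length = integer(),
                      lrr_equivalents = integer(), after_lrr = integer())
    add <- function(res) {
      parts[[length(parts) + 1L]] <<- paste(res, collapse = "")
      iv <- c(pos, pos + length(res))
      pos <<- pos + length(res)
      iv
    }
    lnk <- function(n) sample(.LINKER, n, replace = TRUE)

    add("M")
    if (spec$has_sp) sp_iv <- add(sample(.HYDROPHOBIC, 22, replace = TRUE))
    # hydropathy smoothing can extend a detected SP/TM boundary ~10 residues
    # into flanking linker; spacers below keep the Cys-pairs clear of it
    add(lnk(14))
    if (spec$has_mld && spec$mld_placement == "nterm")
      mld_iv <- add(lnk(110))
    if (spec$has_gdpc) {
      iv <- add(c("G", "D", "P", "C"))
      gdpc_pos <- iv[1]
      if (spec$cys_n) add(c(lnk(2), "C"))  # GDPC Cys doubles as pair start
    } else if (spec$cys_n) {
      add(c("C", lnk(2), "C"))
    }
    add(lnk(6))
    island_after <- vapply(spec$islands, `[`, 1, 1)
    for (i in seq_len(spec$n_lrr)) {
      unit <- motif$template
      free <- which(unit == "x")
      unit[free] <- sample(.LRR_X, length(free), replace = TRUE)
      iv <- add(unit)
      lrr_start <- c(lrr_start, iv[1]); lrr_end <- c(lrr_end, iv[2])
      hit <- which(island_after == i)
      for (k in hit) {
        len <- as.integer(spec$islands[[k]][2])
        iv <- add(lnk(len))
        isl <- rbind(isl, data.frame(start = iv[1], end = iv[2],
                                     length = len,
                                     lrr_equivalents = len %/% 24L,
                                     after_lrr = i))
      }
    }
    if (spec$cys_c) add(c(lnk(4), "C", lnk(2), "C", lnk(12))) else add(lnk(6))
    if (spec$has_mld && spec$mld_placement == "pretm")
      mld_iv <- add(lnk(110))
    if (pos < 55L) add(lnk(55L - pos))  # keep any TM clear of the SP zone
    if (spec$has_tm) tm_iv <- add(sample(.HYDROPHOBIC, 23, replace = TRUE))
    if (spec$has_kd) {
      kd_iv <- add(c(lnk(8), "G", "K", "G", "E", "F", "G", lnk(20),
                     "H", "R", "D", lnk(14), "D", "F", "G", lnk(25)))
    }
    add(lnk(5))

    sequence <- paste(parts, collapse = "")
    hits <- data.frame(start = lrr_start, end = lrr_end,
                       score = rep(11L, length(lrr_start)))
    arch <- new_domain_architecture(pos, hits, isl, sp = sp_iv, tm = tm_iv,
                                    kd = kd_iv, cys_n = spec$cys_n,
                                    cys_c = spec$cys_c, gdpc = gdpc_pos,
                                    has_mld = spec$has_mld,
                                    mld_placement =
                                      if (spec$has_mld) spec$mld_placement
                                      else NA_character_,
                                    mld = mld_iv)
    list(sequence = sequence, arch = arch)
  })
}
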