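#' The 24-residue LRR motif model
#'
#' Plant extracellular LRR units are scanned with a transparent
#' position-weight surrogate of a profile-HMM search: a 24-position template
#' in which 11 canonical positions carry a fixed consensus residue and the
#' 13 non-canonical positions (written `x`) are free. A window is accepted
#' when at least `threshold` of the 11 canonical positions match.
#'
#' @param template 24-character consensus; non-`x` characters are the
#'   canonical positions. Default `"LxxLxxLxLxxNxLSGxIPxxLxx"`.
#' @param threshold minimum number of canonical matches for a hit (default
#'   9 of 11).
#' @return An object of class `lrr_motif_spec` with elements `template`
#'   (character vector of length 24), `canonical` (0-based canonical
#'   positions), `length`, `threshold`.
#' @export
lrr_motif_spec <- function(template = "LxxLxxLxLxxNxLSGxIPxxLxx",
                           threshold = 9) {
  tpl <- strsplit(template, "")[[1]]
  canonical <- which(tpl != "x") - 1L
  if (length(tpl) != 24L)
    stop_("LRR template must have 24 positions, got %d", length(tpl))
  if (length(canonical) != 11L)
    stop_("LRR template must have 11 canonical positions, got %d",
          length(canonical))
  if (threshold < 1 || threshold > length(canonical))
    stop_("threshold must lie in 1..%d", length(canonical))
  structure(list(template = tpl, canonical = canonical,
                 length = length(tpl), threshold = threshold),
            class = "lrr_motif_spec")
}

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

AA_ALPHABET <- names(KD_HYDROPATHY)

# split a protein string into residues, rejecting illegal characters
aa_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop_("sequence must be a non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop_("illegal residue '%s' at position %d", chars[bad[1]], bad[1])
  chars
}
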