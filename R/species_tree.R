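#' Packaged angiosperm species tree
#'
#' A rooted binary tree of the 33 land-plant species used throughout the
#' package examples: 8 monocots, 23 dicots, plus moss (PHYPA) and spikemoss
#' (SELML) as non-angiosperm outgroups. Leaves carry five-letter species
#' codes; clade membership comes from [lrr_species_tags()].
#'
#' @return An [ape::read.tree()] `phylo` object, rooted and binary.
#' @export
lrr_species_tree <- function() {
  tree <- ape::read.tree(lrr_extdata("species_tree.nwk"))
  validate_species_tree(tree, lrr_species_tags())
  tree
}

#' Clade tags for the packaged species tree
#'
#' @return A data frame with columns `code` (five-letter species code),
#'   `clade` (`monocot`, `dicot` or `outgroup`) and `subclade`
#'   (`Poaceae`, `Solanaceae`, `Brassicaceae`, `Brassicales` or empty).
#'   Brassicaceae species are implicitly Brassicales as well; use
#'   [clade_species()] to expand.
#' @export
lrr_species_tags <- function() {
  tags <- read.delim(lrr_extdata("species_tags.tsv"), stringsAsFactors = FALSE)
  tags$subclade[is.na(tags$subclade)] <- ""
  tags
}

#' Species codes belonging to a clade
#'
#' @param tags tag table as returned by [lrr_species_tags()].
#' @param clade one of `"monocot"`, `"dicot"`, `"outgroup"`, `"angiosperm"`,
#'   `"Brassicaceae"`, `"Brassicales"`, `"Poaceae"`, `"Solanaceae"`.
#' @return Character vector of species codes.
#' @export
clade_species <- function(tags, clade) {
  switch(clade,
    monocot   = ,
    dicot     = ,
    outgroup  = tags$code[tags$clade == clade],
    angiosperm = tags$code[tags$clade %in% c("monocot", "dicot")],
    Brassicaceae = tags$code[tags$subclade == "Brassicaceae"],
    # Brassicales = Brassicaceae plus papaya
    Brassicales = tags$code[tags$subclade %in% c("Brassicaceae", "Brassicales")],
    Poaceae = tags$code[tags$subclade == "Poaceae"],
    Solanaceae = tags$code[tags$subclade == "Solanaceae"],
    stop_("unknown clade: %s", clade)
  )
}

# a rooted binary phylo with unique tips, tags covering every tip, and
# monocots / dicots each forming a contiguous clade
validate_species_tree <- function(tree, tags) {
  if (!inherits(tree, "phylo")) stop_("species tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stop_("species tree must be rooted")
  if (!ape::is.binary(tree)) stop_("species tree must be binary")
  if (anyDuplicated(tree$tip.label)) stop_("species tree tips must be unique")
  missing <- setdiff(tree$tip.label, tags$code)
  if (length(missing))
    stop_("species without clade tag: %s", paste(missing, collapse = ", "))
  for (cl in c("monocot", "dicot")) {
    sp <- intersect(clade_species(tags, cl), tree$tip.label)
    if (length(sp) > 1 && !ape::is.monophyletic(tree, sp))
      stop_("%s species do not form a clade", cl)
  }
  invisible(tree)
}
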