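#' Parameters for monocot/dicot ortholog-group extraction
#'
#' @param support branch-support threshold; strict `>` comparison
#'   (default 0.85).
#' @param min_mono minimum number of monocot species in an OG (default 3).
#' @param min_dico minimum number of dicot species (default 4).
#' @param complexity number of ancestral (non species-terminal) duplications
#'   within an OG at which it is called complex (default 2).
#' @return An object of class `og_params`.
#' @export
og_params <- function(support = 0.85, min_mono = 3, min_dico = 4,
                      complexity = 2) {
  if (support < 0 || support > 1) stop_("support must lie in [0, 1]")
  if (min_mono < 1 || min_dico < 1 || complexity < 1)
    stop_("count thresholds must be positive")
  structure(list(support = support, min_mono = min_mono,
                 min_dico = min_dico, complexity = complexity),
            class = "og_params")
}

# supports of internal nodes from node.label; a missing root label counts
# as full support, anything else missing is an error
node_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) stop_("gene tree has no branch supports")
  sup <- suppressWarnings(as.numeric(labs))
  sup[1][is.na(sup[1]) | !nzchar(labs[1])] <- 1  # root
  if (anyNA(sup))
    stop_("missing/non-numeric support at internal node %d",
          ntip + which(is.na(sup))[1])
  sup
}

#' Find monocot/dicot ortholog groups in a rooted gene tree
#'
#' Reports every internal node whose branch support strictly exceeds the
#' threshold and whose two child subtrees cleanly separate monocot from
#' dicot leaves (one child all-monocot, the other all-dicot, no outgroup
#' leaves inside), provided at least `min_mono` monocot and `min_dico` dicot
#' species are represented. Additionally reports complex candidates: maximal
#' supported nodes meeting the species-count condition whose monocot and
#' dicot leaves are intermingled below (no clean bifurcation); these come
#' pre-labeled `complex_candidate`. Reported groups are leaf-disjoint.
#'
#' @param rooted_tree rooted binary `phylo` with numeric supports in
#'   `node.label`.
#' @param tags clade-tag table (see [lrr_species_tags()]).
#' @param params an [og_params()].
#' @return List of `ortholog_group` objects: `id`, `node` (gene-tree node
#'   number), `support`, `members`, `census` (named gene counts per
#'   species), `n_mono`, `n_dico`, `complex_candidate`.
#' @export
find_md_ogs <- function(rooted_tree, tags = lrr_species_tags(),
                        params = og_params()) {
  if (!ape::is.rooted(rooted_tree)) stop_("gene tree must be rooted")
  ntip <- length(rooted_tree$tip.label)
  sup <- node_supports(rooted_tree)
  codes <- leaf_species(rooted_tree$tip.label)
  untagged <- setdiff(unique(codes), tags$code)
  if (length(untagged))
    stop_("species '%s' has no clade tag", untagged[1])
  clade <- setNames(tags$clade, tags$code)[codes]
  mono_tip <- clade == "monocot"; dico_tip <- clade == "dicot"

  kids_of <- split(rooted_tree$edge[, 2], rooted_tree$edge[, 1])
  tips_below <- vector("list", ntip + rooted_tree$Nnode)
  fill <- function(u) {
    if (u <= ntip) { tips_below[[u]] <<- u; return(invisible()) }
    kk <- kids_of[[as.character(u)]]
    for (k in kk) fill(k)
    tips_below[[u]] <<- unlist(tips_below[kk])
  }
  root <- ntip + 1L
  fill(root)

  census_of <- function(tipset) {
    sp <- codes[tipset]
    ok_mono <- length(unique(sp[mono_tip[tipset]]))
    ok_dico <- length(unique(sp[dico_tip[tipset]]))
    list(census = table(sp), n_mono = ok_mono, n_dico = ok_dico)
  }
  make_og <- function(u, complex_candidate) {
    cc <- census_of(tips_below[[u]])
    structure(list(id = NA_character_, node = u,
                   support = sup[u - ntip],
                   members = sort(rooted_tree$tip.label[tips_below[[u]]]),
                   census = cc$census, n_mono = cc$n_mono,
                   n_dico = cc$n_dico,
                   complex_candidate = complex_candidate),
              class = "ortholog_group")
  }

  is_clean_md <- function(u) {
    if (u <= ntip) return(FALSE)
    kk <- kids_of[[as.character(u)]]
    t1 <- tips_below[[kk[1]]]; t2 <- tips_below[[kk[2]]]
    (all(mono_tip[t1]) && all(dico_tip[t2])) ||
      (all(dico_tip[t1]) && all(mono_tip[t2]))
  }
  meets_thresholds <- function(u) {
    if (u <= ntip || !(sup[u - ntip] > params$support)) return(FALSE)
    cc <- census_of(tips_below[[u]])
    cc$n_mono >= params$min_mono && cc$n_dico >= params$min_dico
  }

  # pass 1: clean monocot/dicot bifurcations
  clean_nodes <- integer(0)
  for (u in (ntip + 1L):(ntip + rooted_tree$Nnode)) {
    if (is_clean_md(u) && meets_thresholds(u)) clean_nodes <- c(clean_nodes, u)
  }
  claimed <- logical(ntip + rooted_tree$Nnode)
  for (u in clean_nodes) claimed[tips_below[[u]]] <- TRUE

  # pass 2: complex candidates, top-down maximal nodes whose subtree holds
  # no reported clean OG and is not inside one
  complex_nodes <- integer(0)
  descend <- function(u) {
    if (u <= ntip) return(invisible())
    if (u %in% clean_nodes) return(invisible())
    holds_clean <- any(claimed[tips_below[[u]]])
    if (!holds_clean && meets_thresholds(u) &&
        any(mono_tip[tips_below[[u]]]) && any(dico_tip[tips_below[[u]]]) &&
        !any(clade[tips_below[[u]]] == "outgroup")) {
      complex_nodes <<- c(complex_nodes, u)
      return(invisible())
    }
    for (k in kids_of[[as.character(u)]]) descend(k)
  }
  descend(root)

  ogs <- c(lapply(clean_nodes, make_og, complex_candidate = FALSE),
           lapply(complex_nodes, make_og, complex_candidate = TRUE))
  if (length(ogs)) {
    ord <- order(vapply(ogs, `[[`, 1L, "node"))
    ogs <- ogs[ord]
    for (i in seq_along(ogs)) ogs[[i]]$id <- sprintf("OG_%02d", i)
  }
  ogs
}

#' Classify an ortholog group as simple or complex
#'
#' Counts duplication nodes inside the OG subtree whose reconciled species
#' node is internal (above species level): duplications that only create
#' within-species paralogs are ignored, since paralog content after the
#' monocot/dicot divergence does not enter the classification. The OG is
#' complex when this count reaches the `complexity` threshold or when it was
#' already a complex candidate at extraction.
#'
#' @param og an `ortholog_group` from [find_md_ogs()].
#' @param rec the [lca_map()] reconciliation of the same rooted tree.
#' @param params an [og_params()].
#' @param tree the rooted gene tree the OG was extracted from.
#' @return `"complex"` or `"simple"`.
#' @export
classify_complexity <- function(og, rec, params = og_params(), tree) {
  stopifnot(inherits(og, "ortholog_group"), inherits(rec, "reconciliation"))
  sub_nodes <- og_subtree_nodes(tree, og$node)
  nd <- rec$nodes[rec$nodes$node %in% sub_nodes &
                  rec$nodes$event %in% "duplication", , drop = FALSE]
  ancestral <- sum(nd$sp_node > rec$sp_ntip)
  if (og$complex_candidate || ancestral >= params$complexity) "complex"
  else "simple"
}

# all node numbers (tips + internals) in the subtree rooted at `node`
og_subtree_nodes <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  walk <- function(u) {
    out <<- c(out, u)
    if (u > ntip) for (k in kids_of[[as.character(u)]]) walk(k)
  }
  walk(node)
  out
}

#' Presence/absence matrix of ortholog groups across species
#'
#' @param ogs list of `ortholog_group`s (leaf-disjoint).
#' @param species_list column order; e.g. the 31 angiosperm codes.
#' @return Integer matrix, rows = OG ids, columns = species, cells = gene
#'   counts (0 = inferred loss).
#' @export
presence_absence <- function(ogs, species_list) {
  mat <- matrix(0L, nrow = length(ogs), ncol = length(species_list),
                dimnames = list(vapply(ogs, `[[`, "", "id"), species_list))
  all_members <- unlist(lapply(ogs, `[[`, "members"))
  if (anyDuplicated(all_members)) stop_("ortholog groups are not disjoint")
  for (i in seq_along(ogs)) {
    cen <- ogs[[i]]$census
    keep <- intersect(names(cen), species_list)
    mat[i, keep] <- as.integer(cen[keep])
  }
  mat
}

#' Ortholog groups absent from every member of a clade
#'
#' @param matrix presence/absence matrix from [presence_absence()].
#' @param clade character vector of species codes (must be matrix columns).
#' @return Character vector of OG ids with zero genes in all clade species.
#' @export
detect_clade_absence <- function(matrix, clade) {
  if (!length(clade)) stop_("clade must contain at least one species")
  missing <- setdiff(clade, colnames(matrix))
  if (length(missing))
    stop_("species '%s' is not a matrix column", missing[1])
  rownames(matrix)[rowSums(matrix[, clade, drop = FALSE]) == 0]
}

#' Family census of genes inside and outside ortholog groups
#'
#' @param complex_genes,complex_ogs genes and group count in complex OGs.
#' @param noncomplex_genes,noncomplex_ogs same for non-complex OGs.
#' @param total_sequences family size across all species.
#' @param outgroup_counts named or unnamed vector of gene counts in the
#'   non-angiosperm outgroup species.
#' @return An object of class `family_census`.
#' @export
family_census <- function(complex_genes, complex_ogs, noncomplex_genes,
                          noncomplex_ogs, total_sequences, outgroup_counts) {
  cen <- list(complex_genes = complex_genes, complex_ogs = complex_ogs,
              noncomplex_genes = noncomplex_genes,
              noncomplex_ogs = noncomplex_ogs,
              total_sequences = total_sequences,
              outgroup_counts = outgroup_counts)
  if (any(unlist(cen) < 0)) stop_("census counts must be non-negative")
  structure(cen, class = "family_census")
}

#' Summary statistics of the ortholog-group census
#'
#' Computes the family-level arithmetic reported for the core set: total
#' genes inside OGs, mean genes per complex and per non-complex OG (one
#' decimal, half-up), and the percentage of angiosperm genes contained in
#' OGs (denominator = total sequences minus outgroup genes).
#'
#' @param census a [family_census()].
#' @return List with `genes_in_ogs`, `n_ogs`, `n_complex_ogs`,
#'   `mean_genes_complex`, `mean_genes_noncomplex`, `pct_angiosperm_in_ogs`.
#' @export
summarize_ogs <- function(census) {
  stopifnot(inherits(census, "family_census"))
  in_ogs <- census$complex_genes + census$noncomplex_genes
  angio <- census$total_sequences - sum(census$outgroup_counts)
  if (angio < in_ogs)
    stop_("census inconsistent: %d genes in OGs exceed %d angiosperm genes",
          in_ogs, angio)
  list(
    genes_in_ogs = in_ogs,
    n_ogs = census$complex_ogs + census$noncomplex_ogs,
    n_complex_ogs = census$complex_ogs,
    mean_genes_complex =
      if (census$complex_ogs) round_half_up(census$complex_genes /
                                            census$complex_ogs, 1) else 0,
    mean_genes_noncomplex =
      if (census$noncomplex_ogs) round_half_up(census$noncomplex_genes /
                                               census$noncomplex_ogs, 1)
      else 0,
    pct_angiosperm_in_ogs =
      if (angio > 0) round_half_up(100 * in_ogs / angio, 1) else 0)
}

#' Packaged per-subgroup ortholog-group counts
#'
#' The per-SG table of monocot/dicot OG totals and complex-OG counts for the
#' 20 kinase-phylogeny subgroups.
#'
#' @return Data frame `sg`, `n_og`, `n_complex`.
#' @export
load_og_counts <- function() {
  read.delim(lrr_extdata("table1_og_counts.tsv"), stringsAsFactors = FALSE)
}

#' Packaged family census numbers
#'
#' @return A [family_census()] built from the packaged census file
#'   (7,767 LRR-containing + 593 No_LRR sequences; moss and spikemoss
#'   outgroup counts; complex / non-complex OG gene totals).
#' @export
load_family_census <- function() {
  raw <- read.delim(lrr_extdata("family_census.tsv"),
                    stringsAsFactors = FALSE)
  v <- setNames(raw$value, raw$quantity)
  family_census(
    complex_genes = v[["complex_og_genes"]],
    complex_ogs = v[["complex_og_count"]],
    noncomplex_genes = v[["noncomplex_og_genes"]],
    noncomplex_ogs = v[["noncomplex_og_count"]],
    total_sequences = v[["lrr_containing_sequences"]] +
      v[["no_lrr_sequences"]],
    outgroup_counts = c(PHYPA = v[["outgroup_phypa"]],
                        SELML = v[["outgroup_selml"]]))
}
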