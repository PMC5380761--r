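# Independent reconciliation oracle: same definition, different machinery
# (species sets + ape::getMRCA for the mapping, ape::nodepath for path
# lengths, phangorn::Descendants for clades). Used to cross-check lca_map
# and root_by_dl; kept free of lrrcore internals.

oracle_recon <- function(gene_tree, species_tree) {
  ntip <- length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  desc <- phangorn::Descendants(gene_tree, seq_len(nnode), type = "tips")
  map_of <- function(u) {
    sps <- unique(sub("_.*$", "", gene_tree$tip.label[desc[[u]]]))
    if (length(sps) == 1) match(sps, species_tree$tip.label)
    else ape::getMRCA(species_tree, sps)
  }
  M <- vapply(seq_len(nnode), map_of, 1L)
  D <- 0L; L <- 0L
  for (u in (ntip + 1L):nnode) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == u, 2]
    dup <- M[u] == M[kids[1]] || M[u] == M[kids[2]]
    if (dup) D <- D + 1L
    for (v in kids) {
      path <- length(ape::nodepath(species_tree, M[u], M[v])) - 1L
      L <- L + if (dup) path else path - 1L
    }
  }
  c(D = D, L = L)
}

# exhaustive minimum of D + L over every rooting of an unrooted tree
oracle_min_dl <- function(unrooted, species_tree) {
  phy <- if (ape::is.rooted(unrooted)) ape::unroot(unrooted) else unrooted
  ntip <- length(phy$tip.label)
  best <- Inf
  for (i in seq_len(nrow(phy$edge))) {
    tips <- phangorn::Descendants(phy, phy$edge[i, 2], "tips")[[1]]
    if (length(tips) == ntip) next
    rooted <- ape::root(phy, outgroup = phy$tip.label[tips],
                        resolve.root = TRUE)
    if (!ape::is.binary(rooted)) next
    best <- min(best, sum(oracle_recon(rooted, species_tree)))
  }
  best
}

# random gene tree over a species set: random topology, tips drawn from the
# species codes with replacement (duplicate species create duplications)
random_gene_tree <- function(n_leaves, codes) {
  phy <- ape::rtree(n_leaves, rooted = FALSE, br = NULL)
  sp <- sample(codes, n_leaves, replace = TRUE)
  phy$tip.label <- sprintf("%s_g%d", sp, seq_len(n_leaves))
  phy
}

# compact tag table for hand-built test worlds
make_tags <- function(codes, clades) {
  data.frame(code = codes, clade = clades, subclade = "",
             stringsAsFactors = FALSE)
}

# 5-taxon test world: 2 monocots, 3 dicots (codes must not contain "_")
toy_species_tree <- function() ape::read.tree(text = "((MONOA,MONOB),(DICOA,(DICOB,DICOC)));")
toy_tags <- function() make_tags(c("MONOA", "MONOB", "DICOA", "DICOB", "DICOC"),
                                 c("monocot", "monocot", "dicot", "dicot", "dicot"))
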