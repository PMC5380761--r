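# precomputed navigation for a rooted binary species tree: parent array,
# edge depth from the root, and tip lookup by label
species_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nnode <- ntip + species_tree$Nnode
  parent <- integer(nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  root <- ntip + 1L
  depth <- integer(nnode)
  ed <- reorder(species_tree)$edge  # cladewise: parents before children
  for (i in seq_len(nrow(ed))) depth[ed[i, 2]] <- depth[ed[i, 1]] + 1L
  list(ntip = ntip, root = root, parent = parent, depth = depth,
       tip = setNames(seq_len(ntip), species_tree$tip.label))
}

# LCA of two nodes using depth/parent arrays
sp_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else if (idx$depth[b] < idx$depth[a]) a <- idx$parent[a]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

# species code of a gene leaf label ("ARATH_g001" -> "ARATH")
leaf_species <- function(label) sub("_.*$", "", label)

# reject multifurcating trees, naming the offending node
check_binary <- function(tree, what) {
  deg <- tabulate(tree$edge[, 1])
  bad <- which(deg > 2)
  if (length(bad))
    stop_("%s has a multifurcating node (%d children) at node %d",
          what, deg[bad[1]], bad[1])
  invisible(tree)
}

#' LCA reconciliation of a rooted gene tree with the species tree
#'
#' Maps every gene-tree node to its species-tree node by last-common-ancestor
#' reconciliation: a leaf maps to its species, an internal node to the
#' species LCA of its children's images. A node is a duplication when its
#' image equals a child's image, a speciation otherwise. Losses on the edge
#' from node `u` to child `v` equal the number of species-tree edges on the
#' path from `M(u)` to `M(v)` minus one for speciations, or the full path
#' length for duplications.
#'
#' @param gene_tree rooted binary `phylo`; leaf labels `<SPECI>_...` with the
#'   species code before the first underscore.
#' @param species_tree rooted binary `phylo` containing every leaf's species.
#' @return An object of class `reconciliation`: list with `nodes` (data
#'   frame: gene node number, `sp_node`, `event`), `edge_losses` (data
#'   frame: `parent`, `child`, `n`), `D`, `L`.
#' @export
lca_map <- function(gene_tree, species_tree) {
  check_binary(gene_tree, "gene tree")
  check_binary(species_tree, "species tree")
  if (!ape::is.rooted(gene_tree)) stop_("gene tree must be rooted")
  idx <- species_index(species_tree)
  ntip <- length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  codes <- leaf_species(gene_tree$tip.label)
  unknown <- which(!codes %in% names(idx$tip))
  if (length(unknown))
    stop_("leaf '%s' has species code '%s' absent from the species tree",
          gene_tree$tip.label[unknown[1]], codes[unknown[1]])

  M <- integer(nnode)
  M[seq_len(ntip)] <- idx$tip[codes]
  event <- rep(NA_character_, nnode)
  edge <- gene_tree$edge
  kids_of <- split(edge[, 2], edge[, 1])
  visit <- function(u) {
    if (u <= ntip) return(invisible())
    kk <- kids_of[[as.character(u)]]
    for (k in kk) visit(k)
    M[u] <<- sp_lca(idx, M[kk[1]], M[kk[2]])
    event[u] <<- if (M[u] == M[kk[1]] || M[u] == M[kk[2]]) "duplication"
                 else "speciation"
  }
  visit(ntip + 1L)
  loss <- integer(nrow(edge))
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1]; v <- edge[i, 2]
    path <- idx$depth[M[v]] - idx$depth[M[u]]
    loss[i] <- if (event[u] == "speciation") path - 1L else path
  }
  internal <- (ntip + 1L):nnode
  structure(list(
    nodes = data.frame(node = seq_len(nnode), sp_node = M, event = event),
    edge_losses = data.frame(parent = edge[, 1], child = edge[, 2], n = loss),
    D = sum(event[internal] == "duplication"),
    L = sum(loss), sp_ntip = idx$ntip), class = "reconciliation")
}

#' Duplication and loss totals of a reconciliation
#'
#' @param rec a [lca_map()] result.
#' @return Named integer vector `c(D = ..., L = ...)`.
#' @export
count_events <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  c(D = rec$D, L = rec$L)
}

#' Root an unrooted gene tree by duplication-loss parsimony
#'
#' Evaluates every edge of the unrooted tree as a candidate root position,
#' reconciles each rooting against the species tree, and returns the rooting
#' minimising duplications + losses. Ties are broken by smaller D, then by
#' the candidate edge whose child clade has the lexicographically smallest
#' sorted leaf-label list, making the result deterministic.
#'
#' @param unrooted_tree `phylo` with at least 3 leaves (a rooted input is
#'   unrooted first).
#' @param species_tree rooted binary species `phylo`.
#' @return List with `tree` (the rooted `phylo`), `rec` (its
#'   [lca_map()] reconciliation) and `score` (`c(D=, L=)`).
#' @export
root_by_dl <- function(unrooted_tree, species_tree) {
  if (length(unrooted_tree$tip.label) < 3)
    stop_("need at least 3 leaves to root")
  phy <- if (ape::is.rooted(unrooted_tree)) ape::unroot(unrooted_tree)
         else unrooted_tree
  ntip <- length(phy$tip.label)
  best <- NULL
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2]
    out_tips <- clade_tips(phy, child)
    if (length(out_tips) == ntip) next
    rooted <- ape::root(phy, outgroup = out_tips, resolve.root = TRUE,
                        edgelabel = TRUE)
    if (!ape::is.binary(rooted)) next
    rec <- lca_map(rooted, species_tree)
    key <- paste(sort(out_tips), collapse = "\r")
    cand <- list(tree = rooted, rec = rec, score = count_events(rec),
                 key = key)
    if (is.null(best) ||
        sum(cand$score) < sum(best$score) ||
        (sum(cand$score) == sum(best$score) &&
         (cand$score["D"] < best$score["D"] ||
          (cand$score["D"] == best$score["D"] && key < best$key))))
      best <- cand
  }
  best$key <- NULL
  best
}
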