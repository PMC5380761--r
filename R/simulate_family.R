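#' Simulation configuration for gene-family evolution
#'
#' Parameters of the duplication--loss copy process used by
#' [simulate_gene_family()]. A single gene enters the species-tree root; on
#' every species-tree edge each extant copy duplicates or dies with
#' exponential waiting times, and at every speciation node every surviving
#' copy bifurcates.
#'
#' @param dup_rate duplication rate, events per copy per unit branch length.
#' @param loss_rate loss rate, same units.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param root_duplications number of duplications forced at the species-tree
#'   root before descent, giving `root_duplications + 1` independent family
#'   copies (the ancestral duplications that create paired ortholog groups).
#' @param edge_length branch length assigned to species-tree edges that carry
#'   none.
#' @param clade_rate_mult optional named list of rate multipliers applied to
#'   both rates on edges whose descendant species all belong to the named
#'   clade (`monocot`, `dicot`, `outgroup`).
#' @return An object of class `lrr_sim_config`.
#' @export
sim_config <- function(dup_rate = 0.05, loss_rate = 0.02, seed = 1,
                       root_duplications = 0, edge_length = 1,
                       clade_rate_mult = NULL) {
  if (!is.finite(dup_rate) || dup_rate < 0) stop_("dup_rate must be >= 0")
  if (!is.finite(loss_rate) || loss_rate < 0) stop_("loss_rate must be >= 0")
  if (root_duplications < 0) stop_("root_duplications must be >= 0")
  if (edge_length <= 0) stop_("edge_length must be > 0")
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 seed = as.integer(seed),
                 root_duplications = as.integer(root_duplications),
                 edge_length = edge_length,
                 clade_rate_mult = clade_rate_mult),
            class = "lrr_sim_config")
}

# tips (labels) below a node of a phylo
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

#' Simulate one gene family along a species tree
#'
#' Runs a birth--death copy process along a rooted binary species tree and
#' returns the surviving gene tree together with its full ground truth:
#' the true speciation/duplication label of every internal node, the loss
#' events per species-tree edge, and the true monocot/dicot ortholog groups
#' (gene-tree speciation nodes mapping to the angiosperm crown node).
#'
#' Gene leaves are named `<SPECI>_g<NNN>` where `SPECI` is the five-letter
#' species code. With both rates zero the gene tree is topologically
#' congruent with the species tree, one gene per species, and every internal
#' event is a speciation.
#'
#' @param species_tree rooted binary `phylo`; see [lrr_species_tree()].
#' @param config an [sim_config()] object.
#' @param tags clade-tag table; defaults to [lrr_species_tags()].
#' @return An object of class `gene_family_truth`: a list with elements
#'   `tree` (`phylo`, internal nodes labeled `N1`, `N2`, ...), `newick`
#'   (the exact Newick string written), `events` (data frame: `node`,
#'   `event`, `sp_node`), `losses` (data frame: `sp_node`, `n`), and `ogs`
#'   (list of true ortholog groups, each with `node`, `members`, `n_mono`,
#'   `n_dico`).
#' @export
simulate_gene_family <- function(species_tree, config,
                                 tags = lrr_species_tags()) {
  if (!inherits(config, "lrr_sim_config"))
    stop_("config must be built with sim_config()")
  validate_species_tree(species_tree, tags)
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  edge <- species_tree$edge
  elen <- species_tree$edge.length %||% rep(config$edge_length, nrow(edge))

  # clade label per species node (monocot/dicot/outgroup if the whole
  # subtree is within one clade), for the per-clade rate multipliers
  clade_of <- character(ntip + species_tree$Nnode)
  tagmap <- setNames(tags$clade, tags$code)
  for (v in seq_len(ntip + species_tree$Nnode)) {
    cl <- unique(tagmap[clade_tips(species_tree, v)])
    clade_of[v] <- if (length(cl) == 1) cl else ""
  }
  rate_mult <- function(v) {
    m <- config$clade_rate_mult[[clade_of[v]]] %||% 1
    m
  }

  env <- new.env(parent = emptyenv())
  env$gene_n <- setNames(integer(ntip), species_tree$tip.label)
  env$node_n <- 0L
  env$events <- list()
  env$losses <- integer(ntip + species_tree$Nnode)  # keyed by child sp node

  new_internal <- function(event, sp_node, left, right) {
    env$node_n <- env$node_n + 1L
    lab <- paste0("N", env$node_n)
    env$events[[lab]] <- list(event = event, sp_node = sp_node)
    list(kind = "node", label = lab, left = left, right = right)
  }

  evolve_node <- function(sp) {
    if (sp <= ntip) {
      code <- species_tree$tip.label[sp]
      env$gene_n[code] <- env$gene_n[code] + 1L
      return(list(kind = "leaf",
                  label = sprintf("%s_g%03d", code, env$gene_n[code])))
    }
    kids <- edge[edge[, 1] == sp, 2]
    a <- evolve_edge(kids[1])
    b <- evolve_edge(kids[2])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    new_internal("speciation", sp, a, b)
  }

  evolve_edge <- function(sp_child) {
    t_rem <- elen[match(sp_child, edge[, 2])]
    mult <- rate_mult(sp_child)
    lam <- config$dup_rate * mult
    mu <- config$loss_rate * mult
    descend <- function(t_rem) {
      total <- lam + mu
      if (total > 0) {
        w <- rexp(1, total)
        if (w < t_rem) {
          if (runif(1) < lam / total) {
            a <- descend(t_rem - w)
            b <- descend(t_rem - w)
            if (is.null(a)) return(b)
            if (is.null(b)) return(a)
            return(new_internal("duplication", sp_child, a, b))
          }
          env$losses[sp_child] <- env$losses[sp_child] + 1L
          return(NULL)
        }
      }
      evolve_node(sp_child)
    }
    descend(t_rem)
  }

  res <- withr::with_seed(config$seed, {
    fam <- evolve_node(root)
    for (i in seq_len(config$root_duplications)) {
      extra <- evolve_node(root)
      if (is.null(fam)) fam <- extra
      else if (!is.null(extra))
        fam <- new_internal("duplication", root, fam, extra)
    }
    fam
  })
  if (is.null(res) || res$kind == "leaf")
    stop_("fewer than two genes survived; increase rates' balance or seed")

  to_newick <- function(n) {
    if (n$kind == "leaf") return(n$label)
    sprintf("(%s,%s)%s", to_newick(n$left), to_newick(n$right), n$label)
  }
  newick <- paste0(to_newick(res), ";")
  tree <- ape::read.tree(text = newick)

  events <- data.frame(
    node = names(env$events),
    event = vapply(env$events, `[[`, "", "event"),
    sp_node = vapply(env$events, function(e) as.integer(e$sp_node), 1L),
    row.names = NULL, stringsAsFactors = FALSE)

  loss_idx <- which(env$losses > 0)
  losses <- data.frame(sp_node = loss_idx, n = env$losses[loss_idx])

  # true MD ortholog groups: speciation nodes mapping to the crown node of
  # the angiosperms (the monocot/dicot split)
  angio <- intersect(clade_species(tags, "angiosperm"),
                     species_tree$tip.label)
  md_crown <- ape::getMRCA(species_tree, angio)
  og_nodes <- events$node[events$event == "speciation" &
                          events$sp_node == md_crown]
  mono <- clade_species(tags, "monocot")
  dico <- clade_species(tags, "dicot")
  ogs <- lapply(og_nodes, function(lab) {
    v <- length(tree$tip.label) + match(lab, tree$node.label)
    members <- clade_tips(tree, v)
    sp <- unique(sub("_.*", "", members))
    list(node = lab, members = sort(members),
         n_mono = sum(sp %in% mono), n_dico = sum(sp %in% dico))
  })

  structure(list(tree = tree, newick = newick, events = events,
                 losses = losses, ogs = ogs,
                 species_tree = species_tree, config = config),
            class = "gene_family_truth")
}

#' Attach branch supports to a simulated gene tree
#'
#' Replaces the truth labels of a [simulate_gene_family()] tree with branch
#' support values in `[0, 1]`. With zero noise every internal node gets
#' support 1.0; `noise_sd` draws supports as `1 - |N(0, noise_sd)|`
#' (clamped), and `targets` overrides named nodes exactly -- the handle used
#' to push chosen ortholog-group roots below the 0.85 filter.
#'
#' @param truth a `gene_family_truth` object.
#' @param noise_sd standard deviation of the downward support noise.
#' @param targets named numeric vector: truth node label (e.g. `"N3"`) to
#'   support value.
#' @param seed integer seed for the noise draw.
#' @return A `phylo` whose `node.label` holds the supports (as characters,
#'   the Newick convention).
#' @export
assign_supports <- function(truth, noise_sd = 0, targets = NULL, seed = 1) {
  stopifnot(inherits(truth, "gene_family_truth"))
  labs <- truth$tree$node.label
  supports <- withr::with_seed(as.integer(seed), {
    s <- rep(1, length(labs))
    if (noise_sd > 0) s <- pmin(1, pmax(0, 1 - abs(rnorm(length(s), 0, noise_sd))))
    s
  })
  if (!is.null(targets)) {
    if (any(targets < 0 | targets > 1)) stop_("supports must lie in [0, 1]")
    idx <- match(names(targets), labs)
    if (anyNA(idx)) stop_("unknown node label in targets")
    supports[idx] <- targets
  }
  out <- truth$tree
  out$node.label <- format(supports, trim = TRUE, digits = 6)
  out
}
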