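#' LCA-mapping of a gene or synteny tree into the species tree
#'
#' Maps every node `v` to the lowest common ancestor in the species tree of
#' the species of the leaves below `v`. This mapping minimizes the
#' reconciliation cost, and remains optimal for supertrees of synteny trees.
#'
#' @param tidx indexed tree (from [index_tree()]).
#' @param leaf_species named character vector: leaf label -> species label.
#' @param sidx indexed species tree.
#' @return integer vector: species-tree node id for every node of `tidx`.
#' @keywords internal
lca_mapping <- function(tidx, leaf_species, sidx) {
  smap <- integer(tidx$n)
  for (v in index_postorder(tidx)) {
    if (tidx$is_leaf[v]) {
      sp <- leaf_species[[tidx$label[v]]]
      sid <- sidx$leaf_id[sp]
      if (is.na(sid))
        stop_superrec("superrec_species_mismatch",
                      sprintf("species '%s' not in species tree", sp))
      smap[v] <- sid
    } else {
      ids <- smap[tidx$children[[v]]]
      m <- ids[1L]
      for (i in ids[-1L]) m <- index_lca(sidx, m, i)
      smap[v] <- m
    }
  }
  smap
}

#' Speciation/duplication labeling under the LCA-mapping
#'
#' An internal node is a speciation iff the species of its two children are
#' separated in the species tree (neither is an ancestor of the other), and a
#' duplication otherwise. Labeling precedes loss grafting, so every internal
#' node must be binary.
#'
#' @inheritParams lca_mapping
#' @param smap the LCA-mapping of `tidx`.
#' @return character vector: `"Spe"`, `"Dup"` for internal nodes, `"Leaf"`
#'   for leaves.
#' @keywords internal
label_events <- function(tidx, smap, sidx) {
  ev <- character(tidx$n)
  for (v in seq_len(tidx$n)) {
    if (tidx$is_leaf[v]) { ev[v] <- "Leaf"; next }
    kids <- tidx$children[[v]]
    if (length(kids) != 2L)
      stop_superrec("superrec_nonbinary_tree",
                    "event labeling requires a binary tree")
    a <- smap[kids[1L]]; b <- smap[kids[2L]]
    sep <- !index_is_anc(sidx, a, b) && !index_is_anc(sidx, b, a)
    ev[v] <- if (sep) "Spe" else "Dup"
  }
  ev
}

#' Build the loss-grafted backbone of a supertree
#'
#' Takes a binary synteny (super)tree, LCA-maps it, labels speciations and
#' duplications, and grafts one full-loss leaf per skipped species-tree edge
#' on every edge whose child maps too deep: for a speciation parent, the
#' child should map to a child of the parent's species; for a duplication
#' parent, to the parent's species itself. Grafted nodes are speciations at
#' the intermediate species, with the full-loss leaf assigned the sibling
#' species and the empty synteny; loss leaves sit closest to the parent.
#'
#' The result is a flat node table ready for the ordered and unordered
#' dynamic programs.
#'
#' @param supertree binary `sr_tree` with synteny-id leaves.
#' @param leaf_species named character vector: synteny id -> species label.
#' @param sidx indexed species tree.
#' @return a list (`sr_backbone`) with parallel vectors over nodes:
#'   `children` (list of integer vectors), `event` (`"Spe"`, `"Dup"`,
#'   `"Leaf"` = extant leaf, `"Loss"` = grafted full-loss leaf), `species`
#'   (species-tree node id), `leaf` (synteny id or `NA`), plus `root`,
#'   `postorder` and the species index.
#' @export
build_backbone <- function(supertree, leaf_species, sidx) {
  if (!tree_is_binary(supertree))
    stop_superrec("superrec_nonbinary_tree", "supertree must be binary")
  tidx <- index_tree(supertree)
  smap <- lca_mapping(tidx, leaf_species, sidx)
  ev <- label_events(tidx, smap, sidx)

  children <- list(); event <- character(0); species <- integer(0)
  leaf <- character(0)
  add_node <- function(evt, sp, lf = NA_character_) {
    id <- length(event) + 1L
    event[id] <<- evt; species[id] <<- sp; leaf[id] <<- lf
    children[[id]] <<- integer(0)
    id
  }
  # Emit node v of the original tree; graft the chain for edge (parent -> v)
  # above it and return the id of the topmost emitted node on the edge.
  emit <- function(v, parent_sp, parent_ev) {
    vid <- if (tidx$is_leaf[v]) add_node("Leaf", smap[v], tidx$label[v])
           else add_node(ev[v], smap[v])
    if (!tidx$is_leaf[v]) {
      for (c in tidx$children[[v]])
        children[[vid]] <<- c(children[[vid]], emit(c, smap[v], ev[v]))
    }
    if (is.na(parent_ev)) return(vid)  # root: nothing above
    # graft points: intermediate species between the expected start and s(v)
    path <- index_path_down(sidx, parent_sp, smap[v])
    start <- if (parent_ev == "Spe") 2L else 1L  # Spe: child of s(parent)
    graft_at <- path[seq.int(start, length.out = max(0L, length(path) - start))]
    top <- vid
    for (p in rev(graft_at)) {  # bottom-up so losses end up closest to parent
      q <- path[match(p, path) + 1L]
      sib <- setdiff(sidx$children[[p]], q)
      g <- add_node("Spe", p)
      l <- add_node("Loss", sib)
      children[[g]] <<- c(top, l)
      top <- g
    }
    top
  }
  root <- emit(tidx$root, 0L, NA)
  bb <- list(n = length(event), children = children, event = event,
             species = species, leaf = leaf, root = root,
             species_index = sidx)
  bb$parent <- integer(bb$n)
  for (v in seq_len(bb$n)) for (c in bb$children[[v]]) bb$parent[c] <- v
  bb$postorder <- local({
    out <- integer(0)
    rec <- function(v) {
      for (c in bb$children[[v]]) rec(c)
      out[[length(out) + 1L]] <<- v
    }
    rec(bb$root)
    out
  })
  class(bb) <- "sr_backbone"
  bb
}

#' @export
print.sr_backbone <- function(x, ...) {
  cat(sprintf("<sr_backbone> %d nodes (%d extant, %d full-loss leaves)\n",
              x$n, sum(x$event == "Leaf"), sum(x$event == "Loss")))
  invisible(x)
}

# Number of grafted full-loss leaves in a backbone.
backbone_n_losses <- function(bb) sum(bb$event == "Loss")

#' Classical duplication-loss reconciliation cost of one gene tree
#'
#' The textbook LCA-reconciliation cost: the number of duplication nodes plus
#' the number of lost branches, where an edge from `v` to child `c`
#' contributes `depth(s(c)) - depth(s(v))` losses minus one if `v` is a
#' speciation. Used as the single-gene baseline that segmental
#' super-reconciliation must reduce to when every synteny holds one gene.
#'
#' @param gene_tree binary `sr_tree` with gene-id leaves.
#' @param leaf_species named character vector: gene id -> species label.
#' @param species_tree `sr_tree` (or an index from [index_tree()]).
#' @return integer cost (duplications + losses).
#' @export
classic_dl_cost <- function(gene_tree, leaf_species, species_tree) {
  sidx <- if (inherits(species_tree, "sr_tree"))
    index_tree(species_tree, autolabel = TRUE) else species_tree
  tidx <- index_tree(gene_tree)
  smap <- lca_mapping(tidx, leaf_species, sidx)
  ev <- label_events(tidx, smap, sidx)
  cost <- sum(ev == "Dup")
  for (v in seq_len(tidx$n)) {
    if (tidx$is_leaf[v]) next
    for (c in tidx$children[[v]]) {
      d <- sidx$depth[smap[c]] - sidx$depth[smap[v]]
      cost <- cost + d - (ev[v] == "Spe")
    }
  }
  as.integer(cost)
}
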