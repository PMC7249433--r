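# Instance generators used across the suite. All randomness flows through
# the session RNG, so each test sets its own seed.

# Random rooted binary topology over the given leaf labels: each new leaf is
# attached above a uniformly chosen node (edge subdivision, or a new root).
rand_topology <- function(labels) {
  t <- sr_tree_leaf(labels[1L])
  for (lab in labels[-1L]) {
    leaf <- sr_tree_leaf(lab)
    pick <- sample.int(tree_n_nodes(t), 1L)
    k <- 0L
    ins <- function(node) {
      k <<- k + 1L
      if (k == pick) return(sr_tree_node(list(leaf, node)))
      if (length(node$children)) {
        for (i in seq_along(node$children)) {
          if (k >= pick) break
          node$children[[i]] <- ins(node$children[[i]])
        }
      }
      node
    }
    t <- ins(t)
  }
  t
}

rand_species_tree <- function(n_species) {
  rand_topology(paste0("sp", seq_len(n_species)))
}

# Random nonempty subsequence of A.
rand_subseq <- function(A) {
  k <- sample.int(length(A), 1L)
  A[sort(sample.int(length(A), k))]
}

# A random ordered-mode instance: species tree, backbone over extant
# syntenies with random species, random subsequence syntenies. Regenerates
# until the brute-force oracle grid stays below `max_rows`.
rand_ordered_instance <- function(t = 3L, n_leaves = 3L, n_species = 2L,
                                  max_rows = 2e5) {
  A <- letters[seq_len(t)]
  repeat {
    S <- rand_species_tree(n_species)
    sidx <- index_tree(S, autolabel = TRUE)
    ids <- paste0("X", seq_len(n_leaves))
    st <- if (n_leaves == 1L) sr_tree_leaf(ids) else rand_topology(ids)
    leaf_sp <- stats::setNames(sample(paste0("sp", seq_len(n_species)),
                                      n_leaves, replace = TRUE), ids)
    syn <- stats::setNames(lapply(ids, function(i) rand_subseq(A)), ids)
    bb <- build_backbone(st, leaf_sp, sidx)
    n_free <- sum(!(bb$event %in% c("Leaf", "Loss"))) -
      (bb$event[bb$root] != "Leaf")
    if ((2^t - 1)^n_free <= max_rows)
      return(list(A = A, S = S, sidx = sidx, supertree = st,
                  leaf_species = leaf_sp, syntenies = syn, bb = bb))
  }
}

# A random unordered-mode instance (same structure; only the contents are
# used). |F| = t families, sets are arbitrary nonempty subsets.
rand_unordered_instance <- function(t = 4L, n_leaves = 3L, n_species = 2L,
                                    max_rows = 2e5) {
  fams <- letters[seq_len(t)]
  repeat {
    S <- rand_species_tree(n_species)
    sidx <- index_tree(S, autolabel = TRUE)
    ids <- paste0("X", seq_len(n_leaves))
    st <- if (n_leaves == 1L) sr_tree_leaf(ids) else rand_topology(ids)
    leaf_sp <- stats::setNames(sample(paste0("sp", seq_len(n_species)),
                                      n_leaves, replace = TRUE), ids)
    sets <- stats::setNames(lapply(ids, function(i) {
      k <- sample.int(t, 1L)
      sort(sample(fams, k))
    }), ids)
    # every family of the universe must appear in some extant synteny
    if (!setequal(unique(unlist(sets)), fams)) next
    bb <- build_backbone(st, leaf_sp, sidx)
    # oracle grid size: product over free internal nodes of superset counts
    ls <- compute_lca_sets(bb, sets, fams)
    free <- which(!(bb$event %in% c("Leaf", "Loss")) & seq_len(bb$n) != bb$root)
    sz <- prod(2^(t - vapply(ls$mask[free], bit_count, integer(1))))
    if (sz <= max_rows)
      return(list(families = fams, S = S, sidx = sidx, supertree = st,
                  leaf_species = leaf_sp, sets = sets, bb = bb))
  }
}

# Random single-family instance for the classical-DL reduction: one gene per
# synteny, one gene tree.
rand_single_family_instance <- function(n_genes = 4L, n_species = 3L) {
  S <- rand_species_tree(n_species)
  genes <- paste0("g", seq_len(n_genes))
  gt <- if (n_genes == 1L) sr_tree_leaf(genes) else rand_topology(genes)
  sp <- sample(paste0("sp", seq_len(n_species)), n_genes, replace = TRUE)
  tab <- data.frame(gene = genes, family = "fam1", species = sp,
                    synteny = paste0("X", seq_len(n_genes)), position = 1L,
                    stringsAsFactors = FALSE)
  list(S = S, gene_tree = gt, syn = syntenies_from_table(tab),
       leaf_species = stats::setNames(sp, genes))
}

# Sub-backbone rooted at node v (nodes renumbered in preorder).
sub_backbone <- function(bb, v) {
  event <- character(0); species <- integer(0); leaf <- character(0)
  children <- list()
  copy <- function(w) {
    id <- length(event) + 1L
    event[id] <<- bb$event[w]; species[id] <<- bb$species[w]
    leaf[id] <<- bb$leaf[w]; children[[id]] <<- integer(0)
    for (c in bb$children[[w]])
      children[[id]] <<- c(children[[id]], copy(c))
    id
  }
  root <- copy(v)
  sb <- list(n = length(event), children = children, event = event,
             species = species, leaf = leaf, root = root,
             species_index = bb$species_index)
  sb$postorder <- local({
    out <- integer(0)
    rec <- function(w) {
      for (c in sb$children[[w]]) rec(c)
      out[[length(out) + 1L]] <<- w
    }
    rec(sb$root)
    out
  })
  class(sb) <- "sr_backbone"
  sb
}

# Oracle variant for the extra-content invariance check: the root of `bb`
# is forced to carry exactly `pin_mask` (which must contain its lca set).
oracle_unordered_pinned <- function(bb, leaf_syntenies, families, pin_mask,
                                    max_rows = 2e5) {
  ls <- compute_lca_sets(bb, leaf_syntenies, families)
  t <- length(ls$families)
  full <- 2L^t - 1L
  L <- ls$mask
  fixed <- rep(NA_integer_, bb$n)
  candidates <- vector("list", bb$n)
  for (v in seq_len(bb$n)) {
    if (bb$event[v] %in% c("Leaf", "Loss")) { fixed[v] <- L[v]; next }
    extra <- bitwAnd(full, bitwNot(L[v]))
    ebits <- mask_bits(extra)
    candidates[[v]] <- vapply(0:(2L^length(ebits) - 1L), function(p) {
      keep <- as.logical(intToBits(p))[seq_len(length(ebits))]
      bitwOr(L[v], mask_from_bits(ebits[keep]))
    }, integer(1))
  }
  fixed[bb$root] <- pin_mask
  am <- oracle_grid(bb, fixed, candidates, max_rows)
  valid <- rep(TRUE, nrow(am))
  cost <- rep(0, nrow(am))
  for (v in seq_len(bb$n)) {
    if (bb$event[v] %in% c("Leaf", "Loss")) next
    X <- am[, v]
    kids <- bb$children[[v]]
    cl <- am[, kids[1L]]; cr <- am[, kids[2L]]
    valid <- valid & bitwAnd(cl, X) == cl & bitwAnd(cr, X) == cr
    if (bb$event[v] == "Spe")
      cost <- cost + as.integer(cl != X) + as.integer(cr != X)
    else
      cost <- cost + 1 + pmin(as.integer(cl != X), as.integer(cr != X))
  }
  cost[!valid] <- Inf
  min(cost)
}
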