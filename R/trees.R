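#' Rooted trees for syntenies, genes and species
#'
#' Trees are stored as plain nested lists: a node is `list(label, children)`,
#' where `children` is a (possibly empty) list of nodes. Leaves carry a label;
#' internal nodes may be unlabeled. This representation handles the partially
#' binary trees (unary loss nodes) that arise in duplication-loss histories,
#' which `ape`'s `phylo` matrices are not designed for. Conversion from
#' `phylo` and from Newick text (parsed by \pkg{ape}) is provided.
#'
#' @param label leaf label (character scalar) or `NULL`.
#' @param children list of child nodes.
#' @return `sr_tree_node()` and `sr_tree_leaf()` return a tree node.
#' @name sr-trees
NULL

#' @rdname sr-trees
#' @export
sr_tree_node <- function(children, label = NULL) {
  structure(list(label = label, children = children), class = "sr_tree")
}

#' @rdname sr-trees
#' @export
sr_tree_leaf <- function(label) sr_tree_node(list(), label = label)

tree_is_leaf <- function(x) length(x$children) == 0L

#' @rdname sr-trees
#' @param x a tree-like object: an `sr_tree`, an `ape::phylo`, or a Newick
#'   string.
#' @export
as_sr_tree <- function(x) UseMethod("as_sr_tree")

#' @export
as_sr_tree.sr_tree <- function(x) x

#' @export
as_sr_tree.phylo <- function(x) {
  ntip <- length(x$tip.label)
  kids <- split(x$edge[, 2], x$edge[, 1])
  build <- function(i) {
    if (i <= ntip) return(sr_tree_leaf(x$tip.label[i]))
    sr_tree_node(lapply(kids[[as.character(i)]], build))
  }
  suppress_unary(build(ntip + 1L))
}

#' @export
as_sr_tree.character <- function(x) {
  phy <- ape::read.tree(text = x)
  if (is.null(phy)) stop_superrec("superrec_parse_error",
                                  "cannot parse Newick string")
  as_sr_tree(phy)
}

#' @export
print.sr_tree <- function(x, ...) {
  cat("<sr_tree> ", tree_to_newick(x), "\n", sep = "")
  invisible(x)
}

# Leaf labels, left-to-right.
tree_leaves <- function(t) {
  if (tree_is_leaf(t)) return(t$label)
  unlist(lapply(t$children, tree_leaves), use.names = FALSE)
}

tree_n_nodes <- function(t) {
  1L + sum(vapply(t$children, tree_n_nodes, integer(1)))
}

tree_is_binary <- function(t) {
  if (tree_is_leaf(t)) return(TRUE)
  length(t$children) == 2L && all(vapply(t$children, tree_is_binary, logical(1)))
}

# Collapse unary internal nodes (keeps leaf labels).
suppress_unary <- function(t) {
  if (tree_is_leaf(t)) return(t)
  if (length(t$children) == 1L) return(suppress_unary(t$children[[1L]]))
  sr_tree_node(lapply(t$children, suppress_unary), label = t$label)
}

#' Serialize a tree to Newick
#'
#' Plain Newick with unquoted labels and no branch lengths, the dialect the
#' package reads and writes everywhere.
#'
#' @param t an `sr_tree`.
#' @return a character scalar ending in `";"`.
#' @export
tree_to_newick <- function(t) {
  rec <- function(n) {
    if (tree_is_leaf(n)) return(n$label)
    paste0("(", paste(vapply(n$children, rec, character(1)), collapse = ","),
           ")", n$label %||% "")
  }
  # a bare leaf is written "(x);" so that standard parsers accept it
  if (tree_is_leaf(t)) return(paste0("(", t$label, ");"))
  paste0(rec(t), ";")
}

# Canonical form: children sorted by their canonical strings, so two trees
# are label-isomorphic iff their canonical strings are equal (deterministic
# tie-break of the isomorphism check).
tree_canonical <- function(t) {
  if (tree_is_leaf(t)) return(t$label)
  kids <- sort(vapply(t$children, tree_canonical, character(1)))
  paste0("(", paste(kids, collapse = ","), ")")
}

# Restriction T|_L: subtree spanned by the leaves in `keep`, unary nodes
# suppressed. Returns NULL if no leaf of `keep` is present.
tree_restrict <- function(t, keep) {
  if (tree_is_leaf(t)) {
    if (t$label %in% keep) return(t)
    return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(t$children, tree_restrict, keep = keep))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  sr_tree_node(kids)
}

# Does `t` display `sub` (restriction label-isomorphic to `sub`)?
tree_displays <- function(t, sub) {
  lv <- tree_leaves(sub)
  if (!all(lv %in% tree_leaves(t))) return(FALSE)
  r <- tree_restrict(t, lv)
  identical(tree_canonical(r), tree_canonical(sub))
}

#' All rooted binary topologies on a label set
#'
#' Recursive leaf insertion, producing all `(2n-3)!!` rooted binary trees.
#' Used as the exhaustive topology oracle behind the supertree enumeration;
#' practical only for small `n`.
#'
#' @param labels character vector of leaf labels.
#' @return a list of `sr_tree` objects.
#' @export
all_binary_topologies <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) return(list())
  acc <- list(sr_tree_leaf(labels[1L]))
  for (lab in labels[-1L]) {
    leaf <- sr_tree_leaf(lab)
    insert_all <- function(t) {
      res <- list(sr_tree_node(list(leaf, t)))
      if (!tree_is_leaf(t)) {
        for (i in seq_along(t$children)) {
          for (sub in insert_all(t$children[[i]])) {
            t2 <- t
            t2$children[[i]] <- sub
            res <- c(res, list(t2))
          }
        }
      }
      res
    }
    acc <- unlist(lapply(acc, insert_all), recursive = FALSE)
  }
  acc
}

# Flat index of a tree: preorder ids, parent/children arrays, labels, depth.
# Internal nodes of species trees get deterministic "anc<i>" labels when
# unlabeled, so event logs can name every species.
index_tree <- function(t, autolabel = FALSE) {
  n <- tree_n_nodes(t)
  parent <- integer(n); depth <- integer(n)
  label <- character(n); is_leaf <- logical(n)
  children <- vector("list", n)
  k <- 0L
  walk <- function(node, par, dep) {
    k <<- k + 1L
    id <- k
    parent[id] <<- par; depth[id] <<- dep
    is_leaf[id] <<- tree_is_leaf(node)
    label[id] <<- if (!is.null(node$label)) node$label
                  else if (autolabel) paste0("anc", id) else NA_character_
    children[[id]] <<- integer(0)
    for (ch in node$children) {
      cid <- walk(ch, id, dep + 1L)
      children[[id]] <<- c(children[[id]], cid)
    }
    id
  }
  walk(t, 0L, 0L)
  leaf_id <- stats::setNames(which(is_leaf), label[is_leaf])
  list(n = n, parent = parent, children = children, depth = depth,
       label = label, is_leaf = is_leaf, leaf_id = leaf_id, root = 1L,
       tree = t)
}

# Postorder node ids of an indexed tree.
index_postorder <- function(idx) {
  out <- integer(0)
  rec <- function(v) {
    for (c in idx$children[[v]]) rec(c)
    out[[length(out) + 1L]] <<- v
  }
  rec(idx$root)
  out
}

# LCA of two node ids in an indexed tree, by walking up the deeper node.
index_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else a <- idx$parent[a]
  }
  a
}

# Is `a` an ancestor of (or equal to) `b`?
index_is_anc <- function(idx, a, b) {
  while (b != 0L && idx$depth[b] >= idx$depth[a]) {
    if (b == a) return(TRUE)
    b <- idx$parent[b]
  }
  FALSE
}

# Path of node ids from `top` down to `bottom` (inclusive); `top` must be an
# ancestor of `bottom`.
index_path_down <- function(idx, top, bottom) {
  path <- bottom
  while (bottom != top) {
    bottom <- idx$parent[bottom]
    path <- c(bottom, path)
  }
  path
}

# Sibling of `v` (other child of its parent); 0 if root or parent unary.
index_sibling <- function(idx, v) {
  p <- idx$parent[v]
  if (p == 0L) return(0L)
  sib <- setdiff(idx$children[[p]], v)
  if (length(sib) == 1L) sib else 0L
}
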