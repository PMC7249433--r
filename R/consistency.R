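#' Precedence graph of a synteny set
#'
#' Directed graph on gene families with an edge `(i, j)` whenever some
#' synteny places a family-`i` gene anywhere before a family-`j` gene (all
#' ordered pairs, not only adjacencies). A set of syntenies can descend from
#' a single ancestral gene order through losses iff this graph is acyclic,
#' and then every topological sort of it is a candidate ancestral synteny.
#'
#' @param syn an `sr_syntenies` object, or a list of ordered family vectors.
#' @return an \pkg{igraph} directed graph whose vertices are the families.
#' @export
build_precedence_graph <- function(syn) {
  orders <- if (inherits(syn, "sr_syntenies")) synteny_orders(syn) else syn
  fams <- sort(unique(unlist(orders, use.names = FALSE)))
  edges <- character(0)
  for (o in orders) {
    k <- length(o)
    if (k < 2L) next
    for (i in seq_len(k - 1L))
      for (j in seq.int(i + 1L, k))
        edges <- c(edges, o[i], o[j])
  }
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(fams)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Is a synteny set order consistent?
#'
#' @param g a precedence graph from [build_precedence_graph()] (or an
#'   `sr_syntenies` object, converted on the fly).
#' @return `TRUE` iff the precedence graph is acyclic.
#' @export
is_order_consistent <- function(g) {
  if (inherits(g, "sr_syntenies")) g <- build_precedence_graph(g)
  igraph::is_dag(g)
}

#' Enumerate candidate ancestral gene orders
#'
#' All topological sorts of the precedence graph, each of which contains
#' every input synteny as a subsequence. Enumeration is depth-first with
#' sources tried in alphabetical order, so the output order is
#' deterministic; when more than `limit` sorts exist, the first `limit` are
#' returned with a warning and attribute `truncated = TRUE` (exact counting
#' is intractable in general).
#'
#' @inheritParams is_order_consistent
#' @param limit maximum number of orders to emit.
#' @return a list of character vectors (orders over all families), with
#'   attribute `truncated`.
#' @export
enumerate_ancestral_orders <- function(g, limit = 10000L) {
  if (inherits(g, "sr_syntenies")) g <- build_precedence_graph(g)
  if (!igraph::is_dag(g))
    stop_superrec("superrec_order_inconsistent",
                  "precedence graph is cyclic: no ancestral order exists")
  fams <- sort(igraph::V(g)$name)
  # adjacency and indegrees over family names
  adj <- lapply(fams, function(f)
    igraph::V(g)$name[igraph::neighbors(g, f, mode = "out")])
  names(adj) <- fams
  indeg <- stats::setNames(igraph::degree(g, fams, mode = "in"), fams)
  out <- list()
  truncated <- FALSE
  rec <- function(prefix, indeg) {
    if (truncated) return()
    if (length(prefix) == length(fams)) {
      if (length(out) >= limit) { truncated <<- TRUE; return() }
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    sources <- names(indeg)[indeg == 0L]
    for (s in sources) {
      nd <- indeg[names(indeg) != s]
      succ <- intersect(adj[[s]], names(nd))
      nd[succ] <- nd[succ] - 1L
      rec(c(prefix, s), nd)
      if (truncated) return()
    }
  }
  rec(character(0), indeg)
  if (truncated)
    warning(sprintf("ancestral order enumeration truncated at %d", limit))
  attr(out, "truncated") <- truncated
  out
}

## ---- Tree consistency and supertrees ---------------------------------------

# All resolved rooted triplets of a binary tree, as "a,b|c" strings with
# {a,b} sorted and the cherry pair being the one whose LCA is deepest.
tree_triplets <- function(t) {
  idx <- index_tree(t)
  lv <- which(idx$is_leaf)
  if (length(lv) < 3L) return(character(0))
  out <- character(0)
  for (comb in utils::combn(lv, 3L, simplify = FALSE)) {
    a <- comb[1L]; b <- comb[2L]; c <- comb[3L]
    lab <- idx$label[c(a, b, c)]
    l_ab <- index_lca(idx, a, b)
    l_ac <- index_lca(idx, a, c)
    l_bc <- index_lca(idx, b, c)
    pair <- if (idx$depth[l_ab] > idx$depth[l_ac]) c(1L, 2L)
            else if (idx$depth[l_ac] > idx$depth[l_ab]) c(1L, 3L)
            else if (idx$depth[l_bc] > idx$depth[l_ab]) c(2L, 3L)
            else next  # unresolved (non-binary input)
    out <- c(out, paste0(paste(sort(lab[pair]), collapse = ","), "|",
                         lab[setdiff(1:3, pair)]))
  }
  unique(out)
}

#' Are a set of synteny trees triplet consistent?
#'
#' Pairwise condition: for every 3-subset of leaves shared by two or more
#' trees, all trees containing it display the same rooted triplet. This is
#' necessary for a Super-Reconciliation to exist.
#'
#' @param trees list of rooted binary `sr_tree` objects.
#' @return `TRUE` or `FALSE`.
#' @export
triplet_consistent <- function(trees) {
  if (length(trees) < 2L) return(TRUE)
  trips <- lapply(trees, tree_triplets)
  # index triplets by their unordered leaf 3-set
  set_key <- function(s) {
    parts <- strsplit(sub("\\|", ",", s), ",")[[1L]]
    paste(sort(parts), collapse = ";")
  }
  seen <- list()
  for (tx in trips) {
    for (s in tx) {
      k <- set_key(s)
      if (!is.null(seen[[k]]) && seen[[k]] != s) return(FALSE)
      seen[[k]] <- s
    }
  }
  TRUE
}

#' Supertree of a set of rooted trees (BUILD)
#'
#' The classical recursive algorithm on rooted triplets: at each step the
#' leaves are clustered by connecting the cherry pair of every triplet whose
#' out-taxon is present; a single cluster over two or more leaves means the
#' trees are incompatible. On success the returned tree displays every
#' input tree; it is minimally resolved and may contain multifurcations.
#'
#' @param trees list of rooted `sr_tree` objects with overlapping leaf sets.
#' @return an `sr_tree`, or an error of class `superrec_tree_inconsistent`
#'   when no common supertree exists.
#' @export
build_supertree <- function(trees) {
  if (length(trees) == 1L) return(trees[[1L]])
  leaves <- sort(unique(unlist(lapply(trees, tree_leaves))))
  trips <- unique(unlist(lapply(trees, tree_triplets)))
  parsed <- lapply(strsplit(trips, "[,|]"), identity)  # a, b, out
  rec <- function(L) {
    if (length(L) == 1L) return(sr_tree_leaf(L))
    if (length(L) == 2L) return(sr_tree_node(lapply(sort(L), sr_tree_leaf)))
    active <- Filter(function(p) all(p %in% L), parsed)
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(sort(L))
    if (length(active)) {
      e <- unlist(lapply(active, function(p) p[1:2]))
      g <- igraph::simplify(igraph::add_edges(g, e))
    }
    comp <- igraph::components(g)
    if (comp$no < 2L)
      stop_superrec("superrec_tree_inconsistent",
                    "input trees are incompatible: no supertree exists")
    groups <- split(igraph::V(g)$name, comp$membership)
    groups <- groups[order(vapply(groups, min, character(1)))]
    sr_tree_node(lapply(groups, rec))
  }
  rec(leaves)
}

#' Enumerate binary supertrees
#'
#' All rooted binary topologies on the union of the input leaf sets that
#' display every input tree, by exhaustive generation filtered through the
#' display test — exact and oracle-grade, but limited to small leaf sets
#' (at most `max_leaves`). Emission order is deterministic (lexicographic on
#' canonical Newick); at most `limit` trees are returned, with attribute
#' `truncated` set when the list was cut.
#'
#' @param trees list of rooted `sr_tree` objects (may be empty, in which
#'   case `leaves` must be given).
#' @param limit maximum number of supertrees to return.
#' @param leaves optional character vector of leaf labels (defaults to the
#'   union over the trees).
#' @param max_leaves guard on the exhaustive generation.
#' @return list of binary `sr_tree` objects with attribute `truncated`.
#' @export
enumerate_binary_supertrees <- function(trees, limit = 10000L, leaves = NULL,
                                        max_leaves = 8L) {
  leaves <- leaves %||% sort(unique(unlist(lapply(trees, tree_leaves))))
  if (length(leaves) == 0L)
    stop_superrec("superrec_tree_inconsistent", "no leaves to build on")
  if (length(leaves) > max_leaves)
    stop_superrec("superrec_resource",
                  sprintf("exhaustive supertree enumeration refused for %d > %d leaves",
                          length(leaves), max_leaves))
  # fail early (and with the right error class) on incompatible inputs
  if (length(trees) >= 1L) build_supertree(trees)
  cands <- all_binary_topologies(leaves)
  ok <- vapply(cands, function(tt)
    all(vapply(trees, function(s) tree_displays(tt, s), logical(1))),
    logical(1))
  found <- cands[ok]
  key <- vapply(found, tree_canonical, character(1))
  found <- found[!duplicated(key)]
  found <- found[order(vapply(found, tree_canonical, character(1)))]
  truncated <- length(found) > limit
  if (truncated) {
    warning(sprintf("supertree enumeration truncated at %d", limit))
    found <- found[seq_len(limit)]
  }
  attr(found, "truncated") <- truncated
  found
}
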