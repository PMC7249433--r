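#' Gene-family content below every backbone node
#'
#' Bottom-up union of the leaf contents: `lca_set(v)` is the set of families
#' appearing in some extant synteny below `v` (full-loss leaves contribute
#' the empty set). Any valid content assignment at `v` must contain it.
#'
#' @param bb an `sr_backbone`.
#' @param leaf_syntenies named list: synteny id -> family vector.
#' @param families character vector of all family ids (the universe); by
#'   default the sorted union over the leaves.
#' @return a list with `families` and `mask` (integer vector of bitmasks
#'   over `families`, one per backbone node).
#' @export
compute_lca_sets <- function(bb, leaf_syntenies, families = NULL) {
  if (is.null(families))
    families <- sort(unique(unlist(leaf_syntenies, use.names = FALSE)))
  L <- integer(bb$n)
  for (v in bb$postorder) {
    if (bb$event[v] == "Leaf") {
      pos <- match(leaf_syntenies[[bb$leaf[v]]], families)
      if (anyNA(pos))
        stop_superrec("superrec_family_mismatch",
                      "leaf synteny contains an unknown family")
      L[v] <- mask_from_bits(pos)
    } else if (bb$event[v] == "Loss") {
      L[v] <- 0L
    } else {
      L[v] <- Reduce(bitwOr, L[bb$children[[v]]])
    }
  }
  list(families = families, mask = L)
}

#' Minimum-cost Unordered Super-Reconciliation on a backbone
#'
#' Polynomial-time dynamic program over gene contents (orders are ignored:
#' rearrangements are free and only segmental duplications and losses are
#' counted). Since a single partial loss can remove an arbitrary subset of
#' families when order is irrelevant, at most one loss is ever needed per
#' edge, and the exact extra content assigned to a node beyond its
#' `lca_set` does not affect the cost — only whether there is any. Each node
#' therefore carries two values: `C_lca(v)`, the optimal loss cost of the
#' subtree when `v` is assigned exactly `lca_set(v)`, and `C_star(v)`, the
#' optimal cost when `v` is assigned any strict superset.
#'
#' For an internal node with children `v1, v2` and `spec(v) = 1` for a
#' speciation, 0 for a duplication (a duplication can shed content on its
#' copy side for free):
#' \deqn{C^*(v) = \min\{C_{lca}(v_1)+C_{lca}(v_2)+1+spec(v),\;
#'   C^*(v_1)+C_{lca}(v_2)+spec(v),\; C_{lca}(v_1)+C^*(v_2)+spec(v),\;
#'   C^*(v_1)+C^*(v_2)\}.}
#' `C_lca(v)` follows the same case analysis, except that a child whose
#' content already equals the parent's needs no loss, and a duplication may
#' absorb the reduction of one child into the partial copy. The root is
#' assigned the full family set; the total cost adds one per duplication
#' node and one per grafted full-loss leaf (reached by losing everything on
#' its edge).
#'
#' @inheritParams compute_lca_sets
#' @return a list with `cost` (Dup + fLoss + pLoss events), `assignment`
#'   (list: backbone node id -> character vector of families), `events`
#'   (data.frame of loss events: child node id, event `pLoss`/`fLoss`, lost
#'   families), and the per-node `C_lca`/`C_star` tables.
#' @export
usr_min_cost <- function(bb, leaf_syntenies, families = NULL) {
  ls <- compute_lca_sets(bb, leaf_syntenies, families)
  L <- ls$mask
  fams <- ls$families
  C_lca <- numeric(bb$n)
  C_star <- numeric(bb$n)
  for (v in bb$postorder) {
    evt <- bb$event[v]
    if (evt %in% c("Leaf", "Loss")) {
      C_lca[v] <- 0
      C_star[v] <- Inf
      next
    }
    kids <- bb$children[[v]]
    c1 <- kids[1L]; c2 <- kids[2L]
    needs <- L[kids] != L[v]
    x <- C_lca[kids] + as.integer(needs)        # child at its lca, loss if needed
    y <- ifelse(needs, C_star[kids], Inf)        # child inherits the parent set
    spec <- as.integer(evt == "Spe")
    if (evt == "Spe") {
      C_lca[v] <- min(x[1L], y[1L]) + min(x[2L], y[2L])
    } else {
      # one child may be the partial copy: its reduction to lca is free
      C_lca[v] <- min(min(C_lca[c1], y[1L]) + min(x[2L], y[2L]),
                      min(x[1L], y[1L]) + min(C_lca[c2], y[2L]))
    }
    C_star[v] <- min(C_lca[c1] + C_lca[c2] + 1 + spec,
                     C_star[c1] + C_lca[c2] + spec,
                     C_lca[c1] + C_star[c2] + spec,
                     C_star[c1] + C_star[c2])
  }
  n_dup <- sum(bb$event == "Dup")
  # the root carries the full family set; when some family of the universe
  # has no extant gene the root holds strictly more than its lca set, and
  # by the extra-content invariance that cost is C_star(root)
  full <- mask_from_bits(seq_along(fams))
  root_loss <- if (L[bb$root] == full) C_lca[bb$root] else C_star[bb$root]
  cost <- n_dup + root_loss
  res <- backtrack_usr(bb, L, fams, C_lca, C_star, full)
  list(cost = as.integer(cost), assignment = res$assignment,
       events = res$events, C_lca = C_lca, C_star = C_star,
       families = fams, lca_mask = L)
}

backtrack_usr <- function(bb, L, fams, C_lca, C_star, full) {
  assignment <- vector("list", bb$n)
  events <- list()
  set_of <- function(m) fams[mask_bits(m)]
  add_loss <- function(child, from, to) {
    lost <- bitwAnd(from, bitwNot(to))
    events[[length(events) + 1L]] <<- data.frame(
      node_id = child,
      event = if (to == 0L && bb$event[child] == "Loss") "fLoss" else "pLoss",
      lost = paste(set_of(lost), collapse = "|"),
      stringsAsFactors = FALSE)
  }
  # descend(v, X): v is assigned content X (== L[v] for the lca state, a
  # strict superset for the star state)
  descend <- function(v, X) {
    assignment[[v]] <<- set_of(X)
    evt <- bb$event[v]
    if (evt %in% c("Leaf", "Loss")) return(invisible())
    kids <- bb$children[[v]]
    spec <- evt == "Spe"
    if (X == L[v]) {
      needs <- L[kids] != X
      x <- C_lca[kids] + as.integer(needs)
      y <- ifelse(needs, C_star[kids], Inf)
      free <- c(FALSE, FALSE)  # which child's reduction is absorbed by the copy
      if (!spec) {
        o1 <- min(C_lca[kids[1L]], y[1L]) + min(x[2L], y[2L])
        o2 <- min(x[1L], y[1L]) + min(C_lca[kids[2L]], y[2L])
        if (o1 <= o2) free[1L] <- TRUE else free[2L] <- TRUE
      }
      for (i in 1:2) {
        c <- kids[i]
        xi <- if (free[i]) C_lca[c] else x[i]
        if (xi <= y[i]) {  # ties prefer the smaller (lca) assignment
          if (needs[i] && !free[i]) add_loss(c, X, L[c])
          descend(c, L[c])
        } else {
          descend(c, X)
        }
      }
    } else {
      c1 <- kids[1L]; c2 <- kids[2L]
      sp <- as.integer(spec)
      opts <- c(C_lca[c1] + C_lca[c2] + 1 + sp,
                C_star[c1] + C_lca[c2] + sp,
                C_lca[c1] + C_star[c2] + sp,
                C_star[c1] + C_star[c2])
      case <- which.min(opts)  # first minimum: prefer lca assignments
      if (case == 1L) {
        # both children shrink to lca; a duplication's copy side is free
        if (spec) { add_loss(c1, X, L[c1]); add_loss(c2, X, L[c2]) }
        else add_loss(c2, X, L[c2])
        descend(c1, L[c1]); descend(c2, L[c2])
      } else if (case == 2L) {
        if (spec) add_loss(c2, X, L[c2])
        descend(c1, X); descend(c2, L[c2])
      } else if (case == 3L) {
        if (spec) add_loss(c1, X, L[c1])
        descend(c1, L[c1]); descend(c2, X)
      } else {
        descend(c1, X); descend(c2, X)
      }
    }
  }
  descend(bb$root, full)
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(node_id = integer(0), event = character(0),
                        lost = character(0), stringsAsFactors = FALSE)
  list(assignment = assignment, events = ev)
}
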