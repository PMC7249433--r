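## ---- Brute-force machinery (test ground truth) -----------------------------

# Independent loss distances on bitmasks, by explicit search over sequences
# of single-interval removals (an interval is a run of consecutive set bits
# of the *current* mask). dt[X+1, Y+1] = minimum removals turning X into its
# submask Y; dp[X+1, Y+1] additionally lets X first be cut to any contiguous
# substring for free (the duplicated segment), with the convention that
# reaching the empty synteny still costs one loss.
brute_loss_tables <- function(t) {
  nm <- 2L^t
  dt <- matrix(NA_real_, nm, nm)
  segments_of <- function(bits) {
    # all contiguous (in the current sequence) non-empty subsets of bits
    segs <- list()
    k <- length(bits)
    for (i in seq_len(k)) for (j in i:k)
      segs[[length(segs) + 1L]] <- mask_from_bits(bits[i:j])
    segs
  }
  rec_dt <- function(X, Y) {
    if (!is.na(dt[X + 1L, Y + 1L])) return(dt[X + 1L, Y + 1L])
    if (X == Y) { dt[X + 1L, Y + 1L] <<- 0; return(0) }
    best <- Inf
    for (s in segments_of(mask_bits(X))) {
      if (bitwAnd(s, Y) != 0L) next  # cannot remove kept genes
      best <- min(best, 1 + rec_dt(bitwAnd(X, bitwNot(s)), Y))
    }
    dt[X + 1L, Y + 1L] <<- best
    best
  }
  dpm <- matrix(NA_real_, nm, nm)
  for (X in 0:(nm - 1L)) {
    bx <- mask_bits(X)
    for (Y in 0:(nm - 1L)) {
      if (bitwAnd(X, Y) != Y) next
      rec_dt(X, Y)
      # substrings of X (contiguous bit runs), non-empty
      best <- Inf
      for (s in segments_of(bx)) {
        if (bitwAnd(s, Y) != Y) next  # substring must contain Y
        best <- min(best, rec_dt(s, Y))
      }
      if (Y == 0L && X == 0L) best <- 0
      dpm[X + 1L, Y + 1L] <- best
    }
  }
  list(dt = dt, dp = dpm)
}

# All valid mask assignments for the free (internal, non-root) nodes of a
# backbone, as an expand.grid data frame, plus fixed columns for leaves,
# loss leaves and the root. Returns NULL when the grid exceeds max_rows.
oracle_grid <- function(bb, fixed, candidates, max_rows) {
  free <- which(is.na(fixed))
  sizes <- vapply(candidates[free], length, integer(1))
  if (prod(c(1, sizes)) > max_rows)
    stop_superrec("superrec_resource",
                  sprintf("oracle grid of %g rows exceeds guard %g",
                          prod(c(1, sizes)), max_rows))
  grid <- if (length(free) == 0L) data.frame(row.names = 1L)
          else do.call(expand.grid, c(stats::setNames(candidates[free],
                                                      paste0("v", free)),
                                      list(KEEP.OUT.ATTRS = FALSE)))
  assign_mat <- matrix(0L, nrow = max(1L, nrow(grid)), ncol = bb$n)
  for (v in seq_len(bb$n))
    assign_mat[, v] <- if (is.na(fixed[v])) grid[[paste0("v", v)]]
                       else fixed[v]
  assign_mat
}

#' Brute-force minimum ordered Super-Reconciliation cost
#'
#' Ground-truth oracle: enumerates every valid synteny assignment
#' (subsequences of the root order at internal nodes, extant syntenies at
#' leaves, the empty synteny at full-loss leaves, the full order at the
#' root) and counts events per edge with loss distances obtained by explicit
#' search over interval-removal sequences — fully independent of the
#' dynamic-programming recurrences. Guarded to small instances.
#'
#' @param bb an `sr_backbone`.
#' @param A ancestral order (character vector of families).
#' @param leaf_syntenies named list: synteny id -> family vector.
#' @param max_rows refuse instances whose assignment grid exceeds this.
#' @param tables precomputed brute-force distance tables (internal
#'   `brute_loss_tables()` result), to share across repeated calls.
#' @return the minimum cost (numeric; `Inf` when no valid assignment).
#' @export
oracle_ordered <- function(bb, A, leaf_syntenies, max_rows = 3e5,
                           tables = NULL) {
  t <- length(A)
  if (t > 6L)
    stop_superrec("superrec_resource",
                  sprintf("ordered oracle refused for t = %d families", t))
  nm <- 2L^t
  full <- nm - 1L
  tabs <- tables %||% brute_loss_tables(t)
  fixed <- rep(NA_integer_, bb$n)
  for (v in seq_len(bb$n)) {
    if (bb$event[v] == "Leaf")
      fixed[v] <- synteny_mask(leaf_syntenies[[bb$leaf[v]]], A)
    else if (bb$event[v] == "Loss") fixed[v] <- 0L
  }
  if (bb$event[bb$root] == "Leaf") {
    # single-leaf backbone: the pLoss chain from A to the extant synteny
    return(tabs$dt[full + 1L, fixed[bb$root] + 1L])
  }
  fixed[bb$root] <- full
  candidates <- rep(list(1:full), bb$n)  # non-empty submasks of A
  am <- oracle_grid(bb, fixed, candidates, max_rows)
  valid <- rep(TRUE, nrow(am))
  cost <- rep(0, nrow(am))
  for (v in seq_len(bb$n)) {
    if (bb$event[v] %in% c("Leaf", "Loss")) next
    X <- am[, v]
    kids <- bb$children[[v]]
    cl <- am[, kids[1L]]; cr <- am[, kids[2L]]
    valid <- valid & bitwAnd(cl, X) == cl & bitwAnd(cr, X) == cr
    if (bb$event[v] == "Spe") {
      cost <- cost + tabs$dt[cbind(X + 1L, cl + 1L)] +
        tabs$dt[cbind(X + 1L, cr + 1L)]
    } else {
      cost <- cost + 1 +
        pmin(tabs$dt[cbind(X + 1L, cl + 1L)] + tabs$dp[cbind(X + 1L, cr + 1L)],
             tabs$dp[cbind(X + 1L, cl + 1L)] + tabs$dt[cbind(X + 1L, cr + 1L)])
    }
  }
  cost[!valid | is.na(cost)] <- Inf
  min(cost)
}

#' Brute-force minimum Unordered Super-Reconciliation cost
#'
#' Enumerates every per-node gene-content assignment between `lca_set(v)`
#' and the full family set (respecting containment along edges, full set at
#' the root), counting one event per duplication node, one loss per edge
#' that strictly shrinks under a speciation, and one loss for the
#' non-copy-side shrink of a duplication (the copy side shrinks for free).
#'
#' @inheritParams oracle_ordered
#' @param families all family ids (defaults to the union over the leaves).
#' @return the minimum cost (numeric).
#' @export
oracle_unordered <- function(bb, leaf_syntenies, families = NULL,
                             max_rows = 3e5) {
  ls <- compute_lca_sets(bb, leaf_syntenies, families)
  t <- length(ls$families)
  if (t > 6L)
    stop_superrec("superrec_resource",
                  sprintf("unordered oracle refused for %d families", t))
  full <- 2L^t - 1L
  L <- ls$mask
  fixed <- rep(NA_integer_, bb$n)
  candidates <- vector("list", bb$n)
  for (v in seq_len(bb$n)) {
    if (bb$event[v] %in% c("Leaf", "Loss")) { fixed[v] <- L[v]; next }
    extra <- bitwAnd(full, bitwNot(L[v]))
    ebits <- mask_bits(extra)
    sup <- vapply(0:(2L^length(ebits) - 1L), function(p) {
      keep <- as.logical(intToBits(p))[seq_len(length(ebits))]
      bitwOr(L[v], mask_from_bits(ebits[keep]))
    }, integer(1))
    candidates[[v]] <- sup
  }
  fixed[bb$root] <- full
  am <- oracle_grid(bb, fixed, candidates, max_rows)
  valid <- rep(TRUE, nrow(am))
  cost <- rep(0, nrow(am))
  for (v in seq_len(bb$n)) {
    if (bb$event[v] %in% c("Leaf", "Loss")) next
    X <- am[, v]
    kids <- bb$children[[v]]
    cl <- am[, kids[1L]]; cr <- am[, kids[2L]]
    valid <- valid & bitwAnd(cl, X) == cl & bitwAnd(cr, X) == cr
    shrink_l <- as.integer(cl != X)
    shrink_r <- as.integer(cr != X)
    if (bb$event[v] == "Spe") cost <- cost + shrink_l + shrink_r
    else cost <- cost + 1 + pmin(shrink_l, shrink_r)
  }
  cost[!valid] <- Inf
  min(cost)
}

## ---- The four-step framework -----------------------------------------------

#' Infer minimum-cost Super-Reconciliations
#'
#' The full inference pipeline: check gene-order consistency (ordered mode)
#' and tree consistency, enumerate candidate ancestral gene orders and
#' binary supertrees of the synteny trees, run the exact dynamic program on
#' every (order, supertree) pair — or the polynomial unordered program once
#' per supertree — and keep every optimum found.
#'
#' Supertree enumeration is exhaustive and therefore restricted to small
#' leaf sets; for larger instances pass the backbone topology explicitly via
#' `supertree` (e.g., the true tree of a simulation, or a supertree obtained
#' elsewhere).
#'
#' @param species_tree rooted binary `sr_tree` (or anything
#'   [as_sr_tree()] accepts).
#' @param gene_trees list of rooted binary gene trees, one per family.
#' @param syn an `sr_syntenies` object.
#' @param mode `"ordered"` (exact, exponential in the family count) or
#'   `"unordered"` (gene contents only, polynomial).
#' @param max_orders,max_supertrees,max_optima enumeration caps.
#' @param supertree optional binary `sr_tree` on the synteny ids to use as
#'   the single backbone (skips supertree enumeration).
#' @return an `sr_result` list: `cost`, `optima` (list of records with
#'   `order`, `supertree`, and for the ordered mode an `sr_history`, for the
#'   unordered mode the content `assignment` and loss `events`),
#'   `mode`, counts of orders/supertrees explored, and truncation flags.
#' @export
super_reconcile <- function(species_tree, gene_trees, syn,
                            mode = c("ordered", "unordered"),
                            max_orders = 10000L, max_supertrees = 10000L,
                            max_optima = 100L, supertree = NULL) {
  mode <- match.arg(mode)
  species_tree <- as_sr_tree(species_tree)
  check_species_tree(species_tree)
  validate_instance(species_tree, gene_trees, syn)
  sidx <- index_tree(species_tree, autolabel = TRUE)
  g2s <- gene_synteny_map(syn)
  syn_trees <- lapply(gene_trees, synteny_tree_of, gene_to_synteny = g2s)
  leaf_syntenies <- synteny_orders(syn)
  leaf_species <- synteny_species(syn)
  families <- syn$families

  orders <- if (mode == "ordered") {
    pg <- build_precedence_graph(syn)
    if (!is_order_consistent(pg))
      stop_superrec("superrec_order_inconsistent",
                    "gene orders are inconsistent: no ordered Super-Reconciliation exists")
    enumerate_ancestral_orders(pg, limit = max_orders)
  } else list(NULL)

  if (is.null(supertree)) {
    supertrees <- enumerate_binary_supertrees(syn_trees,
                                              limit = max_supertrees,
                                              leaves = names(syn$syntenies))
  } else {
    supertrees <- list(as_sr_tree(supertree))
    attr(supertrees, "truncated") <- FALSE
  }

  best <- Inf
  optima <- list()
  opt_keys <- character(0)
  optima_truncated <- FALSE
  for (st in supertrees) {
    bb <- build_backbone(st, leaf_species, sidx)
    for (A in orders) {
      if (mode == "ordered") {
        fit <- small_phylogeny_ordered(bb, A, leaf_syntenies)
        rec <- list(order = A, supertree = st, history = fit$history,
                    cost = fit$cost)
        key <- if (is.null(fit$history)) "" else history_to_newick(fit$history)
      } else {
        fit <- usr_min_cost(bb, leaf_syntenies, families)
        rec <- list(order = NULL, supertree = st,
                    assignment = fit$assignment, events = fit$events,
                    cost = fit$cost)
        key <- paste(tree_canonical(st),
                     paste(vapply(fit$assignment, paste, character(1),
                                  collapse = "|"), collapse = ";"))
      }
      if (!is.finite(rec$cost)) next
      if (rec$cost < best) {
        best <- rec$cost
        optima <- list(rec)
        opt_keys <- key
        optima_truncated <- FALSE
      } else if (rec$cost == best && !(key %in% opt_keys)) {
        if (length(optima) < max_optima) {
          optima <- c(optima, list(rec))
          opt_keys <- c(opt_keys, key)
        } else optima_truncated <- TRUE
      }
    }
  }
  if (!is.finite(best))
    stop_superrec("superrec_tree_inconsistent",
                  "no Super-Reconciliation found for any explored candidate")
  structure(list(cost = as.integer(best), optima = optima, mode = mode,
                 n_orders = length(orders), n_supertrees = length(supertrees),
                 truncated = list(
                   orders = isTRUE(attr(orders, "truncated")),
                   supertrees = isTRUE(attr(supertrees, "truncated")),
                   optima = optima_truncated),
                 species_index = sidx),
            class = "sr_result")
}

#' @export
print.sr_result <- function(x, ...) {
  cat(sprintf("<sr_result> %s mode: minimum cost %d (%d optimal histories;
  %d ancestral orders x %d supertrees explored)\n",
              x$mode, x$cost, length(x$optima), x$n_orders, x$n_supertrees))
  if (any(unlist(x$truncated))) cat("  note: enumeration was truncated\n")
  invisible(x)
}
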