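#' Segmental-loss distances between nested syntenies
#'
#' `loss_dist_total(X, Y)` is the minimum number of segmental losses turning
#' the synteny `X` into its subsequence `Y`: one loss per maximal run of
#' consecutive `X` positions absent from `Y`. `loss_dist_partial(X, Y)` is
#' the minimum number of losses turning some substring of `X` into `Y`: only
#' internal gaps count, because the substring can be chosen to shed the
#' missing prefix and suffix for free. Both are linear-time since all
#' families in a synteny are distinct.
#'
#' Transforming into the empty synteny takes exactly one (full) loss, so
#' `loss_dist_total(X, character(0))` is 1 for non-empty `X`; the partial
#' variant also returns 1 in that case (a duplication must copy at least one
#' gene, which a single loss then removes).
#'
#' @param X,Y character vectors of family identifiers; `Y` must be a
#'   subsequence of `X`.
#' @return a non-negative integer count of segmental losses.
#' @export
loss_dist_total <- function(X, Y) {
  loss_runs(X, Y, internal_only = FALSE)
}

#' @rdname loss_dist_total
#' @export
loss_dist_partial <- function(X, Y) {
  if (length(Y) == 0L) return(if (length(X) == 0L) 0L else 1L)
  loss_runs(X, Y, internal_only = TRUE)
}

loss_runs <- function(X, Y, internal_only) {
  if (length(Y) == 0L) return(if (length(X) == 0L) 0L else 1L)
  pos <- match(Y, X)
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE))
    stop_superrec("superrec_not_subsequence",
                  "Y is not a subsequence of X")
  kept <- logical(length(X))
  kept[pos] <- TRUE
  r <- rle(kept)
  gaps <- which(!r$values)
  if (internal_only)
    gaps <- setdiff(gaps, c(1L, length(r$values)))
  length(gaps)
}

## ---- Bitmask machinery -----------------------------------------------------

# Precomputed tables for syntenies encoded as bitmasks over the positions of
# the root order A (t = |A| families). For each mask X, its submasks are
# enumerated in "pattern" order: pattern p (a popcount(X)-bit integer) keeps
# the i-th set bit of X iff bit i of p is set. Zero-run tables give, for
# every pattern, the number of loss events needed: total runs of dropped
# positions (D^T) or internal runs only (D^P).
mask_tables <- function(t) {
  if (t > 16L)
    stop_superrec("superrec_resource",
                  sprintf("mask tables refused for t = %d families", t), t = t)
  nm <- 2L^t
  bits <- lapply(0:(nm - 1L), mask_bits)
  pop <- lengths(bits)
  runsT <- vector("list", t + 1L)
  runsP <- vector("list", t + 1L)
  for (k in 0:t) {
    np <- 2L^k
    rT <- integer(np); rP <- integer(np)
    for (p in 0:(np - 1L)) {
      if (k == 0L) { rT[p + 1L] <- 0L; rP[p + 1L] <- 0L; next }
      b <- as.integer(intToBits(p))[seq_len(k)]
      r <- rle(b)
      zr <- which(r$values == 0L)
      rT[p + 1L] <- length(zr)
      rP[p + 1L] <- length(setdiff(zr, c(1L, length(r$values))))
    }
    # empty result (pattern 0) still needs one full loss
    rT[1L] <- if (k == 0L) 0L else 1L
    rP[1L] <- if (k == 0L) 0L else 1L
    runsT[[k + 1L]] <- rT
    runsP[[k + 1L]] <- rP
  }
  subs <- vector("list", nm)
  for (X in 0:(nm - 1L)) {
    bx <- bits[[X + 1L]]
    k <- length(bx)
    pats <- 0:(2L^k - 1L)
    if (k == 0L) { subs[[X + 1L]] <- 0L; next }
    m <- vapply(pats, function(p) {
      keep <- as.logical(intToBits(p))[seq_len(k)]
      mask_from_bits(bx[keep])
    }, integer(1))
    subs[[X + 1L]] <- m
  }
  list(t = t, nm = nm, bits = bits, pop = pop,
       subs = subs, runsT = runsT, runsP = runsP)
}

# Mask of a synteny (ordered family vector) over root order A; errors if the
# synteny is not a subsequence of A.
synteny_mask <- function(fams, A) {
  if (length(fams) == 0L) return(0L)
  pos <- match(fams, A)
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE))
    stop_superrec("superrec_order_inconsistent",
                  paste("extant synteny is not a subsequence of the",
                        "ancestral order"))
  mask_from_bits(pos)
}

## ---- The ordered small-phylogeny DP ----------------------------------------

#' Exact ordered Super-Reconciliation on a fixed backbone and root order
#'
#' Dynamic program over valid synteny assignments: every node of the
#' loss-grafted, event-labeled backbone is assigned a subsequence of the
#' ancestral synteny `A` (encoded as a bitmask over positions of `A`), the
#' root is assigned `A` itself, and each node's assignment must be a
#' subsequence of its parent's. A speciation passes its synteny to both
#' children, paying one partial loss per maximal dropped run
#' (`loss_dist_total`); a duplication pays one event plus, on at most one
#' child, the cheaper partial-copy distance (`loss_dist_partial`) that lets
#' the copied substring shed a prefix and suffix for free. A grafted
#' full-loss leaf is reached by assigning the empty synteny, at the price of
#' exactly one loss — the full loss itself.
#'
#' The state space is `O(2^t)` per node (`t` families), which makes the
#' method exponential in `t` but linear in the number of nodes.
#'
#' @param bb an `sr_backbone` from [build_backbone()].
#' @param A character vector: the ancestral synteny (root order) over all
#'   families.
#' @param leaf_syntenies named list: synteny id -> ordered family vector.
#' @param max_states guard on the DP table size (`2^t * n` entries); above
#'   it, a `superrec_resource` error reports the offending `t`.
#' @param backtrack set to `FALSE` to return the cost only (faster when the
#'   history is not needed, e.g. in large sweeps).
#' @param tables precomputed mask tables (internal `mask_tables()` result
#'   for `length(A)` families), to share across repeated calls.
#' @return a list with `cost` (minimum number of Dup + pLoss + fLoss events)
#'   and `history` (an [`sr_history`][new_history] achieving it, or `NULL`
#'   when the cost is infinite or `backtrack` is `FALSE`).
#' @export
small_phylogeny_ordered <- function(bb, A, leaf_syntenies,
                                    max_states = 2^22, backtrack = TRUE,
                                    tables = NULL) {
  t <- length(A)
  if (anyDuplicated(A))
    stop_superrec("superrec_order_inconsistent", "ancestral order has repeats")
  nm <- 2L^t
  if (nm * bb$n > max_states)
    stop_superrec("superrec_resource",
                  sprintf("DP table of %d x %d states exceeds budget (t = %d)",
                          bb$n, nm, t), t = t)
  tbl <- tables %||% mask_tables(t)
  stopifnot(tbl$t == t)
  full <- nm - 1L
  leaf_mask <- integer(bb$n)
  d <- matrix(Inf, nrow = bb$n, ncol = nm)

  best_over_subs <- function(dc, X, runs) {
    subs <- tbl$subs[[X + 1L]]
    k <- tbl$pop[X + 1L]
    min(runs[[k + 1L]] + dc[subs + 1L])
  }

  for (v in bb$postorder) {
    evt <- bb$event[v]
    if (evt == "Leaf") {
      m <- synteny_mask(leaf_syntenies[[bb$leaf[v]]], A)
      if (m == 0L)
        stop_superrec("superrec_invalid_history", "extant leaf with empty synteny")
      leaf_mask[v] <- m
      d[v, m + 1L] <- 0
    } else if (evt == "Loss") {
      # handled on the parent's edge: fixed cost 1 (the full loss)
    } else {
      kids <- bb$children[[v]]
      stopifnot(length(kids) == 2L)
      bt <- matrix(Inf, nrow = 2L, ncol = nm)  # best D^T option per child
      bp <- matrix(Inf, nrow = 2L, ncol = nm)  # best D^P option per child
      for (i in 1:2) {
        c <- kids[i]
        if (bb$event[c] == "Loss") {
          if (evt == "Dup")
            stop_superrec("superrec_invalid_history",
                          "full-loss leaf under a duplication node")
          bt[i, ] <- 1
          next
        }
        dc <- d[c, ]
        for (X in 1:(nm - 1L)) {
          bt[i, X + 1L] <- best_over_subs(dc, X, tbl$runsT)
          if (evt == "Dup")
            bp[i, X + 1L] <- best_over_subs(dc, X, tbl$runsP)
        }
      }
      if (evt == "Spe") {
        d[v, ] <- bt[1L, ] + bt[2L, ]
      } else {
        d[v, ] <- 1 + pmin(bt[1L, ] + bp[2L, ], bp[1L, ] + bt[2L, ])
      }
      d[v, 1L] <- Inf  # the empty synteny is reserved for full-loss leaves
    }
  }

  # a single-leaf backbone: the history is the pLoss chain from A down to
  # the extant synteny (the root still carries A)
  cost <- if (bb$event[bb$root] == "Leaf") {
    tbl$runsT[[t + 1L]][leaf_mask[bb$root] + 1L]
  } else d[bb$root, full + 1L]
  if (!is.finite(cost))
    return(list(cost = Inf, history = NULL))
  hist <- if (backtrack) backtrack_ordered(bb, A, tbl, d, leaf_mask, full)
          else NULL
  list(cost = as.integer(cost), history = hist)
}

# Choose, for child c under parent mask X, the child assignment minimizing
# runs + d; ties broken toward the smallest submask value (reproducibility).
choose_sub <- function(dc, X, runs, tbl) {
  subs <- tbl$subs[[X + 1L]]
  k <- tbl$pop[X + 1L]
  sc <- runs[[k + 1L]] + dc[subs + 1L]
  best <- min(sc)
  cand <- subs[sc == best]
  list(mask = min(cand), cost = best)
}

# Nest a chain of pLoss nodes transforming `from` into `to` (losses applied
# left to right) above `inner`.
wrap_losses <- function(from, to, species, inner) {
  segs <- list()
  cur <- from
  while (!identical(cur, to)) {
    kept <- cur %in% to
    i <- which(!kept)[1L]
    j <- i
    while (j < length(cur) && !kept[j + 1L]) j <- j + 1L
    segs[[length(segs) + 1L]] <- list(syn = cur, seg = c(i, j))
    cur <- cur[-seq.int(i, j)]
  }
  node <- inner
  for (s in rev(segs))
    node <- h_node("pLoss", species, synteny = s$syn, segment = s$seg,
                   children = list(node))
  node
}

backtrack_ordered <- function(bb, A, tbl, d, leaf_mask, full) {
  fams_of <- function(m) A[tbl$bits[[m + 1L]]]
  rec <- function(v, mask) {
    evt <- bb$event[v]
    sp <- bb$species[v]
    if (evt == "Leaf")
      return(h_node("extant", sp, synteny = fams_of(mask), leaf = bb$leaf[v]))
    if (evt == "Loss")
      return(h_node("fLoss", sp))
    kids <- bb$children[[v]]
    X <- fams_of(mask)
    child_branch <- function(i, partial) {
      c <- kids[i]
      if (bb$event[c] == "Loss") return(list(seg = NULL, node = rec(c, 0L)))
      ch <- choose_sub(d[c, ], mask, if (partial) tbl$runsP else tbl$runsT, tbl)
      Y <- fams_of(ch$mask)
      if (partial) {
        pos <- match(Y, X)
        seg <- c(min(pos), max(pos))
        copy <- X[seq.int(seg[1L], seg[2L])]
        list(seg = seg,
             node = wrap_losses(copy, Y, bb$species[c], rec(c, ch$mask)))
      } else {
        list(seg = NULL,
             node = wrap_losses(X, Y, bb$species[c], rec(c, ch$mask)))
      }
    }
    if (evt == "Spe") {
      h_node("Spe", sp, synteny = X, segment = c(1L, length(X)),
             children = list(child_branch(1L, FALSE)$node,
                             child_branch(2L, FALSE)$node))
    } else {
      # orientation of the partial copy; ties toward the left child
      bvals <- function(i, runs) {
        c <- kids[i]
        if (bb$event[c] == "Loss") return(1)
        choose_sub(d[c, ], mask, runs, tbl)$cost
      }
      lr <- bvals(1L, tbl$runsP) + bvals(2L, tbl$runsT)
      rl <- bvals(1L, tbl$runsT) + bvals(2L, tbl$runsP)
      left_partial <- lr <= rl
      b1 <- child_branch(1L, left_partial)
      b2 <- child_branch(2L, !left_partial)
      seg <- if (left_partial) b1$seg else b2$seg
      if (is.null(seg)) seg <- c(1L, length(X))  # full copy
      h_node("Dup", sp, synteny = X, segment = seg,
             children = list(b1$node, b2$node))
    }
  }
  if (bb$event[bb$root] == "Leaf") {
    lm <- leaf_mask[bb$root]
    node <- wrap_losses(A, fams_of(lm), bb$species[bb$root],
                        rec(bb$root, lm))
    return(new_history(node, bb$species_index))
  }
  new_history(rec(bb$root, full), bb$species_index)
}
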