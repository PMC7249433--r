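# Brute-force loss distance on character vectors: minimum number of
# single-interval removals turning X into Y, by breadth-first search over
# subsequences. Independent of the analytic run-counting implementation.
brute_dist_chr <- function(X, Y, partial = FALSE) {
  key <- function(v) paste(v, collapse = "\r")
  starts <- if (partial) {
    out <- list()
    for (i in seq_along(X)) for (j in i:length(X))
      out[[length(out) + 1L]] <- X[i:j]
    out
  } else list(X)
  best <- Inf
  for (s in starts) {
    if (!all(Y %in% s)) next
    frontier <- list(s); d <- 0
    seen <- character(0)
    repeat {
      if (any(vapply(frontier, identical, logical(1), y = Y))) break
      d <- d + 1
      nxt <- list()
      for (cur in frontier) {
        for (i in seq_along(cur)) for (j in i:length(cur)) {
          if (any(Y %in% cur[i:j])) next
          red <- cur[-(i:j)]
          k <- key(red)
          if (!(k %in% seen)) { seen <- c(seen, k); nxt[[length(nxt) + 1L]] <- red }
        }
      }
      frontier <- nxt
      if (length(frontier) == 0L) { d <- Inf; break }
    }
    best <- min(best, d)
  }
  best
}

test_that("segmental loss distances match brute-force interval removal", {
  A5 <- letters[1:5]
  expect_identical(loss_dist_total(A5, c("a", "c", "e")), 2L)
  expect_identical(brute_dist_chr(A5, c("a", "c", "e")), 2)
  expect_identical(loss_dist_partial(A5, c("b", "c", "d")), 0L)
  expect_identical(loss_dist_partial(A5, c("b", "d")), 1L)
  expect_identical(brute_dist_chr(A5, c("b", "d"), partial = TRUE), 1)
  expect_identical(loss_dist_partial(A5, c("a", "c", "e")), 2L)
  expect_identical(loss_dist_total(A5, A5), 0L)
  expect_identical(loss_dist_total(letters[1:3], character(0)), 1L)
  expect_error(loss_dist_total(c("a", "b"), c("b", "a")),
               class = "superrec_not_subsequence")
  expect_error(loss_dist_total(c("a", "b"), "z"),
               class = "superrec_not_subsequence")
  # exhaustive agreement with brute force up to length 6
  for (n in 1:6) {
    X <- letters[seq_len(n)]
    for (m in 0:(2^n - 1)) {
      Y <- X[as.logical(intToBits(m))[seq_len(n)]]
      expect_identical(as.numeric(loss_dist_total(X, Y)), brute_dist_chr(X, Y))
      if (length(Y))
        expect_identical(as.numeric(loss_dist_partial(X, Y)),
                         brute_dist_chr(X, Y, partial = TRUE))
    }
  }
})

test_that("distance identities hold exhaustively", {
  for (n in 1:8) {
    X <- letters[seq_len(n)]
    expect_identical(loss_dist_total(X, X), 0L)
    expect_identical(loss_dist_total(X, character(0)), 1L)
    for (m in 1:(2^n - 1)) {
      Y <- X[as.logical(intToBits(m))[seq_len(n)]]
      dp <- loss_dist_partial(X, Y)
      dt <- loss_dist_total(X, Y)
      expect_true(dp <= dt)
      expect_true(dt <= dp + 2L)
    }
  }
})

test_that("the ordered DP solves hand-checked base cases", {
  S <- as_sr_tree("(spA,spB);")
  sidx <- index_tree(S, autolabel = TRUE)
  A <- c("a", "b", "c")
  # one leaf, root order equal to the extant synteny: cost 0
  bb1 <- build_backbone(sr_tree_leaf("X1"), c(X1 = "spA"), sidx)
  f1 <- small_phylogeny_ordered(bb1, A, list(X1 = A))
  expect_identical(f1$cost, 0L)
  expect_true(validate_history(f1$history))
  # speciation root over two identical syntenies congruent with S: cost 0
  bb2 <- build_backbone(as_sr_tree("(X1,X2);"),
                        c(X1 = "spA", X2 = "spB"), sidx)
  f2 <- small_phylogeny_ordered(bb2, A, list(X1 = A, X2 = A))
  expect_identical(f2$cost, 0L)
  # duplication root, children abc and bc in one species: one partial copy
  bb3 <- build_backbone(as_sr_tree("(X1,X2);"),
                        c(X1 = "spA", X2 = "spA"), sidx)
  f3 <- small_phylogeny_ordered(bb3, A, list(X1 = A, X2 = c("b", "c")))
  expect_identical(f3$cost, 1L)
  expect_identical(oracle_ordered(bb3, A, list(X1 = A, X2 = c("b", "c"))), 1)
  h3 <- f3$history
  expect_identical(h3$root$event, "Dup")
  expect_true(validate_history(h3))
  # an extant synteny that is not a subsequence of A is rejected
  expect_error(small_phylogeny_ordered(bb3, A, list(X1 = A, X2 = c("c", "b"))),
               class = "superrec_order_inconsistent")
  # state-space guard reports the offending family count
  expect_error(small_phylogeny_ordered(bb3, letters[1:20],
                                       list(X1 = letters[1:20],
                                            X2 = letters[1:20])),
               class = "superrec_resource")
})

test_that("DP equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (rep in 1:120) {
    t <- sample(2:4, 1); nl <- sample(2:4, 1); ns <- sample(1:3, 1)
    inst <- rand_ordered_instance(t, nl, ns)
    fit <- small_phylogeny_ordered(inst$bb, inst$A, inst$syntenies)
    expect_identical(as.numeric(fit$cost),
                     oracle_ordered(inst$bb, inst$A, inst$syntenies))
    expect_true(validate_history(fit$history))
    expect_identical(history_cost(fit$history), fit$cost)
  }
})

test_that("backtracked duplications use the partial copy on at most one child", {
  set.seed(55)
  check_dup <- function(n) {
    if (n$event == "Dup") {
      copy <- n$synteny[seq.int(n$segment[1], n$segment[2])]
      matches_full <- vapply(n$children, function(c)
        identical(c$synteny, n$synteny) || c$event == "fLoss", logical(1))
      expect_true(any(matches_full) ||
                    identical(copy, n$synteny))
    }
    for (c in n$children) check_dup(c)
  }
  for (rep in 1:25) {
    inst <- rand_ordered_instance(sample(2:4, 1), sample(2:4, 1),
                                  sample(1:2, 1))
    fit <- small_phylogeny_ordered(inst$bb, inst$A, inst$syntenies)
    check_dup(fit$history$root)
  }
})

test_that("grafted full losses cost exactly one event in the DP", {
  # speciation forced two edges down: the two grafted leaves each cost 1
  S4 <- as_sr_tree("(((spA,spB),spC),spD);")
  sidx <- index_tree(S4, autolabel = TRUE)
  bb <- build_backbone(as_sr_tree("(X1,X2);"), c(X1 = "spA", X2 = "spD"),
                       sidx)
  expect_identical(backbone_n_losses(bb), 2L)
  fit <- small_phylogeny_ordered(bb, c("a", "b"),
                                 list(X1 = c("a", "b"), X2 = c("a", "b")))
  expect_identical(fit$cost, 2L)
  cts <- history_event_counts(fit$history)
  expect_identical(unname(cts["fLoss"]), 2L)
  expect_identical(unname(cts["pLoss"]), 0L)
  expect_true(validate_history(fit$history))
})
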