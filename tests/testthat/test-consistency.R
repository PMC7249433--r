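test_that("precedence graph holds all ordered pairs, not only adjacencies", {
  g <- build_precedence_graph(list(c("a", "b", "c")))
  e <- igraph::as_edgelist(g)
  expect_setequal(paste(e[, 1], e[, 2]), c("a b", "a c", "b c"))
  g2 <- build_precedence_graph(list(c("a", "b"), c("b", "c")))
  e2 <- igraph::as_edgelist(g2)
  expect_setequal(paste(e2[, 1], e2[, 2]), c("a b", "b c"))
  # single-gene syntenies give an empty edge set
  g3 <- build_precedence_graph(list("a", "b"))
  expect_identical(igraph::ecount(g3), 0)
})

test_that("order consistency is acyclicity of the precedence graph", {
  expect_false(is_order_consistent(build_precedence_graph(
    list(c("a", "b"), c("b", "a")))))
  expect_true(is_order_consistent(build_precedence_graph(
    list(c("a", "b"), c("b", "c"), c("a", "c")))))
  expect_true(is_order_consistent(build_precedence_graph(list())))
})

test_that("ancestral orders are exactly the topological sorts", {
  ord1 <- enumerate_ancestral_orders(build_precedence_graph(
    list(c("a", "b"), c("b", "c"))))
  expect_identical(ord1, structure(list(c("a", "b", "c")), truncated = FALSE))
  ord2 <- enumerate_ancestral_orders(build_precedence_graph(list("a", "b")))
  expect_length(ord2, 2L)
  ord3 <- enumerate_ancestral_orders(build_precedence_graph(
    list(c("a", "b"), c("a", "c"))))
  expect_identical(lapply(ord3, paste, collapse = ""), list("abc", "acb"))
  expect_error(enumerate_ancestral_orders(build_precedence_graph(
    list(c("a", "b"), c("b", "a")))), class = "superrec_order_inconsistent")
  # truncation is flagged
  expect_warning(
    free <- enumerate_ancestral_orders(build_precedence_graph(
      as.list(letters[1:5])), limit = 10L),
    "truncated")
  expect_true(attr(free, "truncated"))
  expect_length(free, 10L)
})

test_that("every enumerated order contains every input synteny as a subsequence", {
  set.seed(41)
  for (rep in 1:20) {
    t <- sample(3:5, 1)
    A0 <- sample(letters[1:t])
    syn <- lapply(1:4, function(i) rand_subseq(A0))
    g <- build_precedence_graph(syn)
    if (!is_order_consistent(g)) next  # cannot happen: all drawn from A0
    for (A in enumerate_ancestral_orders(g, limit = 200L)) {
      for (s in syn) {
        pos <- match(s, A)
        expect_false(anyNA(pos))
        expect_false(is.unsorted(pos, strictly = TRUE))
      }
    }
  }
})

test_that("triplet consistency compares shared 3-subsets across trees", {
  t1 <- as_sr_tree("((X1,X2),X3);")
  expect_true(triplet_consistent(list(t1, t1)))
  expect_false(triplet_consistent(list(t1, as_sr_tree("((X1,X3),X2);"))))
  expect_true(triplet_consistent(list(as_sr_tree("(X1,X2);"),
                                      as_sr_tree("(X3,X4);"))))
})

test_that("BUILD returns a displaying supertree exactly when one exists", {
  # identity on a single tree
  t1 <- as_sr_tree("((X1,X2),X3);")
  expect_identical(tree_canonical(build_supertree(list(t1))),
                   tree_canonical(t1))
  # a directly conflicting triplet pair
  expect_error(build_supertree(list(as_sr_tree("((X1,X2),X3);"),
                                    as_sr_tree("((X1,X3),X2);"))),
               class = "superrec_tree_inconsistent")
  # overlapping but compatible trees combine into a displaying supertree
  st2 <- build_supertree(list(as_sr_tree("((X1,X2),X3);"),
                              as_sr_tree("((X2,X3),X4);")))
  expect_true(tree_displays(st2, as_sr_tree("((X1,X2),X3);")))
  expect_true(tree_displays(st2, as_sr_tree("((X2,X3),X4);")))
  # two disjoint cherries are compatible
  st <- build_supertree(list(as_sr_tree("(X1,X2);"), as_sr_tree("(X3,X4);")))
  expect_true(tree_displays(st, as_sr_tree("(X1,X2);")))
  expect_true(tree_displays(st, as_sr_tree("(X3,X4);")))
  # randomized: success iff some binary topology displays all inputs
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    leaves <- paste0("X", 1:n)
    src <- rand_topology(leaves)
    trees <- lapply(1:3, function(i) {
      keep <- sample(leaves, sample(3:n, 1))
      tree_restrict(src, keep)
    })
    if (sample(c(TRUE, FALSE), 1)) {
      # inject a possibly conflicting random tree
      trees[[4]] <- rand_topology(sample(leaves, 3))
    }
    exists_exhaustive <- any(vapply(all_binary_topologies(leaves), function(tt)
      all(vapply(trees, function(s) tree_displays(tt, s), logical(1))),
      logical(1)))
    built <- tryCatch(build_supertree(trees), superrec_error = function(e) NULL)
    expect_identical(!is.null(built), exists_exhaustive)
    if (!is.null(built)) {
      # BUILD's tree itself displays every input
      for (s in trees) expect_true(tree_displays(built, s))
    }
  }
})

test_that("binary supertree enumeration is the displaying subset of all topologies", {
  # inputs fully resolving one topology
  full <- as_sr_tree("(((X1,X2),X3),X4);")
  trees <- list(tree_restrict(full, c("X1", "X2", "X3")),
                tree_restrict(full, c("X1", "X3", "X4")),
                tree_restrict(full, c("X2", "X3", "X4")))
  out <- enumerate_binary_supertrees(trees)
  expect_length(out, 1L)
  expect_identical(tree_canonical(out[[1]]), tree_canonical(full))
  # a single cherry plus a free leaf: every 3-leaf topology restricts to the
  # cherry on {X1, X2}, so all three display it
  out2 <- enumerate_binary_supertrees(list(as_sr_tree("(X1,X2);")),
                                      leaves = c("X1", "X2", "X3"))
  expect_length(out2, 3L)
  # a resolved triplet constraint pins the topology down
  out2b <- enumerate_binary_supertrees(list(as_sr_tree("((X1,X2),X3);")))
  expect_length(out2b, 1L)
  # no input trees: all 3 topologies on 3 free leaves
  out3 <- enumerate_binary_supertrees(list(), leaves = c("X1", "X2", "X3"))
  expect_length(out3, 3L)
  # every emitted tree displays every input; matches exhaustive filtering
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    leaves <- paste0("X", 1:n)
    src <- rand_topology(leaves)
    trees <- lapply(1:2, function(i)
      tree_restrict(src, sample(leaves, sample(3:n, 1))))
    out <- enumerate_binary_supertrees(trees, leaves = leaves)
    for (tt in out)
      for (s in trees) expect_true(tree_displays(tt, s))
    brute <- Filter(function(tt)
      all(vapply(trees, function(s) tree_displays(tt, s), logical(1))),
      all_binary_topologies(leaves))
    expect_setequal(vapply(out, tree_canonical, character(1)),
                    unique(vapply(brute, tree_canonical, character(1))))
  }
  expect_error(enumerate_binary_supertrees(list(), leaves = paste0("X", 1:9)),
               class = "superrec_resource")
})
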