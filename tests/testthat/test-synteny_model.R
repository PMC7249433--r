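make_table <- function() {
  data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    family = c("famA", "famB", "famB", "famC", "famA"),
    species = c("spX", "spX", "spY", "spY", "spY"),
    synteny = c("syn1", "syn1", "syn2", "syn2", "syn3"),
    position = c(1L, 2L, 1L, 2L, 1L),
    stringsAsFactors = FALSE)
}

test_that("synteny tables parse into validated domain objects", {
  syn <- syntenies_from_table(make_table())
  expect_s3_class(syn, "sr_syntenies")
  expect_length(syn$syntenies, 3L)
  expect_identical(syn$syntenies$syn1$families, c("famA", "famB"))
  expect_identical(syn$syntenies$syn1$species, "spX")
  expect_setequal(syn$families, c("famA", "famB", "famC"))
  # TSV round-trip
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_synteny_table(syn, tf)
  syn2 <- read_synteny_table(tf)
  expect_identical(synteny_orders(syn2), synteny_orders(syn))
})

test_that("table validation rejects each malformation with its own error class", {
  tab <- make_table()
  t1 <- tab; t1$gene[2] <- "g1"
  expect_error(syntenies_from_table(t1), class = "superrec_duplicate_gene")
  t2 <- tab; t2$family[2] <- "famA"  # two famA genes in syn1
  expect_error(syntenies_from_table(t2), class = "superrec_family_injectivity")
  t3 <- tab; t3$species[2] <- "spY"
  expect_error(syntenies_from_table(t3), class = "superrec_species_mismatch")
  t4 <- tab; t4$position[2] <- 3L
  expect_error(syntenies_from_table(t4), class = "superrec_table_format")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b,c),d);", f)
  expect_error(read_species_tree(f), class = "superrec_nonbinary_tree")
})

test_that("instance cross-validation catches missing and unmapped genes", {
  syn <- syntenies_from_table(make_table())
  S <- as_sr_tree("(spX,spY);")
  gtA <- as_sr_tree("(g1,g5);")
  gtB <- as_sr_tree("(g2,g3);")
  gtC <- as_sr_tree("(g4);")
  expect_silent(validate_instance(S, list(gtA, gtB, gtC), syn))
  expect_error(validate_instance(S, list(gtA, gtB), syn),
               class = "superrec_missing_gene")
  gt_bad <- as_sr_tree("(g1,gZ);")
  expect_error(validate_instance(S, list(gt_bad, gtB, gtC), syn),
               class = "superrec_missing_gene")
  expect_error(validate_instance(as_sr_tree("(spX,spZ);"),
                                 list(gtA, gtB, gtC), syn),
               class = "superrec_species_mismatch")
})

test_that("synteny_tree_of relabels leaves and keeps topology", {
  syn <- syntenies_from_table(make_table())
  gt <- as_sr_tree("(g1,(g2,g3));")
  st <- synteny_tree_of(gt, syn)
  expect_identical(tree_to_newick(st), "(syn1,(syn1,syn2));")
  expect_identical(tree_to_newick(synteny_tree_of(as_sr_tree("(g4);"), syn)),
                   "(syn2);")
  expect_error(synteny_tree_of(as_sr_tree("(gZ,g1);"), syn),
               class = "superrec_missing_gene")
})

test_that("history cost counts Dup + pLoss + fLoss and validation is edge-exact", {
  S <- as_sr_tree("(spA,spB);")
  sidx <- index_tree(S, autolabel = TRUE)
  spA <- sidx$leaf_id[["spA"]]; spB <- sidx$leaf_id[["spB"]]; rt <- sidx$root
  ab <- c("a", "b")
  # Spe root, both children extant with the full synteny: cost 0
  h0 <- new_history(h_node("Spe", rt, ab, c(1L, 2L), list(
    h_node("extant", spA, ab, leaf = "X1"),
    h_node("extant", spB, ab, leaf = "X2"))), sidx)
  expect_identical(history_cost(h0), 0L)
  expect_true(validate_history(h0))
  # Dup then a pLoss on one side, an fLoss under a speciation: cost 3
  h1 <- new_history(h_node("Dup", spA, ab, c(2L, 2L), list(
    h_node("pLoss", spA, ab, c(1L, 1L), list(
      h_node("extant", spA, "b", leaf = "X1"))),
    h_node("extant", spA, "b", leaf = "X2"))), sidx)
  expect_identical(history_cost(h1), 2L)
  expect_true(validate_history(h1))
  # violations: Spe children must carry the parent synteny
  bad <- new_history(h_node("Spe", rt, ab, c(1L, 2L), list(
    h_node("extant", spA, "a", leaf = "X1"),
    h_node("extant", spB, ab, leaf = "X2"))), sidx)
  expect_error(validate_history(bad), class = "superrec_invalid_history")
  # Dup children must be {X, X[i,j]}
  bad2 <- new_history(h_node("Dup", spA, ab, c(1L, 1L), list(
    h_node("extant", spA, "b", leaf = "X1"),
    h_node("extant", spA, "b", leaf = "X2"))), sidx)
  expect_error(validate_history(bad2), class = "superrec_invalid_history")
})

test_that("histories serialize to annotated Newick plus an event log", {
  h <- simulate_history(sim_params(t = 3, d = 2), seed = 5)
  tf <- withr::local_tempfile(fileext = ".nwk")
  paths <- write_history(h, tf)
  nwk <- readLines(paths[1])
  expect_match(nwk, "\\[&event=", all = FALSE)
  log <- utils::read.delim(paths[2])
  expect_setequal(names(log), c("node_id", "parent_id", "event", "species",
                                "synteny", "segment"))
  counts <- history_event_counts(h)
  expect_identical(sum(log$event == "Dup"), unname(counts["Dup"]))
  expect_identical(nrow(log), sum(counts))
  expect_identical(h$cost,
                   sum(log$event %in% c("Dup", "pLoss", "fLoss")))
})
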