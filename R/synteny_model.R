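#' Read a species tree from a Newick file
#'
#' The tree must be rooted and binary; branch lengths, if present, are parsed
#' and ignored. Leaf labels are species identifiers and must be unique.
#'
#' @param path path to a Newick file containing one rooted binary tree.
#' @return an `sr_tree`.
#' @export
read_species_tree <- function(path) {
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  tr <- as_sr_tree(phy)
  check_species_tree(tr)
  tr
}

check_species_tree <- function(tr) {
  if (!tree_is_binary(tr))
    stop_superrec("superrec_nonbinary_tree", "species tree is not binary")
  lv <- tree_leaves(tr)
  if (anyDuplicated(lv))
    stop_superrec("superrec_duplicate_label",
                  "duplicate species labels in species tree")
  invisible(tr)
}

#' Read gene trees from a Newick file
#'
#' One rooted binary tree per line; leaf labels are gene identifiers.
#'
#' @param path path to a Newick file.
#' @return a list of `sr_tree` objects.
#' @export
read_gene_trees <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  trees <- lapply(txt, function(line) {
    tr <- as_sr_tree(line)
    if (!tree_is_binary(tr))
      stop_superrec("superrec_nonbinary_tree",
                    sprintf("gene tree '%s' is not binary", line))
    tr
  })
  all_leaves <- unlist(lapply(trees, tree_leaves))
  if (anyDuplicated(all_leaves))
    stop_superrec("superrec_duplicate_gene",
                  "a gene id appears in more than one gene tree leaf")
  trees
}

#' Build a synteny set from a gene table
#'
#' The table has columns `gene`, `family`, `species`, `synteny`, `position`
#' (1-based, contiguous within each synteny). Each gene belongs to exactly
#' one synteny; within a synteny all genes share the species and no two genes
#' belong to the same family (tandem duplications are out of model).
#'
#' @param x a data.frame with the five columns above.
#' @return an object of class `sr_syntenies`: a list with elements
#'   `syntenies` (named list; each entry has `id`, `species`, `families`
#'   (ordered character vector) and `genes` (ordered gene ids)), `genes`
#'   (the validated table), and `families` (sorted family ids).
#' @export
syntenies_from_table <- function(x) {
  need <- c("gene", "family", "species", "synteny", "position")
  if (!all(need %in% names(x)))
    stop_superrec("superrec_table_format",
                  paste("synteny table must have columns:",
                        paste(need, collapse = " ")))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$position <- as.integer(x$position)
  if (anyDuplicated(x$gene))
    stop_superrec("superrec_duplicate_gene", "duplicate gene id in table")
  syn <- list()
  for (id in unique(x$synteny)) {
    rows <- x[x$synteny == id, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    if (!identical(rows$position, seq_len(nrow(rows))))
      stop_superrec("superrec_table_format",
                    sprintf("positions in synteny '%s' are not contiguous 1..k", id))
    if (length(unique(rows$species)) != 1L)
      stop_superrec("superrec_species_mismatch",
                    sprintf("synteny '%s' mixes species", id))
    if (anyDuplicated(rows$family))
      stop_superrec("superrec_family_injectivity",
                    sprintf("synteny '%s' has two genes of the same family", id))
    syn[[id]] <- list(id = id, species = rows$species[1L],
                      families = rows$family, genes = rows$gene)
  }
  structure(list(syntenies = syn, genes = x,
                 families = sort(unique(x$family))),
            class = "sr_syntenies")
}

#' @rdname syntenies_from_table
#' @param path path to a TSV file with a header row.
#' @export
read_synteny_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  syntenies_from_table(x)
}

#' @export
print.sr_syntenies <- function(x, ...) {
  cat(sprintf("<sr_syntenies> %d syntenies, %d genes, %d families\n",
              length(x$syntenies), nrow(x$genes), length(x$families)))
  invisible(x)
}

#' Write a synteny set back to a TSV table
#'
#' @param syn an `sr_syntenies` object.
#' @param path output path.
#' @export
write_synteny_table <- function(syn, path) {
  utils::write.table(syn$genes[, c("gene", "family", "species", "synteny",
                                   "position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Accessors for a synteny set
#'
#' `gene_synteny_map()` maps gene ids to synteny ids; `synteny_orders()`
#' returns each synteny as its ordered vector of families;
#' `synteny_species()` gives each synteny's species.
#'
#' @param syn an `sr_syntenies` object.
#' @return a named vector or list keyed by gene or synteny id.
#' @export
gene_synteny_map <- function(syn) {
  stats::setNames(syn$genes$synteny, syn$genes$gene)
}

#' @rdname gene_synteny_map
#' @export
synteny_orders <- function(syn) {
  lapply(syn$syntenies, `[[`, "families")
}

#' @rdname gene_synteny_map
#' @export
synteny_species <- function(syn) {
  vapply(syn$syntenies, `[[`, character(1), "species")
}

#' Cross-validate a full instance
#'
#' Checks that every leaf of every gene tree is a gene of the table, that
#' every table gene appears in exactly one tree, that each tree spans exactly
#' one family, and that every species used is a leaf of the species tree.
#'
#' @param species_tree an `sr_tree`.
#' @param gene_trees a list of `sr_tree`.
#' @param syn an `sr_syntenies` object.
#' @return invisibly, a named list of gene trees keyed by family.
#' @export
validate_instance <- function(species_tree, gene_trees, syn) {
  sp <- tree_leaves(species_tree)
  bad_sp <- setdiff(unique(syn$genes$species), sp)
  if (length(bad_sp))
    stop_superrec("superrec_species_mismatch",
                  paste("species not in species tree:",
                        paste(bad_sp, collapse = ", ")))
  fam_of <- stats::setNames(syn$genes$family, syn$genes$gene)
  seen <- character(0)
  by_family <- list()
  for (tr in gene_trees) {
    lv <- tree_leaves(tr)
    missing <- setdiff(lv, names(fam_of))
    if (length(missing))
      stop_superrec("superrec_missing_gene",
                    paste("gene in tree absent from table:",
                          paste(missing, collapse = ", ")))
    fams <- unique(fam_of[lv])
    if (length(fams) != 1L)
      stop_superrec("superrec_family_mismatch",
                    "a gene tree mixes genes from several families")
    if (fams %in% names(by_family))
      stop_superrec("superrec_family_mismatch",
                    sprintf("two gene trees for family '%s'", fams))
    by_family[[fams]] <- tr
    seen <- c(seen, lv)
  }
  unseen <- setdiff(syn$genes$gene, seen)
  if (length(unseen))
    stop_superrec("superrec_missing_gene",
                  paste("table gene absent from every tree:",
                        paste(unseen, collapse = ", ")))
  invisible(by_family)
}

#' Synteny tree corresponding to a gene tree
#'
#' Replaces each gene-tree leaf by the identifier of the synteny housing the
#' gene; the topology is unchanged. Genes of different families that sit in
#' one synteny thus give identical leaf labels across trees, which is what
#' makes the supertree step non-trivial.
#'
#' @param gene_tree an `sr_tree` with gene-id leaves.
#' @param gene_to_synteny named character vector (or `sr_syntenies`).
#' @return an `sr_tree` with synteny-id leaves.
#' @export
synteny_tree_of <- function(gene_tree, gene_to_synteny) {
  if (inherits(gene_to_synteny, "sr_syntenies"))
    gene_to_synteny <- gene_synteny_map(gene_to_synteny)
  rec <- function(n) {
    if (tree_is_leaf(n)) {
      sid <- gene_to_synteny[n$label]
      if (is.na(sid))
        stop_superrec("superrec_missing_gene",
                      sprintf("gene '%s' has no synteny", n$label))
      return(sr_tree_leaf(unname(sid)))
    }
    sr_tree_node(lapply(n$children, rec))
  }
  rec(gene_tree)
}

## ---- Labeled histories -----------------------------------------------------

# A history node: event is one of Spe/Dup/pLoss/fLoss/extant; synteny is the
# ordered character vector of families carried by the node; species is a node
# id in the indexed species tree; segment is the closed 1-based interval
# [i, j] into the node's synteny affected by the event (Spe: [1, l];
# extant/fLoss: NULL); leaf is the extant synteny id for extant leaves.
h_node <- function(event, species, synteny = character(0), segment = NULL,
                   children = list(), leaf = NULL) {
  list(event = event, species = species, synteny = synteny,
       segment = segment, children = children, leaf = leaf)
}

#' Construct a labeled history object
#'
#' @param root nested history node structure (internal representation).
#' @param species_index indexed species tree the node species ids refer to.
#' @return an object of class `sr_history` with the event-count cost.
#' @keywords internal
new_history <- function(root, species_index) {
  h <- structure(list(root = root, species_index = species_index),
                 class = "sr_history")
  h$cost <- history_cost(h)
  h
}

#' Cost of a labeled history
#'
#' The number of induced duplication, full-loss and partial-loss events;
#' speciations and extant leaves are free.
#'
#' @param h an `sr_history`.
#' @return a non-negative integer.
#' @export
history_cost <- function(h) {
  rec <- function(n) {
    own <- if (n$event %in% c("Dup", "pLoss", "fLoss")) 1L else 0L
    own + sum(vapply(n$children, rec, integer(1)))
  }
  rec(h$root)
}

#' Per-event counts of a history
#'
#' @param h an `sr_history`.
#' @return named integer vector with entries Spe, Dup, pLoss, fLoss, extant.
#' @export
history_event_counts <- function(h) {
  counts <- c(Spe = 0L, Dup = 0L, pLoss = 0L, fLoss = 0L, extant = 0L)
  rec <- function(n) {
    counts[n$event] <<- counts[n$event] + 1L
    for (c in n$children) rec(c)
  }
  rec(h$root)
  counts
}

#' @export
print.sr_history <- function(x, ...) {
  cts <- history_event_counts(x)
  cat(sprintf(paste0("<sr_history> cost %d ",
                     "(%d Dup, %d pLoss, %d fLoss; %d Spe, %d extant)\n"),
              x$cost, cts["Dup"], cts["pLoss"], cts["fLoss"], cts["Spe"],
              cts["extant"]))
  invisible(x)
}

#' Validate a labeled history edge by edge
#'
#' Checks the evolutionary-model constraints at every node: a speciation
#' passes its synteny unchanged to the two child species of its own species;
#' a duplication keeps one copy and emits the substring `[i, j]` in the same
#' species; a partial loss is unary and removes exactly its segment; full
#' losses are leaves carrying the empty synteny; extant leaves carry
#' non-empty syntenies at species-tree leaves. Every node's synteny is
#' therefore a subsequence of all of its ancestors' syntenies.
#'
#' @param h an `sr_history`.
#' @return invisibly `TRUE`; otherwise an error of class
#'   `superrec_invalid_history` naming the first violated constraint.
#' @export
validate_history <- function(h) {
  sidx <- h$species_index
  fail <- function(msg) stop_superrec("superrec_invalid_history", msg)
  seg_ok <- function(n) {
    !is.null(n$segment) && length(n$segment) == 2L &&
      n$segment[1] >= 1L && n$segment[1] <= n$segment[2] &&
      n$segment[2] <= length(n$synteny)
  }
  rec <- function(n) {
    ev <- n$event
    if (ev == "extant") {
      if (length(n$children)) fail("extant node has children")
      if (length(n$synteny) == 0L) fail("extant leaf with empty synteny")
      if (!sidx$is_leaf[n$species]) fail("extant leaf at ancestral species")
    } else if (ev == "fLoss") {
      if (length(n$children)) fail("fLoss node has children")
      if (length(n$synteny) != 0L) fail("fLoss leaf carries a synteny")
    } else if (ev == "pLoss") {
      if (length(n$children) != 1L) fail("pLoss node is not unary")
      if (!seg_ok(n)) fail("pLoss segment out of bounds")
      ch <- n$children[[1L]]
      kept <- n$synteny[-seq.int(n$segment[1], n$segment[2])]
      if (!identical(ch$synteny, kept) && ch$event != "fLoss")
        fail("pLoss child synteny is not the truncated synteny")
      if (ch$species != n$species && ch$event != "fLoss")
        fail("pLoss changes species")
    } else if (ev == "Spe") {
      if (length(n$children) != 2L) fail("Spe node is not binary")
      sp_kids <- sidx$children[[n$species]]
      if (length(sp_kids) != 2L) fail("Spe at a species-tree leaf")
      got <- vapply(n$children, `[[`, integer(1), "species")
      if (!setequal(got, sp_kids)) fail("Spe children species are not the two child species")
      for (ch in n$children) {
        if (ch$event != "fLoss" && !identical(ch$synteny, n$synteny))
          fail("Spe child synteny differs from parent")
      }
    } else if (ev == "Dup") {
      if (length(n$children) != 2L) fail("Dup node is not binary")
      if (!seg_ok(n)) fail("Dup segment out of bounds")
      copy <- n$synteny[seq.int(n$segment[1], n$segment[2])]
      syns <- lapply(n$children, `[[`, "synteny")
      evs <- vapply(n$children, `[[`, character(1), "event")
      full_ok <- vapply(seq_along(syns), function(i)
        identical(syns[[i]], n$synteny) || evs[i] == "fLoss", logical(1))
      copy_ok <- vapply(seq_along(syns), function(i)
        identical(syns[[i]], copy) || evs[i] == "fLoss", logical(1))
      if (!((full_ok[1] && copy_ok[2]) || (full_ok[2] && copy_ok[1])))
        fail("Dup children are not {X, X[i,j]}")
      sp <- vapply(n$children, `[[`, integer(1), "species")
      if (any(sp != n$species)) fail("Dup changes species")
    } else fail(sprintf("unknown event '%s'", ev))
    for (ch in n$children) rec(ch)
  }
  rec(h$root)
  invisible(TRUE)
}

## ---- History serialization -------------------------------------------------

#' Flatten a history to an event log
#'
#' @param h an `sr_history`.
#' @return a data.frame with columns node_id (preorder), parent_id, event,
#'   species, synteny (families joined by `|`), segment (`"i-j"` or `""`).
#' @export
history_event_log <- function(h) {
  sidx <- h$species_index
  rows <- list()
  k <- 0L
  rec <- function(n, par) {
    k <<- k + 1L
    id <- k
    rows[[id]] <<- data.frame(
      node_id = id, parent_id = par, event = n$event,
      species = sidx$label[n$species],
      synteny = paste(n$synteny, collapse = "|"),
      segment = if (is.null(n$segment)) ""
                else paste(n$segment, collapse = "-"),
      stringsAsFactors = FALSE)
    for (ch in n$children) rec(ch, id)
  }
  rec(h$root, 0L)
  do.call(rbind, rows)
}

history_node_comment <- function(n, sidx) {
  sprintf("[&event=%s,segment=%s,synteny=%s,species=%s]",
          n$event,
          if (is.null(n$segment)) "" else paste(n$segment, collapse = "-"),
          paste(n$synteny, collapse = "|"),
          sidx$label[n$species])
}

#' Serialize a history as annotated Newick
#'
#' Each node carries a comment block
#' `[&event=...,segment=i-j,synteny=a|b|c,species=...]`. Extant leaves are
#' named by their synteny id; loss leaves get `lossK` names.
#'
#' @param h an `sr_history`.
#' @return a character scalar.
#' @export
history_to_newick <- function(h) {
  sidx <- h$species_index
  k <- 0L
  rec <- function(n) {
    cm <- history_node_comment(n, sidx)
    if (length(n$children) == 0L) {
      nm <- if (n$event == "extant") n$leaf else {
        k <<- k + 1L
        paste0("loss", k)
      }
      return(paste0(nm, cm))
    }
    paste0("(", paste(vapply(n$children, rec, character(1)), collapse = ","),
           ")", cm)
  }
  paste0(rec(h$root), ";")
}

#' Write a history to disk
#'
#' Writes the annotated Newick to `path` and the flat event log to
#' `paste0(path, ".events.tsv")`.
#'
#' @param h an `sr_history`.
#' @param path output path for the annotated Newick.
#' @return invisibly, the two paths written.
#' @export
write_history <- function(h, path) {
  writeLines(history_to_newick(h), path)
  log_path <- paste0(path, ".events.tsv")
  utils::write.table(history_event_log(h), log_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, log_path))
}
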