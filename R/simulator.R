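#' Simulation parameters
#'
#' The five-parameter protocol for generating segmental duplication-loss
#' histories on a balanced species tree: `t` families in the ancestral
#' synteny; species tree of depth `d` (`2^d` species); each internal node of
#' the evolving synteny tree is a segmental duplication with probability
#' `p_dupl` and a speciation otherwise; under each node, each child branch
#' independently receives a loss with probability `p_loss`; a loss removes
#' `k` genes with the shifted geometric law
#' `P(K = k) = (1 - p_length)^(k-1) * p_length`, `k >= 1`, truncated to the
#' genes available from its (uniform) start position. Duplication segments
#' draw their start uniformly and their length from the same shifted
#' geometric.
#'
#' @param t ancestral synteny size (number of gene families), >= 1.
#' @param d depth of the balanced species tree, >= 1.
#' @param p_dupl,p_loss,p_length probabilities in `[0, 1]` (`p_length > 0`).
#' @return a list of class `sr_sim_params`.
#' @export
sim_params <- function(t = 5L, d = 5L, p_dupl = 0.5, p_loss = 0.5,
                       p_length = 0.5) {
  stopifnot(t >= 1L, d >= 1L,
            p_dupl >= 0, p_dupl <= 1, p_loss >= 0, p_loss <= 1,
            p_length > 0, p_length <= 1)
  structure(list(t = as.integer(t), d = as.integer(d), p_dupl = p_dupl,
                 p_loss = p_loss, p_length = p_length),
            class = "sr_sim_params")
}

# Shifted geometric length: support {1, 2, ...}, P(k) = (1-p)^(k-1) p.
rlen_shifted_geom <- function(n, p) stats::rgeom(n, p) + 1L

# Balanced binary species tree of depth d with leaves S1..S(2^d).
balanced_species_tree <- function(d) {
  k <- 0L
  rec <- function(depth) {
    if (depth == 0L) {
      k <<- k + 1L
      return(sr_tree_leaf(paste0("S", k)))
    }
    sr_tree_node(list(rec(depth - 1L), rec(depth - 1L)))
  }
  rec(d)
}

#' Simulate a segmental duplication-loss history
#'
#' Evolves the ancestral synteny `f1..ft` down a balanced species tree. At a
#' species-tree leaf the lineage becomes an extant synteny. Otherwise the
#' node speciates (both children inherit the full synteny, one per child
#' species) or, with probability `p_dupl`, duplicates a random segment
#' (both children stay in the same species; one keeps the synteny, the
#' other starts from the copied segment). After the event, each child
#' branch independently suffers at most one loss with probability `p_loss`;
#' a loss that consumes the whole synteny turns the branch into a full-loss
#' leaf, otherwise it is recorded as a partial-loss node.
#'
#' Randomness comes from the R session RNG: call `set.seed()` (or pass
#' `seed`) for reproducible histories.
#'
#' @param params an [sim_params()] object.
#' @param seed optional integer seed.
#' @param max_nodes safety cap on the history size.
#' @return an `sr_history` with extra fields: `params`, `species_tree`, and
#'   `stats` (event counts, true cost, and a data.frame of losses with drawn
#'   and applied lengths).
#' @export
simulate_history <- function(params, seed = NULL, max_nodes = 100000L) {
  stopifnot(inherits(params, "sr_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  S <- balanced_species_tree(params$d)
  sidx <- index_tree(S, autolabel = TRUE)
  fams <- paste0("f", seq_len(params$t))
  n_nodes <- 0L
  losses <- list()
  bump <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > max_nodes)
      stop_superrec("superrec_resource",
                    sprintf("simulated history exceeded %d nodes", max_nodes))
  }
  # Maybe wrap the lineage continuing at `sp` with synteny `syn` in a loss.
  # Returns the (possibly wrapped) subtree.
  with_loss <- function(sp, syn) {
    if (stats::runif(1) < params$p_loss) {
      k <- rlen_shifted_geom(1L, params$p_length)
      start <- sample.int(length(syn), 1L)
      end <- min(start + k - 1L, length(syn))
      losses[[length(losses) + 1L]] <<- data.frame(
        drawn = k, applied = end - start + 1L, full = (end - start + 1L) == length(syn))
      if (end - start + 1L == length(syn)) {
        bump()
        return(h_node("fLoss", sp))
      }
      inner <- evolve(sp, syn[-seq.int(start, end)])
      bump()
      return(h_node("pLoss", sp, synteny = syn, segment = c(start, end),
                    children = list(inner)))
    }
    evolve(sp, syn)
  }
  evolve <- function(sp, syn) {
    bump()
    if (sidx$is_leaf[sp])
      return(h_node("extant", sp, synteny = syn))
    if (stats::runif(1) < params$p_dupl) {
      start <- sample.int(length(syn), 1L)
      end <- min(start + rlen_shifted_geom(1L, params$p_length) - 1L,
                 length(syn))
      copy <- syn[seq.int(start, end)]
      h_node("Dup", sp, synteny = syn, segment = c(start, end),
             children = list(with_loss(sp, syn), with_loss(sp, copy)))
    } else {
      kids <- sidx$children[[sp]]
      h_node("Spe", sp, synteny = syn, segment = c(1L, length(syn)),
             children = list(with_loss(kids[1L], syn),
                             with_loss(kids[2L], syn)))
    }
  }
  root <- evolve(sidx$root, fams)
  # name extant leaves X1, X2, ... in preorder
  k <- 0L
  name_leaves <- function(n) {
    if (n$event == "extant") {
      k <<- k + 1L
      n$leaf <- paste0("X", k)
    }
    n$children <- lapply(n$children, name_leaves)
    n
  }
  root <- name_leaves(root)
  h <- new_history(root, sidx)
  h$params <- params
  h$species_tree <- S
  cts <- history_event_counts(h)
  h$stats <- list(
    counts = cts, cost = h$cost,
    losses = if (length(losses)) do.call(rbind, losses)
             else data.frame(drawn = integer(0), applied = integer(0),
                             full = logical(0)),
    n_decision = sum(cts[c("Spe", "Dup")]))
  h
}

#' Strip a simulated history down to an inference input
#'
#' Removes loss nodes and all ancestral synteny information, leaving what an
#' inference method would see: the species tree, the extant syntenies (as a
#' gene table with generated gene ids), one gene tree per surviving family,
#' and the backbone synteny tree (the true topology over extant syntenies,
#' used in place of supertree enumeration at simulation scale). Families
#' with no surviving gene are dropped with a message.
#'
#' @param h an `sr_history` from [simulate_history()].
#' @return a list with `species_tree`, `gene_trees` (named by family),
#'   `syn` (an `sr_syntenies`), `synteny_table` (data.frame), `backbone`
#'   (`sr_tree` on synteny ids), `dropped_families`, and `true_cost`.
#' @export
strip_to_input <- function(h) {
  sidx <- h$species_index
  leaves <- list()
  collect <- function(n) {
    if (n$event == "extant")
      leaves[[n$leaf]] <<- list(id = n$leaf, species = sidx$label[n$species],
                                families = n$synteny)
    for (c in n$children) collect(c)
  }
  collect(h$root)
  if (length(leaves) == 0L)
    stop_superrec("superrec_extinct",
                  "all lineages were lost: nothing to reconcile")
  tab <- do.call(rbind, lapply(leaves, function(l) {
    data.frame(gene = paste0(l$id, "_", l$families), family = l$families,
               species = l$species, synteny = l$id,
               position = seq_along(l$families), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  syn <- syntenies_from_table(tab)
  all_fams <- paste0("f", seq_len(h$params$t))
  dropped <- setdiff(all_fams, unique(tab$family))
  if (length(dropped))
    message(sprintf("dropped %d famil%s with no surviving gene: %s",
                    length(dropped), if (length(dropped) == 1L) "y" else "ies",
                    paste(dropped, collapse = ", ")))
  # history tree -> sr_tree keeping a chosen leaf subset
  as_tree <- function(n, keep, relabel) {
    if (n$event == "fLoss") return(NULL)
    if (length(n$children) == 0L) {
      if (!(n$leaf %in% keep)) return(NULL)
      return(sr_tree_leaf(relabel(n$leaf)))
    }
    kids <- Filter(Negate(is.null),
                   lapply(n$children, as_tree, keep = keep, relabel = relabel))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    sr_tree_node(kids)
  }
  backbone <- as_tree(h$root, names(leaves), identity)
  gene_trees <- list()
  for (f in setdiff(all_fams, dropped)) {
    ids <- names(leaves)[vapply(leaves, function(l) f %in% l$families,
                                logical(1))]
    gene_trees[[f]] <- as_tree(h$root, ids,
                               function(x) paste0(x, "_", f))
  }
  list(species_tree = h$species_tree, gene_trees = gene_trees, syn = syn,
       synteny_table = tab, backbone = backbone,
       dropped_families = dropped, true_cost = h$cost)
}

#' Write a simulated instance to a directory
#'
#' Writes `species.nwk`, `gene_trees.nwk` (one per line, ordered by family),
#' `syntenies.tsv`, `backbone.nwk` and `truth.nwk` (the annotated true
#' history with its event log).
#'
#' @param h an `sr_history` from [simulate_history()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list from [strip_to_input()].
#' @export
write_simulation <- function(h, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inp <- strip_to_input(h)
  writeLines(tree_to_newick(inp$species_tree), file.path(dir, "species.nwk"))
  writeLines(vapply(inp$gene_trees, tree_to_newick, character(1)),
             file.path(dir, "gene_trees.nwk"))
  utils::write.table(inp$synteny_table, file.path(dir, "syntenies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tree_to_newick(inp$backbone), file.path(dir, "backbone.nwk"))
  write_history(h, file.path(dir, "truth.nwk"))
  invisible(inp)
}
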