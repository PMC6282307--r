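# MUL-tree construction: expansion of a hybridization network into a
# multi-labeled species tree in which each taxon below a hybridization
# appears twice, once per parental subgenome (copy tags A and B).
#
# MUL trees are topological objects: branch lengths play no role in
# duplication-loss reconciliation and are not carried over.

#' Edge identifiers of a tree
#'
#' Every edge is named by the sorted set of tip labels below it, joined by
#' `|`.  These ids are stable across serializations and are how attachment
#' edges are specified throughout the package.
#'
#' @param tree A `phylo` object.
#' @return Character vector of edge ids (one per non-root node).
#' @export
edge_ids <- function(tree) {
  tb <- tips_below(tree)
  nodes <- setdiff(seq_len(n_tips(tree) + tree$Nnode), root_node(tree))
  vapply(nodes, function(v) paste(tb[[v]], collapse = "|"), character(1))
}

# newick text of a phylo subtree rooted at `v`, with per-edge insertions.
# insertions: named list, edge id -> character vector of subtree texts to
# wrap around the existing subtree (first element outermost).
subtree_text <- function(tree, v, ch, tb, insertions) {
  txt <- if (v <= n_tips(tree)) tree$tip.label[v] else {
    kids <- ch[[v]]
    paste0("(", paste(vapply(kids, function(k)
      subtree_text(tree, k, ch, tb, insertions), character(1)),
      collapse = ","), ")")
  }
  id <- paste(tb[[v]], collapse = "|")
  ins <- insertions[[id]]
  if (!is.null(ins)) {
    for (clade_txt in rev(ins)) txt <- paste0("(", clade_txt, ",", txt, ")")
  }
  txt
}

# clade (phylo or single label) rendered with "@@<event><tag>" suffixed tips
clade_text <- function(clade, event, tag) {
  suffix <- paste0("@@", event, tag)
  if (is.character(clade)) return(paste0(clade, suffix))
  stopifnot(inherits(clade, "phylo"))
  render <- function(v, ch) {
    if (v <= n_tips(clade)) return(paste0(clade$tip.label[v], suffix))
    paste0("(", paste(vapply(ch[[v]], render, character(1), ch = ch),
                      collapse = ","), ")")
  }
  render(root_node(clade), children_list(clade))
}

clade_taxa <- function(clade) {
  if (is.character(clade)) clade else clade$tip.label
}

# Core constructor: expand a backbone plus a list of hybridization events
# into a MUL tree.  Each event: list(clade, parent1, parent2) with parent*
# given as backbone edge ids (a bare taxon name is the id of its pendant
# edge).  Copies under parent1 are tagged A, under parent2 B.
mul_from_events <- function(backbone, events) {
  stopifnot(inherits(backbone, "phylo"))
  assert_binary(backbone, "backbone")
  ids <- edge_ids(backbone)
  poly <- unlist(lapply(events, function(e) clade_taxa(e$clade)))
  if (anyDuplicated(poly))
    stop("polyploid taxa shared between events", call. = FALSE)
  if (length(intersect(poly, backbone$tip.label)))
    stop("polyploid taxa overlap backbone taxa: ",
         paste(intersect(poly, backbone$tip.label), collapse = ", "),
         call. = FALSE)
  insertions <- list()
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (identical(e$parent1, e$parent2))
      stop("the two parent edges of a hybridization must differ",
           call. = FALSE)
    for (side in 1:2) {
      pid <- if (side == 1) e$parent1 else e$parent2
      if (!pid %in% ids)
        stop("no backbone edge with id '", pid, "'", call. = FALSE)
      insertions[[pid]] <- c(insertions[[pid]],
                             clade_text(e$clade, i, c("A", "B")[side]))
    }
  }
  ch <- children_list(backbone)
  tb <- tips_below(backbone)
  txt <- paste0(subtree_text(backbone, root_node(backbone), ch, tb,
                             insertions), ";")
  tree <- parse_newick(txt)
  lab <- tree$tip.label
  tagged <- grepl("@@", lab, fixed = TRUE)
  species <- sub("@@[0-9]+[AB]$", "", lab)
  copy_tag <- ifelse(tagged, sub("^.*@@[0-9]+", "", lab), NA_character_)
  event <- rep(NA_integer_, length(lab))
  event[tagged] <- as.integer(sub("[AB]$", "",
                                  sub("^.*@@", "", lab[tagged])))
  tree$tip.label <- species
  structure(list(tree = tree, species = species, copy_tag = copy_tag,
                 event = event, backbone = backbone, events = events),
            class = "mul_tree")
}

#' Build a MUL tree by grafting a polyploid clade under two parent edges
#'
#' The clade is inserted once into each of the two given backbone edges
#' (each insertion subdivides the edge with a new node).  Copies under
#' `parent_edge_1` are tagged `A`, copies under `parent_edge_2` are tagged
#' `B`, following the convention that the A subgenome groups with the first
#' parental lineage.
#'
#' @param backbone Binary `phylo` tree of the non-polyploid taxa.
#' @param polyploid_clade A `phylo` tree, or a single taxon label, of the
#'   polyploid taxa.  Its taxa must be disjoint from the backbone's.
#' @param parent_edge_1,parent_edge_2 Distinct edge ids of `backbone` (see
#'   [edge_ids()]; a bare taxon name denotes its pendant edge).
#' @return An object of class `mul_tree`.
#' @examples
#' bb <- parse_newick("((P,S),O);")
#' m <- build_mul_tree(bb, "H", "P", "S")
#' write_newick(m$tree)
#' @export
build_mul_tree <- function(backbone, polyploid_clade, parent_edge_1,
                           parent_edge_2) {
  mul_from_events(backbone, list(list(clade = polyploid_clade,
                                      parent1 = parent_edge_1,
                                      parent2 = parent_edge_2)))
}

#' Expand a species network into its MUL tree
#'
#' Every hybridization's clade is duplicated under both of its parent
#' edges; A-tagged copies descend from the first parent (the edge carrying
#' the hybrid subtree in the extended-newick serialization), B-tagged from
#' the second.  A network with no hybridizations yields a MUL tree with no
#' repeated leaves.
#'
#' @param net A `species_network`.
#' @return An object of class `mul_tree`.
#' @export
network_to_multree <- function(net) {
  stopifnot(inherits(net, "species_network"))
  dec <- network_events(net)
  if (length(dec$events) == 0L) {
    tree <- dec$backbone
    tree$edge.length <- NULL
    return(structure(list(tree = tree, species = tree$tip.label,
                          copy_tag = rep(NA_character_, n_tips(tree)),
                          event = rep(NA_integer_, n_tips(tree)),
                          backbone = dec$backbone, events = list()),
                     class = "mul_tree"))
  }
  mul_from_events(dec$backbone,
                  lapply(dec$events, function(e)
                    list(clade = e$clade, parent1 = e$parent1,
                         parent2 = e$parent2)))
}

#' @export
print.mul_tree <- function(x, ...) {
  dup <- unique(x$species[!is.na(x$copy_tag)])
  cat("<mul_tree> ", n_tips(x$tree), " leaves (",
      length(unique(x$species)), " species; duplicated: ",
      if (length(dup)) paste(dup, collapse = ", ") else "none", ")\n",
      sep = "")
  invisible(x)
}
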