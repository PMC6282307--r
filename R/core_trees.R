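# Tree and network structures: newick / extended-newick I/O, LCA machinery.
#
# Trees are plain ape "phylo" objects throughout; networks are a light S3
# wrapper ("species_network") around the evonet representation: a tree in
# which each hybrid clade hangs under its first parent, plus a reticulation
# matrix (second-parent node, hybrid node) and the lengths of those
# reticulation edges.

#' Parse a rooted newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()].  Labels, branch
#' lengths and support values are preserved.  Input must be a single rooted
#' newick statement terminated by `;`.
#'
#' @param text A newick string.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick input", call. = FALSE)
  if (!endsWith(text, ";")) {
    stop("newick parse error at position ", nchar(text),
         ": input does not end with ';'", call. = FALSE)
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("newick parse error at position ", i,
           ": unmatched ')'", call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("newick parse error at position ", nchar(text),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: unreadable input", call. = FALSE)
  tr
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @return A newick string that reparses to an isomorphic tree.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

#' Lowest common ancestor of a set of nodes
#'
#' Works for any mix of tips and internal nodes, identified by the integer
#' node ids of the `phylo` edge matrix.  Tips may also be given by label.
#'
#' @param tree A `phylo` object.
#' @param nodes Integer node ids, or a character vector of tip labels.
#' @return The integer id of the unique lowest common ancestor.
#' @export
lca <- function(tree, nodes) {
  stopifnot(inherits(tree, "phylo"))
  if (is.character(nodes)) {
    idx <- match(nodes, tree$tip.label)
    if (anyNA(idx)) stop("unknown tip label(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    nodes <- idx
  }
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 0L) stop("lca of an empty node set", call. = FALSE)
  nn <- n_tips(tree) + tree$Nnode
  if (any(nodes < 1L | nodes > nn)) stop("node id out of range", call. = FALSE)
  parent <- parent_vector(tree)
  anc <- function(v) {            # v and all its ancestors, root last
    out <- v
    while (!is.na(parent[v])) { v <- parent[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(nodes, anc))
  common[1L]                       # lowest first: ancestor chains are bottom-up
}

# parent_vector[v] = parent node id, NA at the root
parent_vector <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  p <- rep(NA_integer_, nn)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# children as a list indexed by node id
children_list <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  ch
}

# node ids in post-order (children before parents)
postorder_nodes <- function(tree) {
  ch <- children_list(tree)
  out <- integer(0)
  stack <- root_node(tree)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, ch[[v]])
  }
  rev(seen)
}

# tip labels below each node, as a list indexed by node id
tips_below <- function(tree) {
  ch <- children_list(tree)
  nt <- n_tips(tree)
  out <- vector("list", nt + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    out[[v]] <- if (v <= nt) tree$tip.label[v] else
      sort(unique(unlist(out[ch[[v]]])))
  }
  out
}

assert_binary <- function(tree, what = "tree") {
  ch <- children_list(tree)
  nt <- n_tips(tree)
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    k <- length(ch[[v]])
    if (k != 2L) {
      stop(what, " must be strictly bifurcating; node ", v, " has ", k,
           " children (resolve polytomies upstream)", call. = FALSE)
    }
  }
  invisible(tree)
}

#' Construct a gene family
#'
#' A gene family couples a rooted gene tree with the map from each gene-copy
#' leaf to its species of origin.  Several copies per species are allowed
#' (homeologs, paralogs).
#'
#' @param tree A rooted binary `phylo` gene tree.
#' @param leaf_to_species Named character vector, names are tip labels of
#'   `tree`, values are species names.  If `NULL`, species are taken as the
#'   tip label with a trailing `_<copy>` suffix stripped.
#' @param gene_name Identifier for the gene (free text).
#' @return An object of class `gene_family`.
#' @export
gene_family <- function(tree, leaf_to_species = NULL, gene_name = "gene") {
  stopifnot(inherits(tree, "phylo"))
  if (n_tips(tree) < 2L) stop("a gene family needs >= 2 leaves", call. = FALSE)
  assert_binary(tree, "gene tree")
  if (is.null(leaf_to_species)) {
    leaf_to_species <- sub("_[^_]*$", "", tree$tip.label)
    names(leaf_to_species) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(leaf_to_species))
  if (length(missing)) {
    stop("leaves without a species mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(leaf_to_species))) stop("empty species name", call. = FALSE)
  structure(list(tree = tree,
                 leaf_to_species = leaf_to_species[tree$tip.label],
                 gene_name = gene_name),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("<gene_family> ", x$gene_name, ": ", n_tips(x$tree), " copies, ",
      length(unique(x$leaf_to_species)), " species\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Extended newick networks

#' Parse an extended-newick species network
#'
#' Accepts the `#H<k>` dialect: each hybridization node is written twice,
#' the first occurrence carrying its subtree, the second as a bare `#H<k>`
#' leaf marking the other parent edge.  At most two hybridization events are
#' supported.
#'
#' @param text An extended-newick string (a plain newick string yields a
#'   network with zero hybridizations).
#' @return An object of class `species_network`: list with `phy` (the tree
#'   part, hybrid clades attached under their first parents; second-parent
#'   attachment points kept as single-child internal nodes), `ret` (matrix
#'   with one row per event: second-parent node, hybrid node), and
#'   `ret_length` (lengths of the reticulation edges, `NA` if absent).
#' @export
parse_enewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  tags <- regmatches(text, gregexpr("#H[0-9]+", text))[[1]]
  tab <- table(tags)
  if (any(tab != 2L)) {
    bad <- names(tab)[tab != 2L]
    stop("hybrid tag(s) ", paste(bad, collapse = ", "),
         " must appear exactly twice", call. = FALSE)
  }
  n_events <- length(tab)
  if (n_events > 2L) {
    stop("unsupported network: ", n_events,
         " hybridization events (at most 2 allowed)", call. = FALSE)
  }
  if (n_events == 0L) {
    phy <- parse_newick(text)
    return(new_species_network(phy,
                               ret = matrix(integer(0), 0, 2),
                               ret_length = numeric(0)))
  }
  # reticulation-edge lengths: the bare (second) occurrence "#Hk:len",
  # i.e. not preceded by ")"; read.evonet drops these lengths.
  ret_len <- vapply(names(tab), function(tg) {
    m <- gregexpr(paste0("(?<![)])", tg, "(:[0-9.eE+-]+)?(?=[,()  ;])"),
                  text, perl = TRUE)[[1]]
    pieces <- regmatches(text, m)[[1]]
    len <- NA_real_
    for (p in pieces) {
      if (grepl(":", p, fixed = TRUE)) {
        len <- as.numeric(sub(paste0("^", tg, ":"), "", p))
      }
    }
    len
  }, numeric(1))
  net <- tryCatch(ape::read.evonet(text = text),
                  error = function(e) stop("extended-newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  phy <- net
  class(phy) <- "phylo"
  ret <- net$reticulation
  phy$reticulation <- NULL
  if (any(!nzchar(phy$tip.label))) {
    stop("second occurrence of a hybrid tag must be a bare leaf with a ",
         "sibling (e.g. \"(#H1,S)\")", call. = FALSE)
  }
  # order ret rows by tag number for stable event ids
  ord <- order(names(tab))
  new_species_network(phy, ret = ret[seq_len(nrow(ret)), , drop = FALSE],
                      ret_length = unname(ret_len[ord]))
}

new_species_network <- function(phy, ret, ret_length) {
  stopifnot(nrow(ret) == length(ret_length))
  x <- structure(list(phy = phy, ret = ret, ret_length = ret_length),
                 class = "species_network")
  validate_species_network(x)
}

validate_species_network <- function(x) {
  k <- nrow(x$ret)
  if (k > 2L) stop("unsupported network: >2 hybridizations", call. = FALSE)
  if (k == 2L) {
    # no stacked events: neither hybrid node ancestral to the other
    p <- parent_vector(x$phy)
    anc <- function(v) { out <- integer(0)
      while (!is.na(p[v])) { v <- p[v]; out <- c(out, v) }; out }
    h <- x$ret[, 2]
    # stacked if either hybrid node is ancestral to the other event's hybrid
    # node or to its second-parent attachment point
    if (h[1] %in% c(anc(h[2]), anc(x$ret[2, 1])) ||
        h[2] %in% c(anc(h[1]), anc(x$ret[1, 1]))) {
      stop("unsupported network: stacked hybridizations", call. = FALSE)
    }
  }
  x
}

#' Number of hybridization events in a network
#' @param net A `species_network`.
#' @export
n_hybridizations <- function(net) nrow(net$ret)

#' @export
print.species_network <- function(x, ...) {
  cat("<species_network> ", length(network_taxa(x)), " taxa, ",
      n_hybridizations(x), " hybridization event(s)\n", sep = "")
  invisible(x)
}

#' Taxa of a species network
#' @param net A `species_network`.
#' @export
network_taxa <- function(net) sort(net$phy$tip.label)

# Decompose a network into (pruned backbone, events).  Each event:
#   clade      phylo (or single tip label) below the hybrid node
#   parent1/2  backbone edge ids ("taxa-below" strings) of the attachment
#              edges (first parent = tree parent of the hybrid node)
# Edge ids name the sorted backbone taxa below the edge, joined by "|".
network_events <- function(net) {
  phy <- net$phy
  k <- n_hybridizations(net)
  tb <- tips_below(phy)
  hyb_nodes <- net$ret[, 2]
  hyb_taxa <- unlist(lapply(hyb_nodes, function(h) tb[[h]]))
  backbone_taxa <- setdiff(phy$tip.label, hyb_taxa)
  edge_id_of <- function(node) {
    below <- setdiff(tb[[node]], hyb_taxa)
    if (length(below) == 0L)
      stop("attachment edge carries no backbone taxa", call. = FALSE)
    paste(sort(below), collapse = "|")
  }
  p <- parent_vector(phy)
  events <- vector("list", k)
  for (i in seq_len(k)) {
    h <- hyb_nodes[i]
    clade_tips <- tb[[h]]
    clade <- if (length(clade_tips) == 1L) clade_tips else
      ape::keep.tip(phy, clade_tips)
    # first parent edge: the edge the hybrid clade subdivides on the tree side.
    # After removing the clade, the hybrid's parent becomes single-child; the
    # edge it sits on is identified by the backbone taxa below that parent.
    events[[i]] <- list(clade = clade,
                        parent1 = edge_id_of(p[h]),
                        parent2 = edge_id_of(net$ret[i, 1]),
                        ret_length = net$ret_length[i])
  }
  backbone <- ape::keep.tip(phy, backbone_taxa)
  list(backbone = backbone, events = events)
}
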