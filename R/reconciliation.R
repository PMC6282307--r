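# Duplication-loss reconciliation of a gene family against a species tree
# or MUL tree, minimizing over homeolog-to-subgenome leaf assignments.
#
# The score of a hypothesis is the classical LCA duplication-loss cost of
# each gene tree against the hypothesis' MUL-tree expansion, minimized over
# all ways of assigning each gene copy of a repeated (polyploid) species to
# one of that species' MUL leaves.  Losses are charged on the host tree
# restricted to the subtree spanning the images of the sampled leaves, so
# taxa unsampled in a family contribute no loss.

#' Duplication and loss costs
#'
#' @param dup,loss Nonnegative event costs (both default to 1).
#' @return A `recon_costs` object.
#' @export
recon_costs <- function(dup = 1, loss = 1) {
  stopifnot(is.numeric(dup), is.numeric(loss), dup >= 0, loss >= 0)
  structure(list(dup = dup, loss = loss), class = "recon_costs")
}

# --- internal prepared structures ------------------------------------------

# host side: works for a mul_tree or a plain phylo species tree
host_struct <- function(host) {
  if (inherits(host, "mul_tree")) {
    tree <- host$tree; species <- host$species; tag <- host$copy_tag
  } else if (inherits(host, "phylo")) {
    tree <- host; species <- host$tip.label
    tag <- rep(NA_character_, n_tips(host))
  } else stop("host must be a mul_tree or phylo", call. = FALSE)
  assert_binary(tree, "host tree")
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  parent <- parent_vector(tree)
  ch <- children_list(tree)
  kids <- matrix(0L, nn, 2)
  for (v in (nt + 1L):nn) kids[v, ] <- ch[[v]]
  po <- postorder_nodes(tree)
  depth <- integer(nn)
  for (v in rev(po)) depth[v] <- if (is.na(parent[v])) 0L else depth[parent[v]] + 1L
  list(tree = tree, species = species, tag = tag, n_tips = nt, n_nodes = nn,
       parent = parent, kids = kids, po = po, depth = depth)
}

gene_struct <- function(family) {
  tree <- family$tree
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  ch <- children_list(tree)
  kids <- matrix(0L, nn, 2)
  for (v in (nt + 1L):nn) kids[v, ] <- ch[[v]]
  list(tree = tree, n_tips = nt, n_nodes = nn, kids = kids,
       po = postorder_nodes(tree), species = family$leaf_to_species)
}

# leaf images under an assignment; returns integer vector over gene tips.
# assignment: named character ("A"/"B") for leaves of repeated species.
leaf_images <- function(gs, hs, assignment) {
  img <- integer(gs$n_tips)
  for (i in seq_len(gs$n_tips)) {
    sp <- gs$species[i]
    cand <- which(hs$species[seq_len(hs$n_tips)] == sp)
    if (length(cand) == 0L)
      stop("species missing from host: ", sp, call. = FALSE)
    if (length(cand) == 1L) { img[i] <- cand; next }
    lab <- gs$tree$tip.label[i]
    tag <- assignment[[lab]]
    if (is.null(tag) || is.na(tag))
      stop("no assignment for ambiguous leaf '", lab, "'", call. = FALSE)
    hit <- cand[hs$tag[cand] == tag]
    if (length(hit) != 1L)
      stop("no host leaf ", sp, ":", tag, call. = FALSE)
    img[i] <- hit
  }
  img
}

# host LCA by parent climbing
host_lca <- function(hs, a, b) {
  while (a != b) {
    if (hs$depth[a] >= hs$depth[b]) a <- hs$parent[a] else b <- hs$parent[b]
  }
  a
}

# core scorer: LCA map + duplication/loss counts on the induced host tree
recon_score <- function(gs, hs, img_leaf) {
  cnt <- integer(hs$n_nodes)
  for (i in seq_len(gs$n_tips)) cnt[img_leaf[i]] <- cnt[img_leaf[i]] + 1L
  branching <- logical(hs$n_nodes)
  for (v in hs$po) {
    if (v > hs$n_tips) {
      k1 <- hs$kids[v, 1]; k2 <- hs$kids[v, 2]
      cnt[v] <- cnt[v] + cnt[k1] + cnt[k2]
      branching[v] <- cnt[k1] > 0L && cnt[k2] > 0L
    }
  }
  idepth <- integer(hs$n_nodes)
  for (v in rev(hs$po)) {
    p <- hs$parent[v]
    if (!is.na(p)) idepth[v] <- idepth[p] + as.integer(branching[p])
  }
  img <- integer(gs$n_nodes)
  img[seq_len(gs$n_tips)] <- img_leaf
  is_dup <- logical(gs$n_nodes)
  D <- 0L; L <- 0L
  for (g in gs$po) {
    if (g <= gs$n_tips) next
    c1 <- gs$kids[g, 1]; c2 <- gs$kids[g, 2]
    m <- host_lca(hs, img[c1], img[c2])
    img[g] <- m
    dup <- (m == img[c1]) || (m == img[c2])
    is_dup[g] <- dup
    D <- D + as.integer(dup)
    for (cc in c(c1, c2)) {
      k <- idepth[img[cc]] - idepth[m]
      L <- L + k - if (dup) 0L else 1L
    }
  }
  list(node_map = img, is_dup = is_dup, D = D, L = L)
}

new_recon_result <- function(gs, hs, sc, assignment, costs, gene_name) {
  structure(list(
    node_map = sc$node_map,
    is_duplication = sc$is_dup,
    n_duplications = sc$D,
    n_losses = sc$L,
    total_cost = costs$dup * sc$D + costs$loss * sc$L,
    assignment = assignment,
    costs = costs,
    gene_name = gene_name),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> ", x$gene_name, ": ", x$n_duplications,
      " duplication(s), ", x$n_losses, " loss(es), cost ", x$total_cost,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.recon_result <- function(x, ...) {
  tibble::tibble(gene = x$gene_name,
                 n_duplications = x$n_duplications,
                 n_losses = x$n_losses,
                 total_cost = x$total_cost)
}

#' LCA duplication-loss reconciliation under a fixed leaf assignment
#'
#' Maps every gene-tree node to the lowest common ancestor of its
#' descendants' host images.  A gene node is a duplication iff its image
#' equals a child's image.  Losses along a gene edge are the number of
#' induced-host-tree edges traversed, minus one at speciation nodes; the
#' host tree is first restricted to the subtree spanning the images of the
#' sampled leaves, so species absent from the family contribute no losses.
#'
#' @param family A [gene_family()].
#' @param host A `mul_tree` or a binary `phylo` species tree.
#' @param assignment Named character vector mapping each gene leaf of a
#'   repeated species to a subgenome copy (`"A"` or `"B"`).  `NULL` if no
#'   species is repeated in the host.
#' @param costs A [recon_costs()].
#' @return A `recon_result` with the node map, event counts, and total cost.
#' @examples
#' fam <- gene_family(parse_newick("((a,c),b);"),
#'                    c(a = "A", b = "B", c = "C"))
#' lca_reconcile(fam, parse_newick("((A,B),C);"))
#' @export
lca_reconcile <- function(family, host, assignment = NULL,
                          costs = recon_costs()) {
  stopifnot(inherits(family, "gene_family"))
  gs <- gene_struct(family)
  hs <- host_struct(host)
  img <- leaf_images(gs, hs, assignment)
  sc <- recon_score(gs, hs, img)
  new_recon_result(gs, hs, sc, assignment, costs, family$gene_name)
}

# ambiguous gene leaves (species repeated in host), ordered by label
ambiguous_leaves <- function(gs, hs) {
  rep_species <- unique(hs$species[seq_len(hs$n_tips)][!is.na(hs$tag)])
  idx <- which(gs$species %in% rep_species)
  idx[order(gs$tree$tip.label[idx])]
}

#' Exhaustive minimum reconciliation cost over all leaf assignments
#'
#' Reference implementation: enumerates all `2^m` assignments of the `m`
#' ambiguous gene leaves (pure R, one [lca_reconcile()] call each) and
#' returns the minimum-cost result, taking the lexicographically smallest
#' assignment (leaves ordered by label, `A < B`) among ties.  Intended as a
#' testing oracle for [mul_reconcile()]; refuses `m > 20`.
#'
#' @inheritParams lca_reconcile
#' @param mul A `mul_tree`.
#' @return A `recon_result`.
#' @export
brute_force_mul_score <- function(family, mul, costs = recon_costs()) {
  stopifnot(inherits(family, "gene_family"), inherits(mul, "mul_tree"))
  gs <- gene_struct(family)
  hs <- host_struct(mul)
  amb <- ambiguous_leaves(gs, hs)
  m <- length(amb)
  if (m > 20L) stop("refusing exhaustive search over 2^", m,
                    " assignments (m > 20)", call. = FALSE)
  labs <- gs$tree$tip.label[amb]
  best <- NULL
  for (a in seq_len(2^m) - 1L) {
    bits <- if (m) as.integer(intToBits(a))[m:1] else integer(0)
    assignment <- stats::setNames(c("A", "B")[bits + 1L], labs)
    res <- lca_reconcile(family, mul, assignment, costs)
    if (is.null(best) || res$total_cost < best$total_cost) best <- res
  }
  best
}

#' Minimum-cost reconciliation against a MUL tree
#'
#' Returns the reconciliation of minimum total cost over all assignments of
#' gene copies of repeated species to subgenome leaf copies.  The search is
#' an exact enumeration in compiled code; ties are broken by the
#' lexicographically smallest assignment (ambiguous leaves ordered by
#' label, `A < B`), so output is deterministic.
#'
#' @inheritParams brute_force_mul_score
#' @return A `recon_result` carrying the optimal assignment.
#' @examples
#' mul <- build_mul_tree(parse_newick("((P,S),O);"), "H", "P", "S")
#' fam <- gene_family(parse_newick("((h1,p),(h2,s));"),
#'                    c(h1 = "H", h2 = "H", p = "P", s = "S"))
#' mul_reconcile(fam, mul)$total_cost  # 0
#' @export
mul_reconcile <- function(family, mul, costs = recon_costs()) {
  stopifnot(inherits(family, "gene_family"), inherits(mul, "mul_tree"))
  gs <- gene_struct(family)
  hs <- host_struct(mul)
  mul_reconcile_prepared(family, gs, hs, costs)
}

# internal: minimum over assignments via the compiled enumeration; returns
# the raw optimum (bits over ambiguous leaves, counts, cost)
mul_min_search <- function(gs, hs, costs) {
  amb <- ambiguous_leaves(gs, hs)
  m <- length(amb)
  if (m > 25L) stop("too many ambiguous leaves (", m, ")", call. = FALSE)
  host_sp <- hs$species[seq_len(hs$n_tips)]
  img_fixed <- integer(gs$n_tips)
  for (i in seq_len(gs$n_tips)) {
    cand <- which(host_sp == gs$species[i])
    if (length(cand) == 0L)
      stop("species missing from host: ", gs$species[i], call. = FALSE)
    if (length(cand) == 1L) img_fixed[i] <- cand
  }
  optA <- optB <- integer(m)
  for (j in seq_len(m)) {
    cand <- which(host_sp == gs$species[amb[j]])
    optA[j] <- cand[hs$tag[cand] == "A"]
    optB[j] <- cand[hs$tag[cand] == "B"]
  }
  hparent <- hs$parent; hparent[is.na(hparent)] <- 0L
  out <- cpp_min_assignment(gs$kids, gs$po, gs$n_tips, img_fixed,
                            amb, optA, optB,
                            hparent, hs$kids, hs$po, hs$depth,
                            hs$n_tips, costs$dup, costs$loss)
  list(amb = amb, optA = optA, optB = optB, img_fixed = img_fixed,
       bits = out$bits, D = out$D, L = out$L, cost = out$cost)
}

# internal: full result from prepared structures, cross-checked against the
# pure-R scorer
mul_reconcile_prepared <- function(family, gs, hs, costs) {
  out <- mul_min_search(gs, hs, costs)
  assignment <- stats::setNames(c("A", "B")[out$bits + 1L],
                                gs$tree$tip.label[out$amb])
  img <- out$img_fixed
  img[out$amb] <- ifelse(out$bits == 1L, out$optB, out$optA)
  sc <- recon_score(gs, hs, img)
  stopifnot(sc$D == out$D, sc$L == out$L)  # C++/R scorer agreement
  new_recon_result(gs, hs, sc, assignment, costs, family$gene_name)
}

#' Total reconciliation score of a hypothesis
#'
#' Sums the assignment-minimized reconciliation cost of every gene family
#' against the hypothesis' MUL tree.
#'
#' @param mul A `mul_tree`.
#' @param families List of [gene_family()] objects (at least one).
#' @param costs A [recon_costs()].
#' @param .gene_structs Internal: pre-computed gene structures, used by
#'   [run_scan()] to avoid repeated preparation across hypotheses.
#' @return A `hypothesis_score`: list with `total_score` and a tibble
#'   `per_family` of per-gene costs and event counts.
#' @export
score_hypothesis <- function(mul, families, costs = recon_costs(),
                             .gene_structs = NULL) {
  stopifnot(inherits(mul, "mul_tree"), length(families) >= 1L)
  hs <- host_struct(mul)
  if (is.null(.gene_structs)) .gene_structs <- lapply(families, gene_struct)
  nf <- length(families)
  cost <- D <- L <- numeric(nf)
  for (i in seq_len(nf)) {
    out <- mul_min_search(.gene_structs[[i]], hs, costs)
    cost[i] <- out$cost; D[i] <- out$D; L[i] <- out$L
  }
  per_family <- tibble::tibble(
    gene = vapply(families, function(f) f$gene_name, character(1)),
    cost = cost, n_duplications = D, n_losses = L)
  structure(list(per_family = per_family,
                 total_score = sum(cost)),
            class = "hypothesis_score")
}

#' @export
print.hypothesis_score <- function(x, ...) {
  cat("<hypothesis_score> total", x$total_score, "over",
      nrow(x$per_family), "families\n")
  invisible(x)
}

#' @export
tidy.hypothesis_score <- function(x, ...) x$per_family

#' @export
glance.hypothesis_score <- function(x, ...) {
  tibble::tibble(n_families = nrow(x$per_family),
                 total_score = x$total_score)
}
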