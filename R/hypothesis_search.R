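# Enumeration and ranking of allopolyploidy hypotheses: tree-only
# backbones (no hybridization), all one-event networks, and all two-event
# networks obtained by splitting the polyploid clade at its root, with
# attachment edges drawn from the backbone pruned of the polyploid clade
# and at least one parent edge pendant to a candidate diploid lineage.

mul_from_species_tree <- function(tree) {
  assert_binary(tree, "backbone")
  tree$edge.length <- NULL
  structure(list(tree = tree, species = tree$tip.label,
                 copy_tag = rep(NA_character_, n_tips(tree)),
                 event = rep(NA_integer_, n_tips(tree)),
                 backbone = tree, events = list()),
            class = "mul_tree")
}

new_hypothesis <- function(label, n_events, mul, events) {
  structure(list(label = label, n_events = n_events, mul = mul,
                 events = events), class = "hypothesis")
}

#' @export
print.hypothesis <- function(x, ...) {
  cat("<hypothesis> ", x$label, " (", x$n_events, " event(s))\n", sep = "")
  invisible(x)
}

# check monophyly and split a backbone into (pruned backbone, clade)
split_polyploid <- function(backbone, polyploid_taxa) {
  stopifnot(inherits(backbone, "phylo"))
  polyploid_taxa <- as.character(polyploid_taxa)
  missing <- setdiff(polyploid_taxa, backbone$tip.label)
  if (length(missing))
    stop("polyploid taxa absent from backbone: ",
         paste(missing, collapse = ", "), call. = FALSE)
  anc <- lca(backbone, polyploid_taxa)
  below <- tips_below(backbone)[[anc]]
  if (!setequal(below, polyploid_taxa))
    stop("polyploid taxa are not monophyletic in the backbone ",
         "(clade also contains: ",
         paste(setdiff(below, polyploid_taxa), collapse = ", "), ")",
         call. = FALSE)
  clade <- if (length(polyploid_taxa) == 1L) polyploid_taxa else
    ape::keep.tip(backbone, polyploid_taxa)
  pruned <- ape::drop.tip(backbone, polyploid_taxa)
  list(pruned = pruned, clade = clade)
}

# attachment-edge pairs on a pruned backbone: unordered pairs of distinct
# edges with at least one pendant edge of a candidate parent
qualifying_pairs <- function(pruned, candidate_parents) {
  candidate_parents <- as.character(candidate_parents)
  if (length(candidate_parents) == 0L)
    stop("candidate_parents must be non-empty", call. = FALSE)
  missing <- setdiff(candidate_parents, pruned$tip.label)
  if (length(missing))
    stop("candidate parents absent from backbone: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- sort(edge_ids(pruned))
  pend <- intersect(ids, candidate_parents)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  keep <- vapply(pairs, function(p) any(p %in% pend), logical(1))
  pairs[keep]
}

#' Enumerate no-hybridization hypotheses
#'
#' One zero-event hypothesis per backbone tree (the polyploid taxa sit in
#' the backbone at the position implied by one subgenome's topology).
#' Labels are `T1`, `T2`, ... in input order.
#'
#' @param backbones List of binary `phylo` trees containing all species.
#' @return List of `hypothesis` objects.
#' @export
enumerate_no_event <- function(backbones) {
  lapply(seq_along(backbones), function(i)
    new_hypothesis(paste0("T", i), 0L,
                   mul_from_species_tree(backbones[[i]]), list()))
}

#' Enumerate one-hybridization hypotheses
#'
#' The polyploid clade (which must be monophyletic in `backbone`) is
#' treated as a unit and grafted into every qualifying unordered pair of
#' distinct edges of the backbone pruned of the clade; a pair qualifies if
#' at least one of its edges is the pendant edge of a candidate parent.
#'
#' @param backbone Binary `phylo` containing all species.
#' @param polyploid_taxa Character vector of polyploid taxa (a clade in
#'   `backbone`).
#' @param candidate_parents Non-empty character vector of candidate diploid
#'   parent taxa (disjoint from `polyploid_taxa`).
#' @return List of `hypothesis` objects labelled `N1:<edge1>x<edge2>`.
#' @export
enumerate_one_event <- function(backbone, polyploid_taxa, candidate_parents) {
  if (length(intersect(polyploid_taxa, candidate_parents)))
    stop("candidate parents must be disjoint from polyploid taxa",
         call. = FALSE)
  sp <- split_polyploid(backbone, polyploid_taxa)
  pairs <- qualifying_pairs(sp$pruned, candidate_parents)
  lapply(pairs, function(p) {
    ev <- list(clade = sp$clade, parent1 = p[1], parent2 = p[2])
    new_hypothesis(paste0("N1:", p[1], "x", p[2]), 1L,
                   mul_from_events(sp$pruned, list(ev)), list(ev))
  })
}

#' Enumerate two-hybridization hypotheses
#'
#' The polyploid clade is split into the two subclades at its root; each
#' subclade independently receives a qualifying attachment-edge pair (same
#' rule as [enumerate_one_event()]); the cross-product is emitted,
#' deduplicated by label.
#'
#' @inheritParams enumerate_one_event
#' @return List of `hypothesis` objects.
#' @export
enumerate_two_event <- function(backbone, polyploid_taxa, candidate_parents) {
  if (length(polyploid_taxa) < 2L)
    stop("two-event enumeration needs >= 2 polyploid taxa", call. = FALSE)
  if (length(intersect(polyploid_taxa, candidate_parents)))
    stop("candidate parents must be disjoint from polyploid taxa",
         call. = FALSE)
  sp <- split_polyploid(backbone, polyploid_taxa)
  clade <- sp$clade
  kids <- children_list(clade)[[root_node(clade)]]
  subclades <- lapply(kids, function(k) {
    tips <- tips_below(clade)[[k]]
    if (length(tips) == 1L) tips else ape::keep.tip(clade, tips)
  })
  pairs <- qualifying_pairs(sp$pruned, candidate_parents)
  out <- list()
  for (p1 in pairs) for (p2 in pairs) {
    ev1 <- list(clade = subclades[[1]], parent1 = p1[1], parent2 = p1[2])
    ev2 <- list(clade = subclades[[2]], parent1 = p2[1], parent2 = p2[2])
    lab <- paste0("N2:", p1[1], "x", p1[2], "|", p2[1], "x", p2[2])
    out[[lab]] <- new_hypothesis(lab, 2L,
                                 mul_from_events(sp$pruned, list(ev1, ev2)),
                                 list(ev1, ev2))
  }
  unname(out)
}

#' Score and rank all allopolyploidy hypotheses
#'
#' Scores the no-event backbones first, takes the better backbone as the
#' base for one- and two-event enumeration, scores every hypothesis against
#' the gene families, and ranks by total reconciliation score.  The
#' *preferred* hypothesis is the one with the fewest hybridization events
#' whose score lies within `delta_threshold` of the global minimum — the
#' parsimony argument that a marginal score improvement does not justify an
#' extra reticulation.
#'
#' @param backbones List of binary `phylo` trees (all species placed; e.g.
#'   one per subgenome topology).
#' @param polyploid_taxa Character vector of polyploid taxa.
#' @param candidate_parents Character vector of candidate diploid parents.
#' @param families List of [gene_family()] objects.
#' @param costs A [recon_costs()].
#' @param delta_threshold Score slack within which a simpler hypothesis is
#'   preferred over the absolute best (default 5).
#' @param max_events Enumerate hypotheses with up to this many
#'   hybridizations (0, 1 or 2; default 2, automatically lowered to 1 when
#'   the polyploid clade has a single taxon).
#' @return A `scan_report`: list with `ranking` (tibble: label, n_events,
#'   total_score, delta), `best_per_events`, `preferred`, `min_score`, and
#'   the scored `hypotheses`.
#' @export
run_scan <- function(backbones, polyploid_taxa, candidate_parents, families,
                     costs = recon_costs(), delta_threshold = 5,
                     max_events = 2L) {
  stopifnot(length(backbones) >= 1L, length(families) >= 1L)
  gstructs <- lapply(families, gene_struct)
  hyps <- enumerate_no_event(backbones)
  scores0 <- vapply(hyps, function(h)
    score_hypothesis(h$mul, families, costs,
                     .gene_structs = gstructs)$total_score, numeric(1))
  base <- backbones[[which.min(scores0)]]
  if (max_events >= 1L)
    hyps <- c(hyps, enumerate_one_event(base, polyploid_taxa,
                                        candidate_parents))
  if (max_events >= 2L && length(polyploid_taxa) >= 2L)
    hyps <- c(hyps, enumerate_two_event(base, polyploid_taxa,
                                        candidate_parents))
  scored <- lapply(hyps, function(h) {
    h$score <- score_hypothesis(h$mul, families, costs,
                                .gene_structs = gstructs)
    h
  })
  ranking <- tibble::tibble(
    label = vapply(scored, function(h) h$label, character(1)),
    n_events = vapply(scored, function(h) h$n_events, integer(1)),
    total_score = vapply(scored, function(h) h$score$total_score, numeric(1))
  )
  ranking <- dplyr::arrange(ranking, .data$total_score, .data$n_events,
                            .data$label)
  min_score <- min(ranking$total_score)
  ranking$delta <- ranking$total_score - min_score
  best_per_events <- dplyr::slice_min(
    dplyr::group_by(ranking, .data$n_events),
    order_by = .data$total_score, n = 1, with_ties = FALSE)
  best_per_events <- dplyr::ungroup(best_per_events)
  within <- dplyr::filter(ranking, .data$delta <= delta_threshold)
  preferred <- dplyr::arrange(within, .data$n_events, .data$total_score,
                              .data$label)$label[1]
  structure(list(ranking = ranking,
                 best_per_events = best_per_events,
                 preferred = preferred,
                 min_score = min_score,
                 delta_threshold = delta_threshold,
                 hypotheses = scored),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report> ", nrow(x$ranking), " hypotheses; best score ",
      x$min_score, "; preferred: ", x$preferred, "\n", sep = "")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' @export
tidy.scan_report <- function(x, ...) x$ranking

#' @export
glance.scan_report <- function(x, ...) {
  tibble::tibble(n_hypotheses = nrow(x$ranking),
                 min_score = x$min_score,
                 preferred = x$preferred,
                 delta_threshold = x$delta_threshold)
}

#' Plot hypothesis scores by number of hybridization events
#'
#' @param x A `scan_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_report <- function(x, ...) {
  df <- x$ranking
  df$preferred <- df$label == x$preferred
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_events),
                                   y = .data$total_score)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$preferred),
                         width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "hybridization events",
                  y = "total reconciliation score",
                  colour = "preferred") +
    ggplot2::theme_minimal()
}
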