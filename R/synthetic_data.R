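# Generators producing inputs with the statistical structure each pipeline
# stage assumes: gene families evolving by a duplication-loss birth-death
# process along a species network with true genome mergers at hybridization
# nodes; discrete traits evolving under a known Mk rate matrix; genotype
# matrices with diverged groups and missing calls.

#' A small allopolyploid species network
#'
#' Fixed eight-taxon network used throughout the examples and tests: six
#' diploid backbone taxa (`P`, `D1`, `S`, `D2`, `D3`, outgroup `O`) and a
#' two-taxon polyploid clade (`H1`, `H2`) arising from a single
#' hybridization between the lineages of `P` (A subgenome) and `S`
#' (B subgenome).  All edges have length 0.25 time units, so at the default
#' simulation rates (0.2 events per copy per unit time) a family of ~10
#' copies accumulates roughly one duplication and one loss — polyploids
#' retain a homeolog pair in most families, with occasional extra copies
#' or losses.
#'
#' @return A `species_network`.
#' @export
toy_allopolyploid_network <- function() {
  parse_enewick(paste0(
    "((((P:0.25,((H1:0.25,H2:0.25):0.25)#H1:0.25):0.25,D1:0.25):0.25,",
    "((#H1:0.25,S:0.25):0.25,D2:0.25):0.25):0.25,",
    "(D3:0.25,O:0.25):0.25);"))
}

#' Graft a clade once into a tree edge
#'
#' Inserts `clade` into the edge identified by `edge` (a new node
#' subdivides the edge), producing an ordinary species tree.  Useful for
#' building the no-hybridization backbones in which the polyploid taxa sit
#' at the position of one subgenome.
#'
#' @param tree Binary `phylo`.
#' @param clade A `phylo` or single taxon label, taxa disjoint from
#'   `tree`'s.
#' @param edge A backbone edge id (see [edge_ids()]).
#' @return A `phylo` tree.
#' @export
graft_clade <- function(tree, clade, edge) {
  stopifnot(inherits(tree, "phylo"))
  ids <- edge_ids(tree)
  if (!edge %in% ids) stop("no edge with id '", edge, "'", call. = FALSE)
  newtaxa <- clade_taxa(clade)
  if (length(intersect(newtaxa, tree$tip.label)))
    stop("clade taxa overlap the tree's taxa", call. = FALSE)
  ctxt <- if (is.character(clade)) clade else {
    render <- function(v, ch) {
      if (v <= n_tips(clade)) return(clade$tip.label[v])
      paste0("(", paste(vapply(ch[[v]], render, character(1), ch = ch),
                        collapse = ","), ")")
    }
    render(root_node(clade), children_list(clade))
  }
  ins <- stats::setNames(list(ctxt), edge)
  txt <- paste0(subtree_text(tree, root_node(tree), children_list(tree),
                             tips_below(tree), ins), ";")
  parse_newick(txt)
}

# --- gene-family birth-death simulation ------------------------------------

# network as a processable node/edge structure: tree edges plus
# reticulation edges (second parent -> hybrid node)
network_edges <- function(net) {
  phy <- net$phy
  e <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                  length = if (is.null(phy$edge.length))
                    rep(1, nrow(phy$edge)) else phy$edge.length)
  if (nrow(net$ret)) {
    rl <- ifelse(is.na(net$ret_length), 0, net$ret_length)
    e <- rbind(e, data.frame(parent = net$ret[, 1], child = net$ret[, 2],
                             length = rl))
  }
  e
}

#' Simulate gene families along a species network
#'
#' A single ancestral gene enters at the network root and evolves tipward.
#' Along every edge each copy undergoes duplications (rate `dup_rate`) and
#' losses (rate `loss_rate`) as a Poisson birth-death process per unit
#' branch length.  At a hybridization node the hybrid inherits every
#' extant copy from each parental lineage (a genome merger, not a choice
#' of one parent).  Families with fewer than two surviving copies are
#' redrawn (conditioning on reconcilable families).  Leaf labels are
#' `<species>_<copy index>`.
#'
#' @param network A `species_network` with branch lengths.
#' @param n_families Number of independent families to generate.
#' @param dup_rate,loss_rate Events per gene copy per unit branch length.
#' @param gene_names Optional names (defaults to `fam1`, `fam2`, ...).
#' @param seed Optional integer seed.
#' @return A list of [gene_family()] objects; each carries a `truth`
#'   attribute with the realized duplication and loss event counts.
#' @export
simulate_gene_families <- function(network, n_families = 4,
                                   dup_rate = 0.2, loss_rate = 0.2,
                                   gene_names = NULL, seed = NULL) {
  stopifnot(inherits(network, "species_network"),
            dup_rate >= 0, loss_rate >= 0, n_families >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_names)) gene_names <- paste0("fam", seq_len(n_families))
  ed <- network_edges(network)
  phy <- network$phy
  nt <- n_tips(phy)
  out_edges <- split(seq_len(nrow(ed)), factor(ed$parent,
                                               levels = seq_len(nt + phy$Nnode)))
  root <- root_node(phy)
  lapply(seq_len(n_families), function(i) {
    for (try in seq_len(1000)) {
      counter <- new.env()
      counter$dup <- 0L; counter$loss <- 0L
      frag <- sim_from_node(root, phy, ed, out_edges, dup_rate, loss_rate,
                            counter)
      if (is.null(frag)) next
      labels <- fragment_leaves(frag)
      if (length(labels) < 2L) next
      txt <- paste0(fragment_newick(frag, species_counter = new.env()), ";")
      tree <- parse_newick(txt)
      sp <- sub("_[0-9]+$", "", tree$tip.label)
      fam <- gene_family(tree, stats::setNames(sp, tree$tip.label),
                         gene_name = gene_names[i])
      attr(fam, "truth") <- list(n_duplications = counter$dup,
                                 n_losses = counter$loss)
      return(fam)
    }
    stop("no non-trivial family in 1000 draws (loss rate too high?)",
         call. = FALSE)
  })
}

# fragment: list(species=..) for a leaf, or list(children=list(...)) for an
# internal node; both carry brlen (edge length above)
sim_from_node <- function(v, phy, ed, out_edges, lambda, mu, counter) {
  oe <- out_edges[[v]]
  if (length(oe) == 0L) {                      # network tip: a sampled copy
    return(list(species = phy$tip.label[v], brlen = 0))
  }
  frags <- list()
  for (e in oe) {
    f <- sim_along_edge(ed$length[e], ed$child[e], phy, ed, out_edges,
                        lambda, mu, counter)
    if (!is.null(f)) frags[[length(frags) + 1L]] <- f
  }
  if (length(frags) == 0L) return(NULL)
  if (length(frags) == 1L) return(frags[[1]])  # unary point: suppressed
  list(children = frags, brlen = 0)
}

sim_along_edge <- function(len, child, phy, ed, out_edges, lambda, mu,
                           counter) {
  rate <- lambda + mu
  t <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (t >= len) {
    f <- sim_from_node(child, phy, ed, out_edges, lambda, mu, counter)
    if (is.null(f)) return(NULL)
    f$brlen <- f$brlen + len
    return(f)
  }
  if (stats::runif(1) < lambda / rate) {       # duplication
    counter$dup <- counter$dup + 1L
    f1 <- sim_along_edge(len - t, child, phy, ed, out_edges, lambda, mu,
                         counter)
    f2 <- sim_along_edge(len - t, child, phy, ed, out_edges, lambda, mu,
                         counter)
    surv <- Filter(Negate(is.null), list(f1, f2))
    if (length(surv) == 0L) return(NULL)
    if (length(surv) == 1L) {
      f <- surv[[1]]; f$brlen <- f$brlen + t
      return(f)
    }
    return(list(children = surv, brlen = t))
  }
  counter$loss <- counter$loss + 1L            # loss
  NULL
}

fragment_leaves <- function(frag) {
  if (!is.null(frag$species)) return(frag$species)
  unlist(lapply(frag$children, fragment_leaves))
}

fragment_newick <- function(frag, species_counter) {
  if (!is.null(frag$species)) {
    k <- get0(frag$species, envir = species_counter, ifnotfound = 0L) + 1L
    assign(frag$species, k, envir = species_counter)
    return(sprintf("%s_%d:%g", frag$species, k, frag$brlen))
  }
  inner <- vapply(frag$children, fragment_newick, character(1),
                  species_counter = species_counter)
  sprintf("(%s):%g", paste(inner, collapse = ","), frag$brlen)
}

# --- trait simulation -------------------------------------------------------

#' Simulate a discrete trait along a tree under an Mk model
#'
#' Forward simulation: the root state is drawn from the model's root
#' prior, then the state evolves along every branch as a continuous-time
#' Markov jump process.  The full history is returned alongside the tip
#' states, as ground truth for ancestral-reconstruction checks.
#'
#' @param tree Binary `phylo` with branch lengths.
#' @param model An [mk_model()].
#' @param seed Optional integer seed.
#' @return List with `data` (tibble: taxon, state) and `history` (a
#'   `simmap_history`).
#' @export
simulate_trait <- function(tree, model, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  assert_branch_lengths(tree)
  if (!is.null(seed)) set.seed(seed)
  k <- length(model$states)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  parent <- parent_vector(tree)
  st <- integer(nn)
  r <- root_node(tree)
  st[r] <- sample.int(k, 1, prob = model$root_prior)
  maps <- vector("list", nrow(tree$edge))
  edge_of <- integer(nn)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  n_changes <- 0L
  for (v in rev(postorder_nodes(tree))) {
    if (v == r) next
    e <- edge_of[v]
    len <- tree$edge.length[e]
    s <- st[parent[v]]
    times <- numeric(0); states <- s
    pos <- 0
    repeat {
      out_rate <- -model$Q[s, s]
      if (out_rate <= 0) break
      pos <- pos + stats::rexp(1, out_rate)
      if (pos >= len) break
      w <- model$Q[s, ]; w[s] <- 0
      s <- sample.int(k, 1, prob = w)
      times <- c(times, pos); states <- c(states, s)
      n_changes <- n_changes + 1L
    }
    st[v] <- s
    seg <- diff(c(0, times, len))
    names(seg) <- model$states[states]
    maps[[e]] <- seg
  }
  dwell <- stats::setNames(numeric(k), model$states)
  for (seg in maps)
    for (i in seq_along(seg))
      dwell[names(seg)[i]] <- dwell[names(seg)[i]] + seg[i]
  history <- structure(list(tree = tree,
                            node_states = model$states[st],
                            maps = maps, n_changes = n_changes,
                            dwell = dwell, states = model$states),
                       class = "simmap_history")
  list(data = tibble::tibble(taxon = tree$tip.label,
                             state = model$states[st[seq_len(nt)]]),
       history = history)
}

# --- genotype simulation ----------------------------------------------------

#' Simulate structured biallelic genotypes
#'
#' Ancestral allele frequencies are drawn uniformly in `maf_range`; each
#' group's frequency is drawn from a Balding-Nichols beta distribution
#' with divergence `fst` around the ancestral value; genotypes are
#' binomial(2, group frequency); calls are masked missing independently at
#' `missing_rate`.
#'
#' @param n_groups Number of diverged groups.
#' @param n_per_group Samples per group.
#' @param n_snps Number of biallelic variants.
#' @param fst Group divergence in `[0, 1)` (0 = panmixia).
#' @param missing_rate Per-call missingness probability.
#' @param maf_range Range of ancestral allele frequencies.
#' @param vcf_path Optional path; when given the genotypes are also
#'   written as a VCF file.
#' @param seed Optional integer seed.
#' @return List with `genotypes` (a [genotype_matrix()]), `labels`
#'   (tibble: sample, group) and `vcf_path`.
#' @export
simulate_genotypes <- function(n_groups = 3, n_per_group = 20,
                               n_snps = 500, fst = 0.3,
                               missing_rate = 0, maf_range = c(0.05, 0.5),
                               vcf_path = NULL, seed = NULL) {
  stopifnot(n_groups >= 1, n_per_group >= 1, n_snps >= 1,
            fst >= 0, fst < 1, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_groups * n_per_group
  group <- rep(seq_len(n_groups), each = n_per_group)
  samples <- sprintf("G%d_%02d", group, sequence(rep(n_per_group, n_groups)))
  p_anc <- stats::runif(n_snps, maf_range[1], maf_range[2])
  pg <- matrix(0, n_groups, n_snps)
  for (g in seq_len(n_groups)) {
    pg[g, ] <- if (fst == 0) p_anc else
      stats::rbeta(n_snps, p_anc * (1 - fst) / fst,
                   (1 - p_anc) * (1 - fst) / fst)
  }
  calls <- matrix(NA_integer_, n, n_snps)
  for (i in seq_len(n))
    calls[i, ] <- stats::rbinom(n_snps, 2, pg[group[i], ])
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * n_snps) < missing_rate, n, n_snps)
    calls[mask] <- NA_integer_
  }
  rownames(calls) <- samples
  colnames(calls) <- sprintf("snp%04d", seq_len(n_snps))
  G <- genotype_matrix(calls, chrom = rep("1", n_snps),
                       pos = seq_len(n_snps))
  if (!is.null(vcf_path)) write_vcf(G, vcf_path)
  list(genotypes = G,
       labels = tibble::tibble(sample = samples, group = group),
       vcf_path = vcf_path)
}

#' Write a genotype matrix as a minimal VCF file
#'
#' Emits an uncompressed VCF v4.2 with GT-only genotype columns; missing
#' calls become `./.`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$calls
  gt <- c("0/0", "0/1", "1/1")
  chrom <- if (is.null(G$chrom)) rep("1", ncol(X)) else G$chrom
  pos <- if (is.null(G$pos)) seq_len(ncol(X)) else G$pos
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(X)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(X)), function(j) {
    calls <- ifelse(is.na(X[, j]), "./.", gt[X[, j] + 1L])
    paste(c(chrom[j], pos[j], colnames(X)[j], "A", "T", ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
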