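# Shared fixtures and independent oracles, built in code at test time.

# fixed five-leaf tree with branch lengths, used across the mapping tests
tree5 <- function() parse_newick(
  "((A:0.3,B:0.5):0.4,((C:0.2,D:0.7):0.3,E:0.6):0.2);")

# fixed 8-taxon study system: 1-hybridization network, its pruned backbone
# and the two no-hybridization backbones (polyploids placed at the A- or
# B-subgenome position)
toy_system <- function() {
  net <- toy_allopolyploid_network()
  dec <- homeologr:::network_events(net)
  clade <- dec$events[[1]]$clade
  list(net = net,
       pruned = dec$backbone,
       clade = clade,
       T1 = graft_clade(dec$backbone, clade, "P"),
       T2 = graft_clade(dec$backbone, clade, "S"),
       polyploids = c("H1", "H2"),
       candidates = c("P", "S"))
}

# random reconciliation instance: a random MUL tree (random backbone, a
# polyploid clade grafted into two random edges) and a random gene tree
# with <= 10 leaves and <= n_poly repeated species
random_mul_instance <- function(n_backbone = 4, n_poly = 2) {
  bb_taxa <- paste0("S", seq_len(n_backbone))
  poly_taxa <- paste0("P", seq_len(n_poly))
  bb <- ape::rtree(n_backbone, tip.label = sample(bb_taxa))
  clade <- if (n_poly == 1) poly_taxa else
    ape::rtree(n_poly, tip.label = sample(poly_taxa))
  edges <- edge_ids(bb)
  pe <- sample(edges, 2)
  mul <- build_mul_tree(bb, clade, pe[1], pe[2])
  present_bb <- bb_taxa[stats::runif(n_backbone) < 0.8]
  copies <- c(present_bb,
              rep(poly_taxa, times = sample(1:2, n_poly, replace = TRUE)))
  if (length(copies) > 10) copies <- sample(copies, 10)
  if (length(copies) < 2)
    copies <- unique(c(copies, bb_taxa[1:2]))
  labels <- make.unique(copies, sep = "_x")
  gt <- ape::rtree(length(labels), tip.label = sample(labels))
  fam <- gene_family(gt, stats::setNames(copies, labels))
  list(family = fam, mul = mul)
}

# exhaustive Mk likelihood: sum over all interior-node state combinations
# of prior(root) * prod over edges of P_t[state(parent), state(child)]
exhaustive_mk_likelihood <- function(tree, model, data) {
  x <- homeologr:::as_character_data(data, model, tree)
  k <- length(model$states)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  Pm <- lapply(tree$edge.length, function(t)
    as.matrix(Matrix::expm(model$Q * t)))
  tip_sets <- lapply(seq_len(nt), function(i) {
    s <- x[tree$tip.label[i]]
    if (is.na(s)) seq_len(k) else which(model$states == s)
  })
  interior <- (nt + 1L):nn
  grids <- rep(list(seq_len(k)), length(interior))
  names(grids) <- interior
  combs <- expand.grid(c(tip_sets, grids))
  root <- nt + 1L
  total <- 0
  for (r in seq_len(nrow(combs))) {
    st <- as.integer(combs[r, ])
    p <- model$root_prior[st[root]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pm[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  unname(total)
}

# Procrustes RMS after optimal translation/rotation/reflection/scaling-free
# alignment of configuration X onto Y
procrustes_rms <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$v %*% t(s$u)
  d <- X %*% R - Y
  sqrt(mean(d^2))
}

# marginal root posterior from the pruning pass (independent of the
# stochastic-mapping machinery's sampling loop)
root_posterior <- function(tree, model, data) {
  x <- homeologr:::as_character_data(data, model, tree)
  pp <- homeologr:::prune_partials(tree, model, x)
  r <- length(tree$tip.label) + 1L
  w <- model$root_prior * pp$L[r, ]
  w / sum(w)
}

# 100-sample genotype set with planted filter failures: variants 1-12
# exceed 10% missingness, variants 13-21 have MAF < 0.01, the remaining 79
# pass both rules
planted_filter_genotypes <- function() {
  set.seed(42)
  n <- 100
  calls <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  for (j in 1:12) calls[sample(n, 11), j] <- NA          # 11% missing
  for (j in 13:21) { calls[, j] <- 0L; calls[sample(n, 1), j] <- 1L }  # MAF 0.005
  for (j in 22:100) {                                    # guarantee passing
    miss <- which(is.na(calls[, j]))
    if (length(miss) > 10) calls[miss[-(1:10)], j] <- 1L
    if (min(mean(calls[, j], na.rm = TRUE) / 2,
            1 - mean(calls[, j], na.rm = TRUE) / 2) < 0.01)
      calls[1:10, j] <- 1L
  }
  genotype_matrix(calls)
}
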